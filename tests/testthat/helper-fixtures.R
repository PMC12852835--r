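make_fixture <- function(dir, seed = 5) {
  tr <- simulate_tree(24, seed = seed)
  trt <- evolve_traits(tr, 1, seed = seed)
  ct <- assemble_communities(tr, trt,
    sim_config(seed = seed, n_taxa = 24, n_samples = 16, depth_mean = 2000))
  md <- simulate_metadata(16, seed = seed)
  tax <- setNames(paste0("genus", rep(1:12, each = 2)), colnames(ct))
  paths <- list(table = file.path(dir, "table.tsv"),
                tree = file.path(dir, "tree.nwk"),
                meta = file.path(dir, "meta.tsv"),
                tax = file.path(dir, "tax.tsv"))
  write_count_table(ct, paths$table)
  ape::write.tree(tr, paths$tree)
  write_metadata(md, paths$meta)
  write_taxonomy(tax, paths$tax)
  paths
}
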