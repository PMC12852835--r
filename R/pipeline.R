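#' Validate agreement between a count table, tree and metadata
#'
#' Checks id agreement (table taxa vs tree tips, table samples vs metadata),
#' duplicated ids, and count validity, returning diagnostics rather than
#' throwing.
#'
#' @param table A [count_table()] (or matrix).
#' @param tree A `phylo` tree or `NULL`.
#' @param metadata A metadata data frame with `sample_id` or `NULL`.
#' @return Tibble of issues (`check`, `detail`); zero rows when clean.
#' @export
validate_inputs <- function(table, tree = NULL, metadata = NULL) {
  issues <- list()
  add <- function(check, detail)
    issues[[length(issues) + 1L]] <<- tibble::tibble(check = check,
                                                     detail = detail)
  m <- unclass(table)
  if (anyDuplicated(rownames(m)))
    add("duplicate_sample_id",
        paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    add("duplicate_taxon_id",
        paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (any(m < 0)) add("negative_counts", "count table has negative entries")
  if (!is.null(tree)) {
    miss <- setdiff(colnames(m), tree$tip.label)
    if (length(miss))
      add("taxon_missing_from_tree", paste(miss, collapse = ", "))
  }
  if (!is.null(metadata)) {
    md_ids <- if ("sample_id" %in% names(metadata))
      as.character(metadata$sample_id) else rownames(metadata)
    miss <- setdiff(rownames(m), md_ids)
    if (length(miss))
      add("sample_missing_from_metadata", paste(miss, collapse = ", "))
    if (anyDuplicated(md_ids))
      add("duplicate_metadata_sample_id",
          paste(unique(md_ids[duplicated(md_ids)]), collapse = ", "))
  }
  if (length(issues)) dplyr::bind_rows(issues)
  else tibble::tibble(check = character(), detail = character())
}

stratum_labels <- function(metadata, factor_name) {
  v <- metadata[[factor_name]]
  if (is.null(v)) abort(paste0("metadata has no column '", factor_name, "'"))
  ids <- as.character(metadata$sample_id)
  lab <- switch(factor_name,
                fir = quantile_split(v),
                ga_c = quantile_split(v),
                un_c = unc_status(v),
                as.character(v))
  setNames(lab, ids)
}

#' Run the full stratified analysis pipeline
#'
#' Orchestrates the whole analysis from files on disk: read and validate,
#' agglomerate to genus (when taxonomy is given), apply the global
#' prevalence/abundance filter and zero-variance removal, then globally
#' compute Faith's PD, generalized UniFrac, PERMANOVA and host
#' correlations, and per stratifying factor (high/low splits for `fir` and
#' `ga_c`, the 3.5 rule for `un_c`, categories as-is otherwise) apply the
#' within-group filter and produce an assembly-process summary and a
#' SparCC network with topology for every group. All artifacts are written
#' as TSV under `outdir` together with a JSON manifest of parameters and
#' file hashes; a rerun with the same inputs and seed reproduces identical
#' files.
#'
#' @param table_file,tree_file,metadata_file,taxonomy_file Input paths
#'   (taxonomy optional).
#' @param outdir Output directory (created if absent).
#' @param stratify Metadata factors to stratify by.
#' @param permanova_formula RHS formula for the community PERMANOVA.
#' @param n_null Null randomizations for the assembly engine.
#' @param n_boot Bootstrap tables for network significance.
#' @param n_perm PERMANOVA permutations.
#' @param alpha Generalized UniFrac exponent.
#' @param seed Master seed; every stage derives its own substream.
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(table_file, tree_file, metadata_file,
                         taxonomy_file = NULL, outdir,
                         stratify = c("region", "un_c"),
                         permanova_formula = ~ region + fir + ga_c + un_c,
                         n_null = 199L, n_boot = 30L, n_perm = 999L,
                         alpha = 0.5, seed = 1L) {
  for (f in c(table_file, tree_file, metadata_file, taxonomy_file))
    if (!file.exists(f)) abort(paste0("input file not found: ", f))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  table <- read_count_table(table_file, taxonomy_path = taxonomy_file)
  tree <- ape::read.tree(tree_file)
  metadata <- read_metadata(metadata_file)
  for (f in stratify)
    if (!f %in% names(metadata))
      abort(paste0("stratifying factor '", f, "' is not a metadata column"))
  issues <- validate_inputs(table, tree, metadata)
  if (nrow(issues))
    abort(paste0("input validation failed: ",
                 paste(issues$check, issues$detail, sep = ": ",
                       collapse = "; ")))
  say("inputs: %d samples x %d taxa", nrow(table), ncol(table))

  if (!is.null(taxonomy_of(table))) {
    tree <- agglomerate_tree(tree, taxonomy_of(table))
    table <- agglomerate_to_genus(table)
    say("agglomerated to %d genera", ncol(table))
  }
  table <- drop_zero_variance(global_filter(table))
  say("post-filter: %d taxa", ncol(table))
  write_count_table(table, file.path(outdir, "filtered_table.tsv"))

  pd <- faith_pd(table, tree)
  write.table(pd, file.path(outdir, "faith_pd.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gd <- gunifrac(table, tree, alpha = alpha)
  write_distance(gd, file.path(outdir, "gunifrac.tsv"))

  pm <- permanova(gd, metadata, permanova_formula, n_perm = n_perm,
                  seed = substream_seed(seed, "permanova"))
  write.table(as.data.frame(tidy(pm)), file.path(outdir, "permanova.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  host <- dplyr::bind_rows(
    fir_ga = pearson_test(metadata$fir, metadata$ga_c, remove_outliers = TRUE),
    fir_un = pearson_test(metadata$fir, metadata$un_c, remove_outliers = TRUE),
    ga_un = pearson_test(metadata$ga_c, metadata$un_c, remove_outliers = TRUE),
    .id = "pair")
  write.table(as.data.frame(host), file.path(outdir, "host_correlations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  for (f in stratify) {
    strata <- stratum_labels(metadata, f)
    groups <- within_group_filter(table, strata)
    for (g in names(groups)) {
      tag <- paste0(f, "_", g)
      sub <- groups[[g]]
      say("stratum %s: %d samples x %d taxa", tag, nrow(sub), ncol(sub))
      thr <- assembly_thresholds(n_null = n_null,
                                 seed = substream_seed(seed, paste0("asm_", tag)))
      pairs <- assembly_analysis(sub, tree, thr)
      write.table(as.data.frame(pairs),
                  file.path(outdir, paste0("assembly_pairs_", tag, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summ <- summarize_assembly(pairs)
      write.table(as.data.frame(summ),
                  file.path(outdir, paste0("assembly_summary_", tag, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      corr <- sparcc(sub, seed = substream_seed(seed, paste0("net_", tag)))
      pv <- bootstrap_pvalues(sub, corr, n_boot = n_boot,
                              seed = substream_seed(seed, paste0("boot_", tag)))
      net <- build_network(corr, pv$p_adj)
      write.table(as.data.frame(net$edges),
                  file.path(outdir, paste0("network_edges_", tag, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      top <- topology(net)
      write.table(as.data.frame(top$nodes),
                  file.path(outdir, paste0("network_nodes_", tag, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  writeLines(log_lines, file.path(outdir, "run.log"))
  outputs <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    parameters = list(stratify = stratify, n_null = n_null, n_boot = n_boot,
                      n_perm = n_perm, alpha = alpha, seed = seed,
                      formula = deparse(permanova_formula)),
    inputs = list(table = table_file, tree = tree_file,
                  metadata = metadata_file, taxonomy = taxonomy_file),
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(outdir, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
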