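# Small fixture builders and independent brute-force oracles used across
# the suite. Oracles are deliberately naive implementations, kept separate
# from the package's code paths.

toy_table <- function(m, taxonomy = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  count_table(m, taxonomy = taxonomy)
}

star_tree <- function(n, branch = 1) {
  txt <- paste0("(", paste0("t", seq_len(n), ":", branch, collapse = ","), ");")
  ape::read.tree(text = txt)
}

random_table <- function(n_samples, n_taxa, lambda = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
  toy_table(m)
}

# Faith's PD by explicit union of root-paths (independent of the package's
# incidence-matrix implementation).
oracle_faith_pd <- function(tree, present) {
  if (!length(present)) return(0)
  n_tip <- length(tree$tip.label)
  parent_edge <- integer(n_tip + tree$Nnode)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  edges <- integer(0)
  for (tp in present) {
    node <- match(tp, tree$tip.label)
    while (parent_edge[node] > 0) {
      edges <- c(edges, parent_edge[node])
      node <- tree$edge[parent_edge[node], 1]
    }
  }
  sum(tree$edge.length[unique(edges)])
}

# Abundance-weighted beta-MNTD by explicit double loop over taxa.
oracle_bmntd <- function(m, D, weighted = TRUE) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (k in seq_len(n - 1)) for (l in (k + 1):n) {
    pk <- which(m[k, ] > 0); pl <- which(m[l, ] > 0)
    fk <- if (weighted) m[k, pk] / sum(m[k, ]) else rep(1 / length(pk), length(pk))
    fl <- if (weighted) m[l, pl] / sum(m[l, ]) else rep(1 / length(pl), length(pl))
    t1 <- sum(vapply(seq_along(pk), function(i)
      fk[i] * min(D[pk[i], pl]), numeric(1)))
    t2 <- sum(vapply(seq_along(pl), function(j)
      fl[j] * min(D[pl[j], pk]), numeric(1)))
    out[k, l] <- out[l, k] <- 0.5 * (t1 + t2)
  }
  out
}

# Weighted UniFrac (alpha = 1 limit) by direct branch sums.
oracle_weighted_unifrac <- function(table, tree) {
  ra <- relative_abundance(table)
  n_tip <- length(tree$tip.label)
  desc <- lapply(seq_len(nrow(tree$edge)), function(e) {
    nd <- tree$edge[e, 2]
    if (nd <= n_tip) tree$tip.label[nd]
    else ape::extract.clade(tree, nd)$tip.label
  })
  n <- nrow(ra)
  d <- matrix(0, n, n, dimnames = list(rownames(ra), rownames(ra)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- den <- 0
    for (e in seq_along(desc)) {
      tx <- intersect(desc[[e]], colnames(ra))
      pa <- sum(ra[i, tx]); pb <- sum(ra[j, tx])
      num <- num + tree$edge.length[e] * abs(pa - pb)
      den <- den + tree$edge.length[e] * (pa + pb)
    }
    d[i, j] <- d[j, i] <- num / den
  }
  d
}

# Exhaustive-partition modularity maximum for small unweighted graphs.
oracle_best_modularity <- function(g) {
  n <- igraph::vcount(g)
  best <- -Inf
  # enumerate set partitions via restricted growth strings
  rec <- function(assign) {
    if (length(assign) == n) {
      q <- igraph::modularity(g, assign + 1L)
      if (q > best) best <<- q
      return()
    }
    for (b in 0:(max(assign) + 1L)) rec(c(assign, b))
  }
  rec(0L)
  best
}
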