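# Tip-by-edge incidence: tip_edge[i, e] is TRUE when edge e lies on the
# path from tip i to the root. Shared by Faith's PD and UniFrac.
tip_edge_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  parent_edge <- integer(n_tip + tree$Nnode) # edge above each node (0 = root)
  parent_edge[tree$edge[, 2L]] <- seq_len(n_edge)
  inc <- matrix(FALSE, n_tip, n_edge,
                dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(n_tip)) {
    node <- i
    while (parent_edge[node] > 0L) {
      e <- parent_edge[node]
      inc[i, e] <- TRUE
      node <- tree$edge[e, 1L]
    }
  }
  inc
}

check_taxa_in_tree <- function(table, tree) {
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing))
    abort(paste0("taxa missing from tree: ", paste(missing, collapse = ", ")))
}

#' Faith's phylogenetic diversity
#'
#' Per sample, the total branch length of the minimal subtree spanning the
#' present taxa *and the root* (include-root convention, so a single-taxon
#' sample has positive PD). Empty samples get PD 0.
#'
#' @param table A [count_table()]; presence is count > 0.
#' @param tree A rooted `phylo` tree containing every table taxon as a tip.
#' @return A tibble with columns `sample_id` and `faith_pd`.
#' @export
faith_pd <- function(table, tree) {
  check_taxa_in_tree(table, tree)
  inc <- tip_edge_incidence(tree)[colnames(table), , drop = FALSE]
  pres <- unclass(table) > 0
  pd <- apply(pres, 1L, function(p) {
    if (!any(p)) return(0)
    sum(tree$edge.length[colSums(inc[p, , drop = FALSE]) > 0])
  })
  tibble::tibble(sample_id = rownames(table), faith_pd = unname(pd))
}

# Validate and stamp the DistanceMatrix contract.
as_distance_matrix <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  if (max(abs(m - t(m))) > 1e-12) abort("distance matrix not symmetric")
  diag(m) <- 0
  if (any(m < -1e-12)) abort("negative distances")
  m[m < 0] <- 0
  m
}

#' Bray-Curtis dissimilarity on counts
#'
#' `d(x, y) = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, computed on raw
#' counts via [vegan::vegdist()].
#'
#' @param table A [count_table()] with positive sample totals.
#' @return A symmetric sample-by-sample distance matrix in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  relative_abundance(table) # validates positive totals
  m <- as.matrix(vegan::vegdist(unclass(table), method = "bray"))
  as_distance_matrix(m, rownames(table))
}

#' Generalized UniFrac distance
#'
#' For each branch with descendant relative-abundance proportions
#' `p_A`, `p_B` in the two samples, contributions
#' `L * (p_A + p_B)^alpha * |p_A - p_B| / (p_A + p_B)` are summed over
#' branches present in at least one sample and normalized by
#' `sum(L * (p_A + p_B)^alpha)`. `alpha = 1` is weighted UniFrac;
#' `alpha = 0.5` balances weighted and unweighted sensitivity.
#'
#' @param table A [count_table()].
#' @param tree Rooted `phylo` tree covering the table's taxa.
#' @param alpha Abundance-weighting exponent in `[0, 1]`.
#' @return A symmetric distance matrix in `[0, 1]`.
#' @export
gunifrac <- function(table, tree, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  check_taxa_in_tree(table, tree)
  ra <- relative_abundance(table)
  inc <- tip_edge_incidence(tree)[colnames(table), , drop = FALSE]
  # branch-by-sample descendant proportions
  P <- crossprod(inc, t(ra)) # n_edge x n_samples
  L <- tree$edge.length
  n <- nrow(table)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pa <- P[, i]; pb <- P[, j]
    tot <- pa + pb
    use <- tot > 0
    w <- L[use] * tot[use]^alpha
    d[i, j] <- d[j, i] <- sum(w * abs(pa[use] - pb[use]) / tot[use]) / sum(w)
  }
  as_distance_matrix(d, rownames(table))
}

# Core beta-MNTD given a patristic matrix D (taxa x taxa, in table column
# order) and a weight matrix F (samples x taxa, rows summing to 1 over
# present taxa). Nearest-taxon minima are shared across pairs:
# M[, l] = rowwise min of D over the taxa present in sample l, so
# bMNTD(k, l) = 0.5 * (F[k, ] %*% M[, l] + F[l, ] %*% M[, k]).
bmntd_core <- function(D, F, pres) {
  n <- nrow(F)
  M <- vapply(seq_len(n), function(l)
    apply(D[, pres[l, ], drop = FALSE], 1L, min), numeric(ncol(F)))
  C <- F %*% M
  0.5 * (C + t(C))
}

#' Between-community mean nearest taxon distance (beta-MNTD)
#'
#' For each sample pair, the abundance-weighted mean over taxa of the
#' patristic distance to the nearest taxon in the other community,
#' averaged over both directions. Shared taxa contribute zero to their own
#' nearest-neighbour term.
#'
#' @param table A [count_table()] with at least one taxon present per sample.
#' @param tree Rooted `phylo` tree covering the table's taxa.
#' @param weighted Use relative abundances as weights (`TRUE`, default) or
#'   uniform weights over present taxa (`FALSE`).
#' @return A symmetric sample-by-sample distance matrix.
#' @export
bmntd <- function(table, tree, weighted = TRUE) {
  check_taxa_in_tree(table, tree)
  m <- unclass(table)
  if (any(rowSums(m > 0) == 0))
    abort("every sample must contain at least one taxon")
  D <- ape::cophenetic.phylo(tree)[colnames(table), colnames(table)]
  pres <- m > 0
  F <- if (weighted) relative_abundance(table)
       else sweep(pres * 1, 1L, rowSums(pres), "/")
  as_distance_matrix(bmntd_core(D, F, pres), rownames(table))
}
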