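#' Construct a community count table
#'
#' The universal community object: a samples-by-taxa matrix of non-negative
#' integer counts with unique sample and taxon ids, optionally carrying a
#' taxonomy map (taxon id to genus label) used for agglomeration.
#'
#' @param counts A numeric matrix (samples in rows, taxa in columns) with
#'   dimnames, or a data frame whose first column is `sample_id`.
#' @param taxonomy Optional named character vector mapping taxon ids to
#'   genus labels; may cover a subset of taxa.
#' @return An integer matrix of class `count_table` with a `taxonomy`
#'   attribute.
#' @export
count_table <- function(counts, taxonomy = NULL) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts[[1L]])
    counts <- as.matrix(counts[-1L])
    rownames(counts) <- ids
  }
  if (!is.matrix(counts)) abort("`counts` must be a matrix or data frame.")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("`counts` needs sample ids (rownames) and taxon ids (colnames).")
  if (anyDuplicated(rownames(counts))) abort("duplicated sample ids")
  if (anyDuplicated(colnames(counts))) abort("duplicated taxon ids")
  if (any(!is.finite(counts)) || any(counts < 0))
    abort("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    abort("counts must be integers")
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) abort("`taxonomy` must be named by taxon id")
    extra <- setdiff(names(taxonomy), colnames(counts))
    if (length(extra))
      abort(paste0("taxonomy names absent from table: ",
                   paste(head(extra, 5), collapse = ", ")))
  }
  structure(counts, taxonomy = taxonomy, class = c("count_table", "matrix", "array"))
}

taxonomy_of <- function(table) attr(table, "taxonomy")

# Rebuild the class/taxonomy attributes after a subsetting operation.
restore_ct <- function(counts, taxonomy = NULL) {
  tx <- if (!is.null(taxonomy))
    taxonomy[names(taxonomy) %in% colnames(counts)] else NULL
  if (!length(tx)) tx <- NULL
  count_table(unclass(counts), taxonomy = tx)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d samples x %d taxa%s\n", nrow(x), ncol(x),
              if (is.null(taxonomy_of(x))) "" else " (with taxonomy)"))
  invisible(x)
}

#' Agglomerate ASV-level counts to genus level
#'
#' Sums counts over all taxa sharing a genus label. Taxa without a genus
#' assignment are dropped: one taxonomic rank per analysis, no fallback to
#' coarser ranks.
#'
#' @param table A [count_table()] with a taxonomy attribute.
#' @return A `count_table` with one column per genus (taxonomy becomes the
#'   identity map genus -> genus).
#' @export
agglomerate_to_genus <- function(table) {
  tx <- taxonomy_of(table)
  if (is.null(tx)) abort("taxonomy required for genus agglomeration")
  keep <- colnames(table)[colnames(table) %in% names(tx)]
  genera <- tx[keep]
  m <- unclass(table)[, keep, drop = FALSE]
  agg <- t(rowsum(t(m), group = genera))
  # rowsum sorts groups; keep first-appearance order of genera
  ord <- unique(unname(genera))
  agg <- agg[, ord, drop = FALSE]
  count_table(agg, taxonomy = setNames(ord, ord))
}

#' Relative abundances
#'
#' @param table A [count_table()] (or count matrix); every sample total must
#'   be positive.
#' @return A numeric matrix whose rows sum to one.
#' @export
relative_abundance <- function(table) {
  m <- unclass(table)
  tot <- rowSums(m)
  bad <- rownames(m)[tot <= 0]
  if (length(bad))
    abort(paste0("zero-total sample(s): ", paste(bad, collapse = ", ")))
  sweep(m, 1L, tot, "/")
}

#' Global prevalence and abundance filter
#'
#' Retains taxa that occur (count > 0) in at least `min_prevalence` of all
#' samples *and* whose mean relative abundance strictly exceeds
#' `min_mean_relabund`. Defaults encode the standard pre-analysis filter:
#' present in >= 20% of samples and > 0.1% mean relative abundance.
#'
#' @param table A [count_table()].
#' @param min_prevalence Inclusive prevalence threshold (fraction of samples).
#' @param min_mean_relabund Strict mean relative-abundance threshold.
#' @return Filtered `count_table`; the sample set is unchanged.
#' @export
global_filter <- function(table, min_prevalence = 0.20,
                          min_mean_relabund = 0.001) {
  m <- unclass(table)
  prev <- colMeans(m > 0)
  mra <- colMeans(relative_abundance(table))
  keep <- prev >= min_prevalence & mra > min_mean_relabund
  if (!any(keep))
    abort("all taxa removed by global filter; review thresholds")
  restore_ct(m[, keep, drop = FALSE], taxonomy_of(table))
}

#' Remove zero-variance taxa
#'
#' Drops taxa whose count vector is constant across samples (including
#' all-zero taxa).
#'
#' @param table A [count_table()].
#' @return Filtered `count_table`.
#' @export
drop_zero_variance <- function(table) {
  m <- unclass(table)
  keep <- apply(m, 2L, function(v) any(v != v[1L]))
  restore_ct(m[, keep, drop = FALSE], taxonomy_of(table))
}

#' Per-group prevalence filter
#'
#' Splits samples by a stratum assignment and, independently within each
#' group, keeps taxa present in at least `min_prevalence` of the group's
#' samples.
#'
#' @param table A [count_table()].
#' @param strata Named character vector (or factor) sample id -> group label.
#' @param min_prevalence Inclusive within-group prevalence threshold.
#' @return Named list of per-group `count_table`s.
#' @export
within_group_filter <- function(table, strata, min_prevalence = 0.05) {
  strata <- setNames(as.character(strata), names(strata))
  if (is.null(names(strata))) abort("`strata` must be named by sample id")
  missing <- setdiff(names(strata), rownames(table))
  if (length(missing))
    abort(paste0("strata samples absent from table: ",
                 paste(missing, collapse = ", ")))
  out <- list()
  for (g in unique(strata)) {
    ids <- names(strata)[strata == g]
    if (length(ids) < 2L)
      abort(paste0("group '", g, "' has fewer than 2 samples"))
    m <- unclass(table)[ids, , drop = FALSE]
    keep <- colMeans(m > 0) >= min_prevalence
    out[[g]] <- restore_ct(m[, keep, drop = FALSE], taxonomy_of(table))
  }
  out
}

#' Centered log-ratio transform
#'
#' Per sample, log(count + pseudocount) centered by the sample mean log, so
#' rows sum to zero.
#'
#' @param table A [count_table()].
#' @param pseudocount Positive offset added to every count before the log.
#' @return Numeric matrix of CLR values.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    abort("`pseudocount` must be positive")
  lg <- log(unclass(table) + pseudocount)
  lg - rowMeans(lg)
}

#' Rank-based equal-size binning (high/low splits)
#'
#' `ntile`-style binning: ranks with ties broken by stable input order,
#' earlier bins receiving the extra elements when `length(x)` is not a
#' multiple of `n_bins`. With `n_bins = 2` the labels are `low`/`high`.
#'
#' @param values Numeric vector (NAs allowed; they get NA labels).
#' @param n_bins Number of tiles.
#' @return Character vector of labels (`low`/`high` for 2 bins, otherwise
#'   `tile1..tileK`).
#' @export
quantile_split <- function(values, n_bins = 2L) {
  ok <- !is.na(values)
  if (sum(ok) < n_bins) abort("fewer non-missing values than bins")
  r <- rank(values[ok], ties.method = "first")
  n <- sum(ok)
  bin <- floor((r - 1L) * n_bins / n) + 1L
  labs <- if (n_bins == 2L) c("low", "high") else paste0("tile", seq_len(n_bins))
  out <- rep(NA_character_, length(values))
  out[ok] <- labs[bin]
  out
}

#' Nutritional status from the urinary urea nitrogen:creatinine ratio
#'
#' UN:C ratios strictly above 3.5 indicate catabolism of endogenous protein
#' (poor nutritional status) and are labelled `high`; 3.5 itself is `low`.
#'
#' @param un_c Non-negative numeric vector of UN:C ratios.
#' @param threshold Strict cut point.
#' @return Character vector `high`/`low`.
#' @export
unc_status <- function(un_c, threshold = 3.5) {
  if (any(un_c < 0, na.rm = TRUE)) abort("UN:C ratios must be non-negative")
  ifelse(un_c > threshold, "high", "low")
}

#' Prune a tree to one representative tip per genus
#'
#' Companion to [agglomerate_to_genus()]: keeps the first listed member of
#' each genus and relabels it with the genus name, so phylogenetic metrics
#' can be computed on the agglomerated table.
#'
#' @param tree A `phylo` tree whose tips are the pre-agglomeration taxa.
#' @param taxonomy Named character vector taxon id -> genus.
#' @return A `phylo` tree with one tip per genus.
#' @export
agglomerate_tree <- function(tree, taxonomy) {
  taxonomy <- taxonomy[names(taxonomy) %in% tree$tip.label]
  if (!length(taxonomy)) abort("taxonomy covers no tree tips")
  reps <- tapply(names(taxonomy), taxonomy, function(x) x[[1L]])
  out <- ape::keep.tip(tree, unname(reps))
  out$tip.label <- names(reps)[match(out$tip.label, reps)]
  out
}
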