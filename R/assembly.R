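#' Null-model thresholds for assembly-process classification
#'
#' @param bnti_crit Critical beta-NTI magnitude separating deterministic
#'   from stochastic assembly (z-score units; the framework's conventional
#'   value is 2).
#' @param rc_crit Critical Raup-Crick magnitude (on the `[-1, 1]` scale;
#'   conventional 0.95).
#' @param n_null Number of null randomizations for both the beta-MNTD and
#'   Raup-Crick nulls (>= 99).
#' @param seed Integer seed driving both null engines.
#' @return A list of class `assembly_thresholds`.
#' @export
assembly_thresholds <- function(bnti_crit = 2, rc_crit = 0.95,
                                n_null = 999L, seed = 1L) {
  if (bnti_crit <= 0) abort("bnti_crit must be > 0")
  if (rc_crit <= 0 || rc_crit >= 1) abort("rc_crit must be in (0, 1)")
  if (n_null < 99L) abort("n_null must be >= 99")
  structure(list(bnti_crit = bnti_crit, rc_crit = rc_crit,
                 n_null = as.integer(n_null), seed = as.integer(seed)),
            class = "assembly_thresholds")
}

pair_index <- function(ids) {
  cmb <- combn(ids, 2L)
  tibble::tibble(sample_a = cmb[1L, ], sample_b = cmb[2L, ])
}

#' Beta nearest taxon index (beta-NTI) for every sample pair
#'
#' Observed beta-MNTD is compared with a null distribution obtained by
#' shuffling taxon identities across the tips of the phylogeny (abundances
#' fixed), recomputing beta-MNTD `n_null` times;
#' `bNTI = (obs - mean_null) / sd_null`. A pair whose null distribution is
#' degenerate (sd 0) gets `NA` and is later classified `unclassifiable`.
#'
#' @param table A [count_table()] (>= 2 samples).
#' @param tree Rooted `phylo` tree covering the table's taxa.
#' @param thresholds An [assembly_thresholds()].
#' @param weighted Abundance-weighted beta-MNTD (default) or
#'   presence-absence.
#' @return A tibble with `sample_a`, `sample_b`, `bmntd_obs`, `null_mean`,
#'   `null_sd`, `bnti`.
#' @export
bnti_pairwise <- function(table, tree, thresholds = assembly_thresholds(),
                          weighted = TRUE) {
  stopifnot(inherits(thresholds, "assembly_thresholds"))
  if (nrow(table) < 2L) abort("need at least 2 samples")
  check_taxa_in_tree(table, tree)
  m <- unclass(table)
  if (any(rowSums(m > 0) == 0)) abort("empty sample")
  D <- ape::cophenetic.phylo(tree)[colnames(table), colnames(table)]
  pres <- m > 0
  F <- if (weighted) relative_abundance(table)
       else sweep(pres * 1, 1L, rowSums(pres), "/")
  obs <- bmntd_core(D, F, pres)
  n <- nrow(m); d <- ncol(m)
  up <- upper.tri(obs)
  s1 <- s2 <- matrix(0, n, n)
  with_substream(thresholds$seed, "bnti_null", {
    for (b in seq_len(thresholds$n_null)) {
      p <- sample.int(d)
      Bn <- bmntd_core(D[p, p], F, pres)
      s1 <- s1 + Bn
      s2 <- s2 + Bn^2
    }
  })
  nm <- s1 / thresholds$n_null
  nv <- (s2 - thresholds$n_null * nm^2) / (thresholds$n_null - 1L)
  nv[nv < 0] <- 0
  nsd <- sqrt(nv)
  pairs <- pair_index(rownames(m))
  ia <- match(pairs$sample_a, rownames(m)); ib <- match(pairs$sample_b, rownames(m))
  idx <- cbind(ia, ib)
  sdv <- nsd[idx]
  degenerate <- sdv <= 1e-6 * pmax(1, nm[idx]) # exact-null symmetry up to fp noise
  bnti <- ifelse(degenerate, NA_real_, (obs[idx] - nm[idx]) / sdv)
  if (anyNA(bnti))
    warn(sprintf("%d pair(s) have degenerate beta-MNTD nulls (sd = 0); bNTI is NA",
                 sum(is.na(bnti))))
  tibble::tibble(pairs, bmntd_obs = obs[idx], null_mean = nm[idx],
                 null_sd = sdv, bnti = bnti)
}

# One Raup-Crick null community for a sample: richness and total count are
# preserved; taxa enter with probability proportional to dataset-wide
# occupancy, then individuals fill proportionally to dataset-wide relative
# abundance.
rc_null_draws <- function(richness, total, occ, relab, n_null) {
  d <- length(occ)
  out <- matrix(0L, d, n_null)
  for (b in seq_len(n_null)) {
    chosen <- sample.int(d, richness, prob = occ)
    v <- integer(d)
    v[chosen] <- 1L
    if (total > richness)
      v[chosen] <- v[chosen] +
        rmultinom(1L, total - richness, relab[chosen])[, 1L]
    out[, b] <- v
  }
  out
}

bray_cols <- function(A, B) {
  # column-wise Bray-Curtis between two d x n matrices
  1 - 2 * colSums(pmin(A, B)) / (colSums(A) + colSums(B))
}

#' Raup-Crick metric on Bray-Curtis dissimilarity
#'
#' For each sample pair the observed Bray-Curtis value is located within a
#' null distribution of dissimilarities between stochastically assembled
#' communities that preserve each sample's richness and total count (taxa
#' drawn by occupancy, filled by dataset-wide relative abundance):
#' `RC = 2 * [P(null < obs) + 0.5 * P(null = obs)] - 1`, in `[-1, 1]`.
#'
#' @param table A [count_table()] with >= 2 taxa and positive totals.
#' @param thresholds An [assembly_thresholds()].
#' @param pairs Optional tibble/data frame with columns `sample_a`,
#'   `sample_b` restricting which pairs are evaluated (default: all).
#' @return A tibble with `sample_a`, `sample_b`, `bray_obs`, `rc_bray`.
#' @export
rc_bray <- function(table, thresholds = assembly_thresholds(), pairs = NULL) {
  stopifnot(inherits(thresholds, "assembly_thresholds"))
  m <- unclass(table)
  if (ncol(m) < 2L) abort("Raup-Crick needs >= 2 taxa in the pool")
  if (any(rowSums(m) <= 0)) abort("zero-total sample")
  occ <- colSums(m > 0)
  relab <- colSums(m) / sum(m)
  n <- nrow(m)
  obs <- as.matrix(vegan::vegdist(m, method = "bray"))
  if (is.null(pairs)) pairs <- pair_index(rownames(m))
  else pairs <- tibble::as_tibble(pairs[, c("sample_a", "sample_b")])
  needed <- unique(c(pairs$sample_a, pairs$sample_b))
  nulls <- with_substream(thresholds$seed, "rc_null", {
    out <- vector("list", n)
    for (k in seq_len(n)) {
      if (!rownames(m)[k] %in% needed) next
      out[[k]] <- rc_null_draws(sum(m[k, ] > 0), sum(m[k, ]), occ, relab,
                                thresholds$n_null)
    }
    out
  })
  rc <- bray_o <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs$sample_a[r], rownames(m))
    j <- match(pairs$sample_b[r], rownames(m))
    bn <- bray_cols(nulls[[i]], nulls[[j]])
    o <- obs[i, j]
    less <- sum(bn < o - 1e-12); eq <- sum(abs(bn - o) <= 1e-12)
    rc[r] <- 2 * ((less + 0.5 * eq) / thresholds$n_null) - 1
    bray_o[r] <- o
  }
  tibble::tibble(pairs, bray_obs = bray_o, rc_bray = rc)
}

#' Classify a sample pair into an assembly process
#'
#' The two-stage Stegen decision rule: `|bNTI| > bnti_crit` signals
#' deterministic selection (variable if positive, homogeneous if negative);
#' otherwise Raup-Crick separates the stochastic processes
#' (`rc > rc_crit` dispersal limitation, `rc < -rc_crit` homogenizing
#' dispersal, `|rc| <= rc_crit` drift/undominated). Non-finite inputs give
#' `unclassifiable`.
#'
#' @param bnti Numeric vector of beta-NTI values.
#' @param rc Numeric vector of Raup-Crick values in `[-1, 1]`.
#' @param thresholds An [assembly_thresholds()].
#' @return Character vector of process labels.
#' @export
classify_assembly <- function(bnti, rc, thresholds = assembly_thresholds()) {
  if (any(abs(rc) > 1 + 1e-12, na.rm = TRUE)) abort("rc outside [-1, 1]")
  out <- rep("unclassifiable", length(bnti))
  ok <- is.finite(bnti) & is.finite(rc)
  out[ok & bnti > thresholds$bnti_crit] <- "variable_selection"
  out[ok & bnti < -thresholds$bnti_crit] <- "homogeneous_selection"
  sto <- ok & abs(bnti) <= thresholds$bnti_crit
  out[sto & rc > thresholds$rc_crit] <- "dispersal_limitation"
  out[sto & rc < -thresholds$rc_crit] <- "homogenizing_dispersal"
  out[sto & abs(rc) <= thresholds$rc_crit] <- "drift_undominated"
  out
}

process_levels <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "drift_undominated")

#' Full pairwise assembly analysis
#'
#' Runs [bnti_pairwise()] and [rc_bray()] on one table and classifies every
#' sample pair.
#'
#' @inheritParams bnti_pairwise
#' @return A tibble (class `pairwise_assembly`) with per-pair beta-MNTD,
#'   beta-NTI, Raup-Crick and process label.
#' @export
assembly_analysis <- function(table, tree,
                              thresholds = assembly_thresholds(),
                              weighted = TRUE) {
  b <- bnti_pairwise(table, tree, thresholds, weighted = weighted)
  r <- rc_bray(table, thresholds)
  out <- dplyr::inner_join(b, r, by = c("sample_a", "sample_b"))
  out$process <- classify_assembly(out$bnti, out$rc_bray, thresholds)
  class(out) <- c("pairwise_assembly", class(out))
  out
}

#' Summarize assembly-process fractions per group
#'
#' Fractions are computed over *within-group* sample pairs only;
#' unclassifiable pairs are reported but excluded from the denominator, so
#' the five process fractions sum to one within each group.
#'
#' @param pairs A tibble from [assembly_analysis()] (columns `sample_a`,
#'   `sample_b`, `process`).
#' @param strata Optional named vector sample id -> group label; `NULL`
#'   treats all samples as one group `all`.
#' @return A tibble (class `assembly_summary`) with `group`, `process`,
#'   `fraction`, `n_pairs` (classified pairs in the group) and
#'   `n_unclassifiable`.
#' @export
summarize_assembly <- function(pairs, strata = NULL) {
  ids <- unique(c(pairs$sample_a, pairs$sample_b))
  if (is.null(strata)) strata <- setNames(rep("all", length(ids)), ids)
  strata <- setNames(as.character(strata), names(strata))
  ga <- strata[pairs$sample_a]; gb <- strata[pairs$sample_b]
  res <- list()
  for (g in unique(stats::na.omit(unname(strata)))) {
    sel <- !is.na(ga) & !is.na(gb) & ga == g & gb == g
    lab <- pairs$process[sel]
    n_uncl <- sum(lab == "unclassifiable")
    lab <- lab[lab != "unclassifiable"]
    if (!length(lab)) {
      warn(sprintf("group '%s' has no classifiable pairs", g))
      frac <- rep(NA_real_, length(process_levels))
    } else {
      frac <- as.numeric(table(factor(lab, process_levels)) / length(lab))
    }
    res[[g]] <- tibble::tibble(group = g, process = process_levels,
                               fraction = frac, n_pairs = length(lab),
                               n_unclassifiable = n_uncl)
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("assembly_summary", class(out))
  out
}
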