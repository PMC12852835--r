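# One SparCC basis-correlation estimate from a single fraction matrix
# (samples x taxa). T_ij = var(log(x_i/x_j)) is obtained from the log
# covariance S as S_ii + S_jj - 2 S_ij; the basis variances solve the
# approximation  t = M w  with M = J + (d-2) I, modified as strongly
# correlated pairs are excluded.
sparcc_basis <- function(frac, exclusion_threshold, max_excl) {
  lg <- log(frac)
  S <- cov(lg)
  d <- ncol(S)
  v <- diag(S)
  Tm <- outer(v, v, "+") - 2 * S
  M <- matrix(1, d, d); diag(M) <- d - 1
  tvec <- rowSums(Tm)
  excluded <- matrix(FALSE, d, d)
  rho <- NULL
  for (iter in seq_len(max_excl + 1L)) {
    w <- tryCatch(solve(M, tvec), error = function(e) NULL)
    if (is.null(w)) break
    w[w <= 0] <- min(w[w > 0], 1e-6) # guard: variances must be positive
    cb <- (outer(w, w, "+") - Tm) / 2
    rho <- cb / sqrt(outer(w, w))
    rho[rho > 1] <- 1; rho[rho < -1] <- -1
    diag(rho) <- 1
    if (iter > max_excl) break
    cand <- abs(rho); cand[excluded] <- 0; diag(cand) <- 0
    mx <- max(cand)
    if (mx <= exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1L, ]
    i <- ij[1L]; j <- ij[2L]
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1; M[j, j] <- M[j, j] - 1
    tvec[i] <- tvec[i] - Tm[i, j]; tvec[j] <- tvec[j] - Tm[i, j]
  }
  if (is.null(rho)) abort("singular SparCC system; too few taxa or samples")
  rho
}

#' SparCC compositional correlation estimation
#'
#' Estimates correlations among *basis* (absolute) abundances from
#' compositional counts. Each of `n_inner` repetitions resamples fractions
#' from a per-sample Dirichlet posterior (counts + 1), solves the log-ratio
#' variance system for basis variances, and forms basis correlations;
#' pairs whose estimated correlation magnitude exceeds
#' `exclusion_threshold` are iteratively excluded from the system (at most
#' `d - 3` exclusions). The final estimate is the element-wise median over
#' repetitions.
#'
#' @param table A [count_table()] with >= 4 taxa and >= 2 samples.
#' @param n_inner Number of Dirichlet resampling repetitions.
#' @param exclusion_threshold Magnitude above which a pair is excluded from
#'   the basis-variance system.
#' @param seed Integer seed.
#' @return Symmetric correlation matrix with unit diagonal, taxa as
#'   dimnames.
#' @export
sparcc <- function(table, n_inner = 20L, exclusion_threshold = 0.1,
                   seed = 1L) {
  m <- unclass(table)
  m <- m[order(rownames(m)), , drop = FALSE] # canonical order: row-order invariance
  d <- ncol(m)
  if (d < 4L)
    abort("SparCC needs >= 4 taxa: the basis decomposition is unidentifiable below that")
  if (nrow(m) < 2L) abort("SparCC needs >= 2 samples")
  max_excl <- d - 3L
  with_substream(seed, "sparcc", {
    est <- array(NA_real_, c(d, d, n_inner))
    for (b in seq_len(n_inner)) {
      frac <- t(apply(m + 1, 1L, function(row) {
        g <- rgamma(d, shape = row, rate = 1); g / sum(g)
      }))
      est[, , b] <- sparcc_basis(frac, exclusion_threshold, max_excl)
    }
    out <- apply(est, c(1, 2), median)
    out <- (out + t(out)) / 2
    diag(out) <- 1
    dimnames(out) <- list(colnames(m), colnames(m))
    out
  })
}

#' Bootstrap significance for SparCC correlations
#'
#' Null tables are built by independently permuting each taxon's counts
#' across samples (marginals preserved, associations broken) and SparCC is
#' re-estimated on each. Null correlation magnitudes are pooled across all
#' taxon pairs and permutation tables, and each observed pair gets the
#' two-sided plus-one p-value
#' `p = (1 + #{|r_null| >= |r_obs|}) / (1 + n_null_values)` against that
#' pooled null, followed by Benjamini-Hochberg adjustment across pairs.
#' Pooling gives p-value resolution `1 / (1 + n_pairs * n_boot)`; with
#' per-pair nulls the smallest attainable p, `1 / (1 + n_boot)`, could
#' never survive a multiple-testing correction at realistic `n_boot`.
#'
#' @param table The [count_table()] `observed` was estimated from.
#' @param observed Correlation matrix from [sparcc()] on `table`.
#' @param n_boot Number of permutation tables (>= 20).
#' @param n_inner Passed to the inner [sparcc()] runs.
#' @param seed Integer seed.
#' @return List with `p` (raw) and `p_adj` (BH-adjusted) symmetric
#'   matrices.
#' @export
bootstrap_pvalues <- function(table, observed, n_boot = 100L, n_inner = 20L,
                              seed = 1L) {
  if (n_boot < 20L) abort("n_boot must be >= 20 (p-value resolution)")
  m <- unclass(table)
  d <- ncol(m)
  stopifnot(nrow(observed) == d)
  up <- upper.tri(observed)
  null_pool <- with_substream(seed, "sparcc_boot", {
    vapply(seq_len(n_boot), function(b) {
      perm <- apply(m, 2L, sample)
      rownames(perm) <- rownames(m)
      rn <- sparcc(count_table(perm), n_inner = n_inner,
                   seed = substream_seed(seed, paste0("boot", b)))
      abs(rn[up])
    }, numeric(sum(up)))
  })
  null_sorted <- sort(as.numeric(null_pool))
  n_null <- length(null_sorted)
  # #{null >= obs} via binary search on the sorted pooled null
  exceed_count <- function(x)
    n_null - findInterval(x - 1e-12, null_sorted)
  p <- matrix(1, d, d)
  p[up] <- (1 + exceed_count(abs(observed[up]))) / (1 + n_null)
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  diag(p) <- 1
  padj <- p
  padj[up] <- p.adjust(p[up], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  dimnames(p) <- dimnames(padj) <- dimnames(observed)
  list(p = p, p_adj = padj)
}
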