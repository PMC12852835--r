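#' IQR outlier removal for a pair of variables
#'
#' Computes Tukey fences `[Q1 - k IQR, Q3 + k IQR]` for each variable
#' separately (quartiles by linear interpolation) and removes a pair when
#' either coordinate falls outside its own variable's fences.
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @param k Fence multiplier.
#' @return A list with `x`, `y` (retained pairs), `removed` (indices) and
#'   `fences` (2 x 2 matrix).
#' @export
iqr_outlier_filter <- function(x, y, k = 1.5) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 4L) abort("need at least 4 pairs")
  fence <- function(v) {
    q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    c(q[1] - k * (q[2] - q[1]), q[2] + k * (q[2] - q[1]))
  }
  fx <- fence(x); fy <- fence(y)
  bad <- x < fx[1] | x > fx[2] | y < fy[1] | y > fy[2]
  list(x = x[!bad], y = y[!bad], removed = which(bad),
       fences = rbind(x = fx, y = fy))
}

#' Pearson correlation test
#'
#' Two-sided test of association; the statistic is
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 3, both with nonzero variance).
#' @param remove_outliers Apply [iqr_outlier_filter()] first.
#' @param k Fence multiplier when removing outliers.
#' @return A tibble with `r`, `t_stat`, `df`, `p_value`, `n_used`.
#' @export
pearson_test <- function(x, y, remove_outliers = FALSE, k = 1.5) {
  if (remove_outliers) {
    f <- iqr_outlier_filter(x, y, k = k)
    x <- f$x; y <- f$y
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), t_stat = unname(ct$statistic),
                 df = as.integer(ct$parameter), p_value = ct$p.value,
                 n_used = length(x))
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` with natural logarithm over the positive
#' entries of the renormalized proportion vector.
#'
#' @param proportions Non-negative vector with positive sum.
#' @return Non-negative scalar.
#' @export
shannon_diversity <- function(proportions) {
  if (any(proportions < 0)) abort("proportions must be non-negative")
  if (sum(proportions) <= 0) abort("proportions sum to zero")
  unname(vegan::diversity(proportions, index = "shannon"))
}

# All permutations of 1..n (n small), one per row.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(k, rows), sub + (sub >= k))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

#' Distance-based PERMANOVA with marginal (type II-like) sums of squares
#'
#' McArdle-Anderson partitioning of a distance matrix: the Gower-centered
#' inner-product matrix `G` is formed from squared distances, the sum of
#' squares explained by a model-matrix column space is `trace(H G H)`, and
#' each term's marginal SS is `SS(full) - SS(full minus that term's
#' columns)`. Pseudo-F uses residual degrees of freedom; p-values come
#' from free permutation of the sample labels.
#'
#' @param dist A symmetric distance matrix (or `dist`) with sample ids.
#' @param metadata Data frame with a `sample_id` column (or rownames)
#'   covering the distance matrix samples.
#' @param formula Right-hand-side model formula, e.g.
#'   `~ region + fir + un_c + fir:un_c`.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive Enumerate all `n!` permutations instead (only for
#'   `n <= 8`); p-values are then exact.
#' @return An object of class `permanova`; see [tidy.permanova()].
#' @export
permanova <- function(dist, metadata, formula, n_perm = 999L, seed = 1L,
                      exhaustive = FALSE) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  ids <- rownames(dist)
  if (is.null(ids)) abort("distance matrix needs sample ids")
  md <- as.data.frame(metadata)
  if ("sample_id" %in% names(md)) rownames(md) <- md$sample_id
  if (!all(ids %in% rownames(md)))
    abort("metadata does not cover all distance-matrix samples")
  md <- md[ids, , drop = FALSE]
  n <- length(ids)
  if (!exhaustive && n_perm < 99L) abort("n_perm must be >= 99")

  A <- -0.5 * dist^2
  cen <- diag(n) - matrix(1 / n, n, n)
  G <- cen %*% A %*% cen
  ss_total <- sum(diag(G))

  mm <- model.matrix(formula, data = md)
  asg <- attr(mm, "assign")
  labels <- attr(terms(formula, data = md), "term.labels")
  if (qr(mm)$rank < ncol(mm)) {
    # name an offending term for the user
    for (t in seq_along(labels)) {
      sub <- mm[, asg <= t, drop = FALSE]
      if (qr(sub)$rank < ncol(sub))
        abort(paste0("model matrix rank-deficient at term '", labels[t], "'"))
    }
    abort("model matrix is rank-deficient")
  }
  hat <- function(X) {
    qd <- qr(X)
    Q <- qr.Q(qd)[, seq_len(qd$rank), drop = FALSE]
    tcrossprod(Q)
  }
  H_full <- hat(mm)
  rank_full <- qr(mm)$rank
  df_res <- n - rank_full
  H_drop <- lapply(seq_along(labels), function(t)
    hat(mm[, asg != t, drop = FALSE]))
  df_term <- vapply(seq_along(labels), function(t)
    rank_full - qr(mm[, asg != t, drop = FALSE])$rank, numeric(1))

  ss_stats <- function(Gp) {
    ss_full <- sum(H_full * Gp) # trace(H G) for symmetric H, G
    ss_res <- sum(diag(Gp)) - ss_full
    ss_t <- ss_full - vapply(H_drop, function(H) sum(H * Gp), numeric(1))
    f <- (ss_t / df_term) / (ss_res / df_res)
    list(ss = ss_t, f = f, ss_res = ss_res)
  }
  obs <- ss_stats(G)

  if (exhaustive) {
    if (n > 8L) abort("exhaustive enumeration limited to n <= 8")
    P <- all_perms(n)
    count <- numeric(length(labels))
    for (r in seq_len(nrow(P))) {
      p <- P[r, ]
      count <- count + (ss_stats(G[p, p])$f >= obs$f - 1e-12)
    }
    pval <- count / nrow(P)
    n_perm_used <- nrow(P) - 1L
  } else {
    count <- numeric(length(labels))
    with_substream(seed, "permanova", {
      for (b in seq_len(n_perm)) {
        p <- sample.int(n)
        count <- count + (ss_stats(G[p, p])$f >= obs$f - 1e-12)
      }
    })
    pval <- (1 + count) / (1 + n_perm)
    n_perm_used <- n_perm
  }

  res <- tibble::tibble(term = labels, df = df_term, sum_of_squares = obs$ss,
                        r_squared = obs$ss / ss_total, pseudo_f = obs$f,
                        p_value = pval)
  structure(list(results = res, ss_total = ss_total, ss_residual = obs$ss_res,
                 df_residual = df_res, n = n, n_perm = n_perm_used,
                 formula = formula, exhaustive = exhaustive),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (marginal SS, %d permutations, n = %d)\n",
              x$n_perm, x$n))
  print(as.data.frame(x$results), row.names = FALSE)
  invisible(x)
}

#' Tidy a PERMANOVA fit
#'
#' @param x A [permanova()] object.
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `df`,
#'   `sum_of_squares`, `r_squared`, `pseudo_f`, `p_value`.
#' @export
tidy.permanova <- function(x, ...) x$results

#' One-row summary of a PERMANOVA fit
#'
#' @param x A [permanova()] object.
#' @param ... Unused.
#' @return Tibble with `n`, `df_residual`, `ss_total`, `ss_residual`,
#'   `r_squared_model`, `n_perm`.
#' @export
glance.permanova <- function(x, ...) {
  tibble::tibble(n = x$n, df_residual = x$df_residual,
                 ss_total = x$ss_total, ss_residual = x$ss_residual,
                 r_squared_model = 1 - x$ss_residual / x$ss_total,
                 n_perm = x$n_perm)
}
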