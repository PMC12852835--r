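test_that("genus agglomeration sums member ASVs and drops unassigned taxa", {
  m <- matrix(c(3, 4, 2,
                1, 0, 5), nrow = 2, byrow = TRUE)
  tb <- toy_table(m, taxonomy = c(t1 = "G", t2 = "G")) # t3 unassigned
  out <- agglomerate_to_genus(tb)
  expect_equal(colnames(out), "G")
  expect_equal(unname(unclass(out)[, "G"]), c(7L, 1L))

  # already at genus level: identity up to column order
  tb2 <- toy_table(m, taxonomy = c(t1 = "a", t2 = "b", t3 = "c"))
  out2 <- agglomerate_to_genus(tb2)
  expect_equal(matrix(as.integer(out2), nrow(out2)),
               matrix(as.integer(tb2), nrow(tb2)))
  expect_equal(unname(taxonomy_of(tb2)[colnames(tb2)]), colnames(out2))

  # 6 ASVs in 3 genera vs an independent group-by oracle
  set.seed(4)
  m3 <- matrix(rpois(30, 4), 5, 6)
  tax <- setNames(rep(c("gA", "gB", "gC"), each = 2), paste0("t", 1:6))
  tb3 <- toy_table(m3, taxonomy = tax)
  out3 <- agglomerate_to_genus(tb3)
  for (g in c("gA", "gB", "gC")) {
    members <- names(tax)[tax == g]
    expect_equal(unname(unclass(out3)[, g]),
                 unname(rowSums(m3[, match(members, colnames(tb3))])))
  }
  expect_error(agglomerate_to_genus(toy_table(m3)), "taxonomy")
})

test_that("global filter boundaries: >= 20% prevalence kept, 0.1% mean abundance strict", {
  # 10 samples; taxon A present in exactly 2 (20%) at high abundance
  m <- matrix(0L, 10, 3)
  m[, 1] <- 1000L                 # anchor taxon, always present
  m[1:2, 2] <- 500L               # prevalence exactly 0.20, abundant
  m[, 3] <- 1L                    # prevalent but rare
  tb <- toy_table(m)
  kept <- colnames(global_filter(tb))
  expect_true("t2" %in% kept)     # >= is inclusive

  # mean relative abundance exactly 0.1% must be dropped (strict "exceeds")
  m2 <- cbind(a = rep(999L, 10), b = rep(1L, 10))
  rownames(m2) <- paste0("s", 1:10)
  out2 <- global_filter(count_table(m2))
  expect_false("b" %in% colnames(out2))

  # hand-enumerated prevalence ladder 0.1..1.0 at high abundance
  m3 <- matrix(0L, 10, 10)
  for (j in 1:10) m3[seq_len(j), j] <- 100L
  keep3 <- colnames(global_filter(toy_table(m3)))
  expect_equal(keep3, paste0("t", 2:10)) # prevalence >= 0.2
})

test_that("zero-variance taxa are removed", {
  m <- cbind(z = rep(0L, 6), c = rep(7L, 6), v = c(1L, 2L, 1L, 2L, 1L, 2L))
  rownames(m) <- paste0("s", 1:6)
  out <- drop_zero_variance(count_table(m))
  expect_equal(colnames(out), "v")

  set.seed(9)
  m2 <- matrix(rpois(60, 2), 6, 10)
  m2[, 3] <- 5L
  out2 <- drop_zero_variance(toy_table(m2))
  expect_equal(colnames(out2),
               colnames(toy_table(m2))[apply(m2, 2, var) > 0])
})

test_that("within-group filter: 5% boundary kept, groups independent, oracle agreement", {
  m <- matrix(0L, 20, 2)
  m[, 1] <- 10L
  m[1, 2] <- 3L # present in 1 of 20 = 5%
  tb <- toy_table(m)
  strata <- setNames(rep("g1", 20), rownames(tb))
  out <- within_group_filter(tb, strata)
  expect_true("t2" %in% colnames(out$g1))

  # taxon absent in group A, present in B: removed only from A
  m2 <- rbind(matrix(c(5L, 0L), 4, 2, byrow = TRUE),
              matrix(c(5L, 5L), 4, 2, byrow = TRUE))
  tb2 <- toy_table(m2)
  strata2 <- setNames(rep(c("A", "B"), each = 4), rownames(tb2))
  out2 <- within_group_filter(tb2, strata2)
  expect_false("t2" %in% colnames(out2$A))
  expect_true("t2" %in% colnames(out2$B))

  # random strata vs brute-force per-group prevalence
  tb3 <- random_table(12, 8, seed = 11)
  strata3 <- setNames(rep(c("x", "y"), 6), rownames(tb3))
  out3 <- within_group_filter(tb3, strata3, min_prevalence = 0.3)
  for (g in c("x", "y")) {
    ids <- names(strata3)[strata3 == g]
    prev <- colMeans(unclass(tb3)[ids, ] > 0)
    expect_equal(colnames(out3[[g]]), names(prev)[prev >= 0.3])
  }
  expect_error(within_group_filter(tb3, setNames("x", rownames(tb3)[1])),
               "fewer than 2")
})

test_that("relative abundance and CLR transforms satisfy their contracts", {
  tb <- toy_table(matrix(c(2L, 2L, 4L), 1))
  expect_equal(unname(relative_abundance(tb)[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(relative_abundance(toy_table(matrix(5L, 3, 1)))[, 1]),
               rep(1, 3))

  tb2 <- random_table(8, 12, seed = 2)
  expect_true(all(abs(rowSums(relative_abundance(tb2)) - 1) < 1e-12))

  m0 <- unclass(tb2); m0[1, ] <- 0L
  expect_error(relative_abundance(toy_table(m0)), "s1")

  # CLR: equal counts -> zeros; rows centred; scale invariance
  expect_equal(unname(clr_transform(toy_table(matrix(7L, 2, 5)))),
               matrix(0, 2, 5))
  expect_true(all(abs(rowSums(clr_transform(tb2))) < 1e-10))
  m <- matrix(c(1L, 4L, 10L), 1)
  a <- clr_transform(toy_table(m), pseudocount = 1)
  b <- clr_transform(toy_table(3L * m), pseudocount = 3)
  expect_equal(a, b)
  expect_error(clr_transform(tb2, pseudocount = 0), "positive")
})

test_that("quantile splits follow ntile semantics with stable ties", {
  expect_equal(quantile_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(quantile_split(c(5, 5, 5, 5)), c("low", "low", "high", "high"))
  expect_equal(quantile_split(c(1, 2, 3)), c("low", "low", "high"))
  expect_error(quantile_split(c(1)), "fewer")
})

test_that("UN:C status uses a strict 3.5 threshold", {
  expect_equal(unc_status(c(3.6, 3.5, 0)), c("high", "low", "low"))
  expect_error(unc_status(-1), "non-negative")
})

test_that("filters are idempotent and the pipeline composition never adds taxa", {
  tb <- random_table(15, 25, lambda = 2, seed = 21)
  tax <- setNames(rep(paste0("g", 1:5), 5), colnames(tb))
  attr(tb, "taxonomy") <- tax

  f1 <- global_filter(tb)
  expect_equal(unclass(global_filter(f1)), unclass(f1))
  z1 <- drop_zero_variance(tb)
  expect_equal(unclass(drop_zero_variance(z1)), unclass(z1))

  steps <- list(agglomerate_to_genus, global_filter, drop_zero_variance)
  cur <- tb
  for (f in steps) {
    nxt <- f(cur)
    expect_lte(ncol(nxt), ncol(cur))
    cur <- nxt
  }
})
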