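test_that("simulated trees are deterministic rooted binaries with positive branches", {
  tr <- simulate_tree(10, seed = 1)
  expect_equal(length(tr$tip.label), 10L)
  expect_true(ape::is.rooted(tr) && ape::is.binary(tr))
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(10, seed = 1)))
  expect_error(simulate_tree(3), ">= 4")
})

test_that("tree total branch length equals Faith's PD of the full community", {
  tr <- simulate_tree(50, seed = 7)
  tb <- toy_table(matrix(1L, 1, 50, dimnames = list("s1", tr$tip.label)))
  expect_equal(faith_pd(tb, tr)$faith_pd, sum(tr$edge.length))
})

test_that("Brownian traits are deterministic, scale with sigma2, and track the tree", {
  tr <- simulate_tree(20, seed = 3)
  expect_identical(evolve_traits(tr, 1, seed = 5), evolve_traits(tr, 1, seed = 5))
  expect_true(all(abs(evolve_traits(tr, 1e-12, seed = 5)) < 1e-4))
  expect_error(evolve_traits(tr, 0), "> 0")

  # Pagel-style signal: patristic distance correlates positively with
  # squared trait differences over replicate realizations
  D <- ape::cophenetic.phylo(tr)
  up <- upper.tri(D)
  cors <- vapply(1:100, function(i) {
    x <- evolve_traits(tr, 1, seed = 1000 + i)[rownames(D)]
    cor(D[up], outer(x, x, function(a, b) (a - b)^2)[up])
  }, numeric(1))
  expect_gt(mean(cors), 0.2)
})

test_that("assembled communities have the contracted shape and depth distribution", {
  tr <- simulate_tree(30, seed = 2)
  trt <- evolve_traits(tr, 1, seed = 2)
  cfg <- sim_config(seed = 4, n_taxa = 30, n_samples = 12, depth_mean = 2000)
  ct <- assemble_communities(tr, trt, cfg)
  expect_s3_class(ct, "count_table")
  expect_equal(dim(ct), c(12L, 30L))
  expect_true(all(unclass(ct) >= 0))
  # depths around depth_mean (negative binomial, dispersion 10)
  expect_true(all(rowSums(ct) >= qnbinom(1e-5, mu = 2000, size = 10)))
  expect_true(all(rowSums(ct) <= qnbinom(1 - 1e-5, mu = 2000, size = 10)))
  # determinism
  expect_identical(unclass(ct), unclass(assemble_communities(tr, trt, cfg)))
  expect_error(sim_config(process = "magic"), "should be one of")
})

test_that("drift draws are independent across samples and strong selection fixes the winner", {
  tr <- simulate_tree(10, seed = 6)
  trt <- evolve_traits(tr, 1, seed = 6)
  ct <- assemble_communities(tr, trt,
    sim_config(seed = 8, n_taxa = 10, n_samples = 6, depth_mean = 1000))
  bc <- bray_curtis(ct)
  expect_true(all(bc[upper.tri(bc)] > 0))

  cfg <- sim_config(seed = 8, n_taxa = 10, n_samples = 6, depth_mean = 1000,
                    process = "homogeneous_selection",
                    selection_strength = 500, establishment_prob = 1)
  sel <- assemble_communities(tr, trt, cfg)
  tops <- apply(unclass(sel), 1, which.max)
  expect_equal(length(unique(tops)), 1L)
})

test_that("compositional simulator plants basis correlations and closes properly", {
  cfg0 <- sim_config(seed = 5, n_taxa = 20, n_samples = 300, depth_mean = 2000)
  ct0 <- simulate_compositional_counts(cfg0)
  lb <- attr(ct0, "log_basis")
  off <- cor(lb)[upper.tri(diag(20))]
  expect_lt(max(abs(off)), 0.2)
  expect_lt(abs(mean(off)), 0.05)

  R <- diag(20); R[1, 2] <- R[2, 1] <- 0.8
  cfg1 <- sim_config(seed = 5, n_taxa = 20, n_samples = 200,
                     depth_mean = 2000, basis_correlation = R)
  lb1 <- attr(simulate_compositional_counts(cfg1), "log_basis")
  expect_lt(abs(cor(lb1[, 1], lb1[, 2]) - 0.8), 0.05)

  # closure: at huge depth the observed fractions approach basis fractions
  cfg2 <- sim_config(seed = 9, n_taxa = 10, n_samples = 5, depth_mean = 1e6)
  ct2 <- simulate_compositional_counts(cfg2)
  basis_frac <- exp(attr(ct2, "log_basis"))
  basis_frac <- basis_frac / rowSums(basis_frac)
  expect_lt(max(abs(relative_abundance(ct2) - basis_frac)), 1e-2)

  bad <- matrix(0.99, 4, 4); diag(bad) <- 1; bad[1, 2] <- bad[2, 1] <- -0.99
  expect_error(sim_config(n_taxa = 4, basis_correlation = bad),
               "positive definite")
})

test_that("metadata generator is deterministic with independent margins when targeted", {
  md <- simulate_metadata(200, seed = 3)
  expect_identical(md, simulate_metadata(200, seed = 3))
  expect_true(all(md$fir >= 0 & md$fir <= 1))
  expect_true(all(md$ga_c > 0 & md$un_c > 0))
  expect_setequal(unique(md$region), c("east", "west"))

  md0 <- simulate_metadata(5000, targets = c(0, 0, 0), seed = 12)
  expect_lt(abs(cor(md0$fir, md0$ga_c)), 0.05)
  expect_lt(abs(cor(md0$fir, md0$un_c)), 0.05)
  expect_lt(abs(cor(md0$ga_c, md0$un_c)), 0.05)
})

test_that("count tables from all generators respect the count-table invariants", {
  tr <- simulate_tree(15, seed = 10)
  trt <- evolve_traits(tr, 1, seed = 10)
  for (p in c("drift", "homogenizing_dispersal", "dispersal_limitation",
              "homogeneous_selection", "variable_selection")) {
    ct <- assemble_communities(tr, trt,
      assembly_scenario(p, seed = 10, n_taxa = 15, n_samples = 6,
                        depth_mean = 500))
    expect_true(all(unclass(ct) >= 0))
    expect_true(is.integer(unclass(ct)))
  }
})
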