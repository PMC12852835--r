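test_that("SparCC output is a proper correlation matrix, invariant to sample order", {
  ct <- random_table(30, 8, lambda = 20, seed = 5)
  r <- sparcc(ct, seed = 3)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 8))
  expect_true(all(abs(r) <= 1))
  perm <- unclass(ct)[sample(nrow(ct)), ]
  expect_equal(sparcc(count_table(perm), seed = 3), r)
  expect_error(sparcc(random_table(10, 3, seed = 1)), ">= 4 taxa")
})

test_that("SparCC separates a planted pair from independent taxa", {
  R <- diag(12); R[1, 2] <- R[2, 1] <- 0.8
  ct <- simulate_compositional_counts(
    sim_config(seed = 6, n_taxa = 12, n_samples = 150, depth_mean = 3000,
               basis_correlation = R))
  est <- sparcc(ct, seed = 7)
  expect_gt(est[1, 2], 0.5)
  others <- abs(est[upper.tri(est)])
  others <- others[-1] # drop the planted pair (first upper-tri entry)
  expect_lt(median(others), 0.15)
})

test_that("bootstrap p-values are valid and detect the planted association", {
  R <- diag(20); R[1, 2] <- R[2, 1] <- 0.8
  ct <- simulate_compositional_counts(
    sim_config(seed = 8, n_taxa = 20, n_samples = 120, depth_mean = 3000,
               basis_correlation = R))
  obs <- sparcc(ct, seed = 2)
  bp <- bootstrap_pvalues(ct, obs, n_boot = 40, n_inner = 10, seed = 4)
  expect_true(all(bp$p > 0 & bp$p <= 1))
  expect_lt(bp$p_adj[1, 2], 0.05)
  expect_error(bootstrap_pvalues(ct, obs, n_boot = 10), ">= 20")
})

test_that("network construction applies both edge thresholds", {
  ids <- paste0("g", 1:5)
  corr <- diag(5); dimnames(corr) <- list(ids, ids)
  pv <- matrix(1, 5, 5, dimnames = list(ids, ids))
  expect_equal(nrow(build_network(corr, pv)$edges), 0L)

  corr["g1", "g2"] <- corr["g2", "g1"] <- -0.6
  pv["g1", "g2"] <- pv["g2", "g1"] <- 0.001
  net <- build_network(corr, pv)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$sign, "negative")

  set.seed(11)
  rc <- matrix(runif(100, -1, 1), 10); rc <- (rc + t(rc)) / 2; diag(rc) <- 1
  pp <- matrix(runif(100), 10); pp <- pmin(pp, t(pp)); diag(pp) <- 1
  dimnames(rc) <- dimnames(pp) <- list(paste0("x", 1:10), paste0("x", 1:10))
  net2 <- build_network(rc, pp, p_cut = 0.2, r_cut = 0.4)
  up <- which(upper.tri(rc), arr.ind = TRUE)
  manual <- sum(pp[up] < 0.2 & abs(rc[up]) >= 0.4)
  expect_equal(nrow(net2$edges), manual)
})

test_that("topology metrics match closed forms on symmetric graphs", {
  ids <- paste0("n", 1:5)
  mk_net <- function(pairs, ids) {
    corr <- diag(length(ids)); dimnames(corr) <- list(ids, ids)
    pv <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
    for (p in pairs) {
      corr[p[1], p[2]] <- corr[p[2], p[1]] <- 0.8
      pv[p[1], p[2]] <- pv[p[2], p[1]] <- 0.001
    }
    build_network(corr, pv)
  }
  # star K_{1,4}
  star <- mk_net(lapply(2:5, function(i) c("n1", paste0("n", i))), ids)
  ts <- topology(star)
  expect_equal(ts$nodes$eigenvector_centrality[ts$nodes$node == "n1"], 1)
  leaves <- ts$nodes$eigenvector_centrality[ts$nodes$node != "n1"]
  expect_true(all(abs(leaves - leaves[1]) < 1e-10))

  # complete K5: equal centralities, zero betweenness
  cmb <- combn(ids, 2)
  k5 <- mk_net(lapply(seq_len(ncol(cmb)), function(j) cmb[, j]), ids)
  tk <- topology(k5)
  expect_true(all(abs(tk$nodes$eigenvector_centrality - 1) < 1e-8))
  expect_true(all(tk$nodes$betweenness == 0))
})

test_that("fast-greedy clustering finds the exhaustive modularity optimum on two cliques", {
  ids <- paste0("v", 1:8)
  corr <- diag(8); dimnames(corr) <- list(ids, ids)
  pv <- matrix(1, 8, 8, dimnames = list(ids, ids))
  link <- function(a, b) {
    corr[a, b] <<- corr[b, a] <<- 1
    pv[a, b] <<- pv[b, a] <<- 0.001
  }
  for (i in 1:3) for (j in (i + 1):4) link(ids[i], ids[j])
  for (i in 5:7) for (j in (i + 1):8) link(ids[i], ids[j])
  link(ids[4], ids[5])
  net <- build_network(corr, pv)
  tp <- topology(net)
  expect_equal(tp$n_clusters, 2L)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = ids))
  expect_equal(tp$modularity_q, oracle_best_modularity(g), tolerance = 1e-10)
})

test_that("network comparison reports centralization and hub overlap correctly", {
  ids <- paste0("n", 1:5)
  mk <- function(pairs) {
    corr <- diag(5); dimnames(corr) <- list(ids, ids)
    pv <- matrix(1, 5, 5, dimnames = list(ids, ids))
    for (p in pairs) {
      corr[p[1], p[2]] <- corr[p[2], p[1]] <- 0.7
      pv[p[1], p[2]] <- pv[p[2], p[1]] <- 0.001
    }
    topology(build_network(corr, pv))
  }
  star <- mk(lapply(2:5, function(i) c("n1", paste0("n", i))))
  cmb <- combn(ids, 2)
  full <- mk(lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  cmp <- compare_networks(star, full)
  expect_equal(cmp$degree_centralization[1], 1)  # star maximizes Freeman
  expect_equal(cmp$degree_centralization[2], 0)
  same <- compare_networks(star, star)
  expect_equal(attr(same, "hub_jaccard"), 1)
  expect_equal(same$n_edges[1], same$n_edges[2])
  # field agreement with independent recomputation
  expect_equal(cmp$mean_degree[2], mean(full$nodes$degree))
  expect_equal(cmp$density[1], 4 / choose(5, 2))
})
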