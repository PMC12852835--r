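#' Build an association network from correlations and p-values
#'
#' An edge connects two taxa when the BH-adjusted p-value is below `p_cut`
#' *and* the correlation magnitude reaches `r_cut`; edges carry the signed
#' correlation.
#'
#' @param corr Symmetric correlation matrix (e.g. from [sparcc()]).
#' @param pvals Symmetric matrix of adjusted p-values conformable with
#'   `corr` (e.g. `bootstrap_pvalues()$p_adj`).
#' @param p_cut Significance threshold (strict).
#' @param r_cut Minimum correlation magnitude (inclusive).
#' @return A list of class `assoc_network`: `nodes` (character vector) and
#'   `edges` (tibble `node_a`, `node_b`, `r`, `p_adj`, `sign`).
#' @export
build_network <- function(corr, pvals, p_cut = 0.05, r_cut = 0.3) {
  if (!all(dim(corr) == dim(pvals))) abort("corr and pvals not conformable")
  ids <- colnames(corr)
  if (is.null(ids)) ids <- paste0("t", seq_len(ncol(corr)))
  up <- which(upper.tri(corr), arr.ind = TRUE)
  keep <- pvals[up] < p_cut & abs(corr[up]) >= r_cut
  edges <- tibble::tibble(node_a = ids[up[keep, 1L]],
                          node_b = ids[up[keep, 2L]],
                          r = corr[up][keep],
                          p_adj = pvals[up][keep],
                          sign = ifelse(corr[up][keep] >= 0,
                                        "positive", "negative"))
  structure(list(nodes = ids, edges = edges), class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("<assoc_network> %d nodes, %d edges (%d positive, %d negative)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative")))
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  igraph::E(g)$weight <- abs(net$edges$r)
  igraph::E(g)$r <- net$edges$r
  g
}

#' Topology of an association network
#'
#' Degree and betweenness on the unweighted skeleton, eigenvector
#' centrality on |r|-weighted adjacency (max-normalized), community
#' structure by fast-greedy modularity maximization on |r| weights, and
#' hubs as nodes at or above the `hub_quantile` of eigenvector centrality.
#'
#' @param net An [build_network()] result.
#' @param hub_quantile Empirical quantile of eigenvector centrality above
#'   which a node is called a hub.
#' @return A list of class `network_metrics`: `nodes` tibble (`node`,
#'   `degree`, `betweenness`, `eigenvector_centrality`, `cluster_id`,
#'   `hub`), plus `modularity_q`, `n_clusters`, `n_edges`, `density`.
#' @export
topology <- function(net, hub_quantile = 0.95) {
  g <- as_igraph(net)
  n <- length(net$nodes)
  if (nrow(net$edges) == 0L) {
    nodes <- tibble::tibble(node = net$nodes, degree = 0L, betweenness = 0,
                            eigenvector_centrality = 0,
                            cluster_id = seq_len(n), hub = FALSE)
    out <- list(nodes = nodes, modularity_q = NA_real_, n_clusters = n,
                n_edges = 0L, density = 0)
    class(out) <- "network_metrics"
    return(out)
  }
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA) # unweighted shortest paths
  ec <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  fg <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(fg)
  q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  hub_thr <- quantile(ec, hub_quantile, names = FALSE)
  nodes <- tibble::tibble(node = net$nodes,
                          degree = as.integer(deg),
                          betweenness = unname(btw),
                          eigenvector_centrality = unname(ec),
                          cluster_id = as.integer(memb),
                          hub = unname(ec) >= hub_thr & deg > 0L)
  out <- list(nodes = nodes, modularity_q = q,
              n_clusters = length(unique(memb)),
              n_edges = nrow(net$edges),
              density = nrow(net$edges) / (n * (n - 1) / 2))
  class(out) <- "network_metrics"
  out
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics> %d nodes, %d edges, Q = %.3f, %d clusters, %d hub(s)\n",
              nrow(x$nodes), x$n_edges, x$modularity_q, x$n_clusters,
              sum(x$nodes$hub)))
  invisible(x)
}

freeman_centralization <- function(deg) {
  n <- length(deg)
  if (n < 3L) return(NA_real_)
  sum(max(deg) - deg) / ((n - 1) * (n - 2))
}

#' Contrast the topology of two networks
#'
#' Compares edge count, density, mean degree, Freeman degree
#' centralization, modularity and hub sets (Jaccard overlap) between two
#' networks on a shared node universe (the intersection is used when the
#' universes differ).
#'
#' @param metrics_a,metrics_b [topology()] results.
#' @return A tibble with one row per network plus attributes
#'   `hub_jaccard` and `shared_nodes`.
#' @export
compare_networks <- function(metrics_a, metrics_b) {
  common <- intersect(metrics_a$nodes$node, metrics_b$nodes$node)
  if (!length(common)) abort("networks share no nodes")
  summ <- function(m, label) {
    nd <- m$nodes[m$nodes$node %in% common, ]
    tibble::tibble(network = label,
                   n_nodes = nrow(nd),
                   n_edges = m$n_edges,
                   density = m$density,
                   mean_degree = mean(nd$degree),
                   degree_centralization = freeman_centralization(nd$degree),
                   modularity_q = m$modularity_q,
                   n_hubs = sum(nd$hub))
  }
  out <- dplyr::bind_rows(summ(metrics_a, "a"), summ(metrics_b, "b"))
  ha <- metrics_a$nodes$node[metrics_a$nodes$hub]
  hb <- metrics_b$nodes$node[metrics_b$nodes$hub]
  jac <- if (length(union(ha, hb)) == 0L) 1
         else length(intersect(ha, hb)) / length(union(ha, hb))
  attr(out, "hub_jaccard") <- jac
  attr(out, "shared_nodes") <- common
  out
}
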