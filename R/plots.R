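process_palette <- c(variable_selection = "#2e7d32",
                     homogeneous_selection = "#ef6c00",
                     dispersal_limitation = "#6a1b9a",
                     homogenizing_dispersal = "#e91e8c",
                     drift_undominated = "#9e9e9e")

#' Stacked-bar plot of assembly-process fractions
#'
#' @param object An `assembly_summary` tibble from [summarize_assembly()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assembly_summary <- function(object, ...) {
  df <- dplyr::mutate(object,
                      process = factor(.data$process, names(process_palette)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$fraction,
                                   fill = .data$process)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = process_palette, drop = FALSE) +
    ggplot2::labs(x = NULL, y = "fraction of pairwise comparisons",
                  fill = "assembly process") +
    ggplot2::theme_minimal()
}

#' Node-metric plot for an association network
#'
#' Degree against eigenvector centrality, hubs highlighted, points coloured
#' by fast-greedy cluster.
#'
#' @param object A `network_metrics` object from [topology()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.network_metrics <- function(object, ...) {
  df <- object$nodes
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree,
                                   y = .data$eigenvector_centrality,
                                   colour = factor(.data$cluster_id),
                                   shape = .data$hub)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "degree", y = "eigenvector centrality",
                  colour = "cluster", shape = "hub",
                  subtitle = sprintf("Q = %.3f, %d clusters",
                                     object$modularity_q, object$n_clusters)) +
    ggplot2::theme_minimal()
}

#' Tidy pairwise assembly results
#'
#' @param x A `pairwise_assembly` tibble from [assembly_analysis()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.pairwise_assembly <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pairwise_assembly")
  out
}

#' Summarize pairwise assembly results in one row
#'
#' @param x A `pairwise_assembly` tibble.
#' @param ... Unused.
#' @return Tibble with pair counts and the modal process.
#' @export
glance.pairwise_assembly <- function(x, ...) {
  cls <- x$process[x$process != "unclassifiable"]
  tb <- table(factor(cls, process_levels))
  tibble::tibble(n_pairs = nrow(x),
                 n_classified = length(cls),
                 modal_process = if (length(cls)) names(which.max(tb))
                                 else NA_character_,
                 drift_fraction = if (length(cls))
                   unname(tb["drift_undominated"] / length(cls)) else NA_real_)
}
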