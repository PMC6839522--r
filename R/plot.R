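#' Plot a clade-support table
#'
#' Horizontal bars of bootstrap percentages with Bremer values printed at
#' the bar ends; clades ordered by bootstrap support.
#'
#' @param object an `mp_support_table` (the `supports` element of a
#'   [run_protocol()] bundle, or a [bremer_support()]/[bootstrap_support()]
#'   table given both columns).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mp_support_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$clade <- stats::reorder(df$clade, df$bootstrap_pct)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bootstrap_pct,
                                   y = .data$clade)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$bremer), "",
                     paste0("B=", .data$bremer))), hjust = -0.15, size = 3) +
    ggplot2::labs(x = "bootstrap support (%)", y = NULL,
                  title = "Clade supports") +
    ggplot2::xlim(0, 105) +
    ggplot2::theme_minimal()
}

#' Plot per-character fit
#'
#' Histogram of per-character consistency indices from a [fitch_length()]
#' result: homoplasy at a glance (ci = 1 means a character fits the tree
#' perfectly).
#'
#' @param object an `mp_fitch` object.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mp_fitch <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$steps > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ci)) +
    ggplot2::geom_histogram(binwidth = 0.1, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::labs(x = "per-character consistency index",
                  y = "characters",
                  title = sprintf("Character fit (tree length %d steps)",
                                  as.integer(object$total))) +
    ggplot2::theme_minimal()
}

#' Plot search progress of a tree pool
#'
#' Replicate-by-replicate best lengths from a replicated or driven search,
#' with the pooled best length marked.
#'
#' @param object an `mp_tree_pool`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mp_tree_pool <- function(object, ...) {
  rb <- object$diagnostics$rep_best
  if (is.null(rb)) stop("pool has no per-replicate diagnostics")
  df <- tibble::tibble(replicate = seq_along(rb), best_length = rb)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$replicate,
                                   y = .data$best_length)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$best_length,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "search replicate", y = "best length (steps)",
                  title = "Replicate best lengths") +
    ggplot2::theme_minimal()
}

#' Plot a consensus tree
#'
#' Thin convenience wrapper over [ape::plot.phylo] for the (reduced)
#' consensus with optional support labels.
#'
#' @param tree an [ape::phylo], e.g. from [strict_consensus()].
#' @param ... passed to [ape::plot.phylo].
#' @export
plot_consensus <- function(tree, ...) {
  ape::plot.phylo(tree, no.margin = TRUE, cex = 0.7, ...)
  invisible(tree)
}
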