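# Tidy, glance and autoplot methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a connectivity matrix into a long edge table
#'
#' @param x a [dcov_fc()].
#' @param ... unused.
#' @return tibble with columns `sink`, `source`, `value`, `method`.
#' @exportS3Method generics::tidy
#' @export
tidy.dcov_fc <- function(x, ...) {
  labels <- rownames(x)
  tibble::tibble(
    sink = rep(labels, times = length(labels)),
    source = rep(labels, each = length(labels)),
    value = as.numeric(fc_values(x)),
    method = fc_method(x))
}

#' Tidy an edge-significance result into a long table
#'
#' @param x an `edge_significance` object.
#' @param ... unused.
#' @return tibble with `sink`, `source`, `empirical`, `null_mean`,
#'   `null_sd`, `p`.
#' @exportS3Method generics::tidy
#' @export
tidy.edge_significance <- function(x, ...) {
  labels <- rownames(x$p_values)
  tibble::tibble(
    sink = rep(labels, times = length(labels)),
    source = rep(labels, each = length(labels)),
    empirical = as.numeric(fc_values(x$empirical)),
    null_mean = as.numeric(x$null_mean),
    null_sd = as.numeric(x$null_sd),
    p = as.numeric(x$p_values))
}

#' Tidy an ASCS curve
#'
#' @param x an `ascs_curve` object.
#' @param ... unused.
#' @return tibble with `method`, `threshold`, `n_edges`, `ascs`.
#' @exportS3Method generics::tidy
#' @export
tidy.ascs_curve <- function(x, ...) {
  tibble::tibble(
    method = vapply(x, `[[`, character(1), "method"),
    threshold = vapply(x, `[[`, numeric(1), "threshold"),
    n_edges = vapply(x, `[[`, numeric(1), "n_edges"),
    ascs = vapply(x, `[[`, numeric(1), "ascs"))
}

#' One-row summary of a topology report
#'
#' @param x a `topology_report`.
#' @param ... unused.
#' @return tibble with the scalar measures.
#' @exportS3Method generics::glance
#' @export
glance.topology_report <- function(x, ...) {
  tibble::tibble(
    directed = x$directed,
    n_nodes = length(x$out_degree),
    n_edges = sum(x$out_degree),
    global_efficiency = x$global_efficiency,
    local_efficiency = x$local_efficiency,
    clustering = x$clustering,
    transitivity = x$transitivity,
    modularity = x$modularity,
    n_modules = length(unique(x$partition)))
}

#' Heatmap of a connectivity matrix
#'
#' @param object a [dcov_fc()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dcov_fc <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("autoplot requires ggplot2")
  }
  df <- tidy(object)
  df$sink <- factor(df$sink, levels = rev(rownames(object)))
  df$source <- factor(df$source, levels = rownames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$sink,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(title = sprintf("%s connectivity", fc_method(object)),
                  x = "source", y = "sink", fill = "weight") +
    ggplot2::theme_minimal()
}

#' ASCS against binarization threshold
#'
#' @param object an `ascs_curve`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ascs_curve <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("autoplot requires ggplot2")
  }
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$ascs)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "binarization threshold (p)",
                  y = "average structural connectivity strength") +
    ggplot2::theme_minimal()
}

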