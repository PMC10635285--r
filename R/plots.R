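#' @importFrom rlang .data
NULL

#' Plot the first two embedding coordinates of a fit
#'
#' @param object a `tpca_fit` with `m >= 2`.
#' @param ... unused.
#' @return a ggplot object; points are colored by label when labels exist.
#' @export
autoplot.tpca_fit <- function(object, ...) {
  df <- tidy(object)
  if (!"PC2" %in% colnames(df)) {
    stop("autoplot needs at least 2 components", call. = FALSE)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(title = paste0(object$config$method, " embedding"),
                  x = "component 1", y = "component 2") +
    ggplot2::theme_minimal()
  if ("label" %in% colnames(df)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$label), size = 1)
  } else {
    p + ggplot2::geom_point(size = 1)
  }
}

#' Objective trace of a fit
#'
#' @param fit a `tpca_fit`.
#' @return a ggplot object showing the (non-increasing) objective by
#'   iteration.
#' @export
plot_objective_trace <- function(fit) {
  stopifnot(inherits(fit, "tpca_fit"))
  df <- tibble::tibble(iteration = seq_along(fit$objective_trace) - 1,
                       objective = fit$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "objective trace", y = "objective") +
    ggplot2::theme_minimal()
}

#' Residue-similarity plot
#'
#' Per-class panels of residue (x) versus similarity (y) scores, the
#' standard multiclass separation visualization.
#'
#' @param object an [rs_scores()] result.
#' @param ... unused.
#' @return a ggplot object faceted by class.
#' @export
autoplot.rs_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$similarity,
                                   color = .data$label)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "residue score R", y = "similarity score S") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Per-run clustering scores
#'
#' @param object a [cluster_eval()] report.
#' @param ... unused.
#' @return a ggplot object with ARI and NMI per clustering run.
#' @export
autoplot.cluster_eval_report <- function(object, ...) {
  df <- tidy(object)
  long <- rbind(
    data.frame(run = df$run, metric = "ARI", value = df$ari),
    data.frame(run = df$run, metric = "NMI", value = df$nmi))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$run, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = paste0(object$method, " clustering evaluation"),
                  y = "score") +
    ggplot2::theme_minimal()
}
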