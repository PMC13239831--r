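#' Tidy a fitted model's training history
#'
#' @param x An `mfcp_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (epoch, train_loss, val_loss,
#'   val_accuracy).
#' @export
tidy.mfcp_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x An `mfcp_fit`.
#' @param ... Unused.
#' @return Tibble with the pattern set, best epoch and test-set metrics.
#' @export
glance.mfcp_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(patterns = paste(x$patterns, collapse = "+"),
                   best_epoch = x$best_epoch),
    x$metrics)
}

#' Per-layer parameter inventory of a model
#'
#' @param x An `mfcp_model`.
#' @param ... Unused.
#' @return Tibble with one row per weight tensor: component, layer, rows,
#'   cols, n_parameters.
#' @export
tidy.mfcp_model <- function(x, ...) {
  flat <- .flatten_params(x)
  dplyr::bind_rows(lapply(names(flat), function(nm) {
    w <- flat[[nm]]
    d <- if (is.matrix(w)) dim(w) else c(length(w), 1L)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    tibble::tibble(component = parts[1L],
                   layer = paste(parts[-1L], collapse = "."),
                   rows = d[1L], cols = d[2L], n_parameters = prod(d))
  }))
}

#' Per-run metrics of a repeated-seed experiment
#'
#' @param x An `mfcp_runs`.
#' @param ... Unused.
#' @return Long tibble: rep, seed, metric, value.
#' @export
tidy.mfcp_runs <- function(x, ...) {
  tidyr::pivot_longer(x$runs[, c("rep", "seed", .metric_cols)],
                      dplyr::all_of(.metric_cols),
                      names_to = "metric")
}

#' Aggregate summary of a repeated-seed experiment
#'
#' @param x An `mfcp_runs`.
#' @param ... Unused.
#' @return Wide one-row tibble of metric means and sample sds.
#' @export
glance.mfcp_runs <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"),
                     names_glue = "{metric}_{.value}")
}

#' Per-fold metrics of a cross-validation
#'
#' @param x An `mfcp_cv`.
#' @param ... Unused.
#' @return Long tibble: fold, metric, value.
#' @export
tidy.mfcp_cv <- function(x, ...) {
  tidyr::pivot_longer(x$folds[, c("fold", .metric_cols)],
                      dplyr::all_of(.metric_cols), names_to = "metric")
}

#' Aggregate summary of a cross-validation
#'
#' @param x An `mfcp_cv`.
#' @param ... Unused.
#' @return Wide one-row tibble of metric means and sample sds across folds.
#' @export
glance.mfcp_cv <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"),
                     names_glue = "{metric}_{.value}")
}

#' Plot a training history
#'
#' Training loss, validation loss and validation accuracy per epoch, with
#' the checkpointed epoch marked.
#'
#' @param object An `mfcp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mfcp_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = paste("Training history:",
                                paste(object$patterns, collapse = "+")),
                  subtitle = "dashed line = checkpointed epoch") +
    ggplot2::theme_minimal()
}

#' Plot an ablation summary
#'
#' Mean test accuracy (+/- sample sd when several seeds were run) per
#' pattern subset.
#'
#' @param object An `mfcp_ablation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mfcp_ablation <- function(object, ...) {
  s <- dplyr::arrange(object$summary, .data$n_patterns, .data$patterns)
  s$patterns <- factor(s$patterns, levels = s$patterns)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$patterns,
                                       y = .data$accuracy_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "pattern subset", y = "mean test accuracy",
                  title = "Pattern-subset ablation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (any(is.finite(s$accuracy_sd))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$accuracy_mean - .data$accuracy_sd,
                   ymax = .data$accuracy_mean + .data$accuracy_sd),
      width = 0.2)
  }
  p
}

#' Plot a sensitivity sweep
#'
#' Test accuracy against the swept parameter (lambda or threshold);
#' degenerate rows (empty graphs) are dropped from the line and flagged in
#' the subtitle.
#'
#' @param object An `mfcp_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mfcp_sweep <- function(object, ...) {
  param <- attr(object, "param")
  df <- tibble::as_tibble(object)
  n_degen <- if ("degenerate" %in% names(df)) sum(df$degenerate) else 0L
  if (n_degen > 0L) df <- df[!df$degenerate, ]
  df <- dplyr::group_by(df, .data[[param]]) |>
    dplyr::summarise(accuracy = mean(.data$accuracy, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[param]], y = .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = param, y = "mean test accuracy",
                  title = paste("Sensitivity to", param),
                  subtitle = if (n_degen > 0L) {
                    paste(n_degen, "degenerate row(s) omitted")
                  } else NULL) +
    ggplot2::theme_minimal()
}

#' Plot an importance report
#'
#' Mean Grad-CAM score of each pattern's top-k ROIs.
#'
#' @param object An `mfcp_importance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mfcp_importance_report <- function(object, ...) {
  ggplot2::ggplot(object$top,
                  ggplot2::aes(x = stats::reorder(.data$roi_label,
                                                  .data$mean_score),
                               y = .data$mean_score)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$roi_label, yend = 0)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$pattern), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean normalized Grad-CAM score",
                  title = paste0("Top-", object$k, " ROIs per pattern")) +
    ggplot2::theme_minimal()
}
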