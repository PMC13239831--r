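# channel weights = node-averaged gradients; node score = rectified
# channel-weighted sum of features
.gradcam_scores <- function(H, g) {
  alpha <- colMeans(g)
  pmax(as.vector(H %*% alpha), 0)
}

#' Node-level Grad-CAM importance
#'
#' For each GCN branch, takes the node feature map H (n x 32) produced by
#' the branch's final graph convolution (before readout pooling), computes
#' the gradient of the target class's pre-softmax logit with respect to H
#' by exact differentiation of the network function (eval mode, dropout
#' off), averages the gradient over nodes to get one weight per feature
#' channel, and scores each ROI by the rectified channel-weighted sum of
#' its features. Scores are normalized within the subject by dividing by
#' their maximum, giving values in `[0, 1]`; an all-zero score vector
#' (everything rectified away, or a branch the head ignores) is returned
#' unnormalized with `degenerate = TRUE`.
#'
#' @param model An `mfcp_model` (or `mfcp_fit`).
#' @param graphs_subject One subject's named list of [pattern_graph()]s
#'   (an element of `mfcp_graphs$graphs`).
#' @param target_class `"case"` or `"control"`: whose logit is attributed.
#' @param subject_id Identifier carried into the result.
#' @param normalize Divide by the per-subject maximum (default TRUE).
#' @return A tibble with one row per branch x ROI: `subject_id`,
#'   `pattern`, `target_class`, `roi`, `roi_label`, `score`, `normalized`,
#'   `degenerate`.
#' @export
gradcam_node_importance <- function(model, graphs_subject,
                                    target_class = c("case", "control"),
                                    subject_id = "subject",
                                    normalize = TRUE) {
  if (inherits(model, "mfcp_fit")) model <- model$model
  stopifnot(inherits(model, "mfcp_model"))
  target_class <- match.arg(target_class)
  class_idx <- if (target_class == "case") 2L else 1L
  patterns <- model$config$patterns
  cg <- lapply(graphs_subject[patterns], function(g) {
    P <- propagation_operator(g$adjacency)
    list(P = P, PX = P %*% g$node_features)
  })
  fw <- .forward_compiled(model, cg)          # eval mode: no masks
  dscores <- c(0, 0)
  dscores[class_idx] <- 1                     # d(logit_c)/d(scores)
  bw <- .backward_compiled(model, cg, fw, dscores, want_dH2 = TRUE)

  rows <- lapply(patterns, function(p) {
    H <- fw$branch[[p]]$H2
    g <- bw$dH2[[p]]
    s <- .gradcam_scores(H, g)
    mx <- max(s)
    degenerate <- mx == 0
    norm_applied <- normalize && !degenerate
    if (norm_applied) s <- s / mx
    labels <- graphs_subject[[p]]$adjacency$roi_labels
    tibble::tibble(subject_id = subject_id, pattern = p,
                   target_class = target_class,
                   roi = seq_along(s), roi_label = labels, score = s,
                   normalized = norm_applied, degenerate = degenerate)
  })
  dplyr::bind_rows(rows)
}

#' Grad-CAM importance for many subjects
#'
#' @param model An `mfcp_model` or `mfcp_fit`.
#' @param graphs An `mfcp_graphs`.
#' @param indices Subject indices (default all).
#' @inheritParams gradcam_node_importance
#' @return Row-bound tibble of [gradcam_node_importance()] results.
#' @export
gradcam_cohort <- function(model, graphs, indices = NULL,
                           target_class = "case", normalize = TRUE) {
  stopifnot(inherits(graphs, "mfcp_graphs"))
  indices <- indices %||% seq_along(graphs$graphs)
  dplyr::bind_rows(lapply(indices, function(k) {
    gradcam_node_importance(model, graphs$graphs[[k]], target_class,
                            subject_id = graphs$subject_ids[k],
                            normalize = normalize)
  }))
}

#' Top-k ROIs by mean Grad-CAM importance
#'
#' Averages normalized scores across subjects (and, if the table pools
#' several fitted models, across runs) per pattern, and returns the k
#' highest-mean ROIs. Ties are broken by ROI index (lower index first).
#'
#' @param importance Tibble from [gradcam_cohort()] /
#'   [gradcam_node_importance()] (possibly row-bound across runs).
#' @param k Number of ROIs per pattern (default 5).
#' @return Tibble with `pattern`, `rank`, `roi`, `roi_label`,
#'   `mean_score`.
#' @export
top_k_rois <- function(importance, k = 5L) {
  if (nrow(importance) == 0L) stop("empty importance table")
  label_sets <- importance |>
    dplyr::group_by(.data$subject_id, .data$pattern) |>
    dplyr::summarise(key = paste(.data$roi_label[order(.data$roi)],
                                 collapse = "|"), .groups = "drop")
  if (length(unique(label_sets$key)) > 1L) {
    stop("inconsistent ROI labels across subjects")
  }
  importance |>
    dplyr::group_by(.data$pattern, .data$roi, .data$roi_label) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop") |>
    dplyr::group_by(.data$pattern) |>
    dplyr::arrange(dplyr::desc(.data$mean_score), .data$roi,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("pattern", "rank", "roi", "roi_label", "mean_score")
}

#' Per-pattern importance report with cross-pattern overlap
#'
#' Emits the per-pattern top-k listing (ROI label, rank, mean score) and a
#' pairwise overlap statistic: the number of ROIs shared between two
#' patterns' top-k sets, quantifying how much the discriminative regions
#' differ across connection patterns.
#'
#' @inheritParams top_k_rois
#' @return An `mfcp_importance_report`: list with tibbles `top` and
#'   `overlap` (`pattern_a`, `pattern_b`, `overlap`), and `k`.
#' @export
importance_report <- function(importance, k = 5L) {
  top <- top_k_rois(importance, k)
  pats <- unique(top$pattern)
  pairs <- if (length(pats) >= 2L) utils::combn(pats, 2L, simplify = FALSE)
           else list()
  overlap <- dplyr::bind_rows(lapply(pairs, function(pr) {
    a <- top$roi[top$pattern == pr[1L]]
    b <- top$roi[top$pattern == pr[2L]]
    tibble::tibble(pattern_a = pr[1L], pattern_b = pr[2L],
                   overlap = length(intersect(a, b)))
  }))
  structure(list(top = top, overlap = overlap, k = k),
            class = "mfcp_importance_report")
}

#' @export
print.mfcp_importance_report <- function(x, ...) {
  cat("<mfcp_importance_report> top-", x$k, " ROIs per pattern\n", sep = "")
  print(x$top)
  if (nrow(x$overlap) > 0L) {
    cat("pairwise top-", x$k, " overlap:\n", sep = "")
    print(x$overlap)
  }
  invisible(x)
}

#' Zero one ROI's node features across branches
#'
#' Utility for attribution faithfulness checks: returns the subject's
#' graphs with the given ROI's feature row set to zero (adjacency
#' untouched).
#'
#' @param graphs_subject Named list of [pattern_graph()]s.
#' @param roi ROI index to mask.
#' @return Modified list of pattern graphs.
#' @export
mask_roi_features <- function(graphs_subject, roi) {
  lapply(graphs_subject, function(g) {
    g$node_features[roi, ] <- 0
    g
  })
}
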