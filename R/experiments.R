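.metric_cols <- c("accuracy", "precision", "recall", "f1", "auc")

.pattern_subsets <- function() {
  subsets <- list()
  for (m in 1:7) {
    pick <- MFCP_PATTERNS[as.logical(bitwAnd(m, c(1L, 2L, 4L)))]
    subsets[[paste(pick, collapse = "+")]] <- pick
  }
  # order by size then canonical order: PC, SR, GCM, PC+SR, PC+GCM, SR+GCM, all
  subsets[order(vapply(subsets, length, integer(1)))]
}

#' Pattern-subset ablation study
#'
#' Trains and evaluates the identical architecture on each of the seven
#' non-empty subsets of \{PC, SR, GCM\}, under identical data splits and
#' seeds across subsets (the head input width adapts automatically:
#' 64/128/192 for 1/2/3 branches). With several seeds, each subset is run
#' once per seed and per-subset means are reported.
#'
#' @param graphs An `mfcp_graphs` containing all three patterns.
#' @param config A [train_config()].
#' @param seeds Integer vector of seeds (default: the config seed).
#' @return An `mfcp_ablation`: tibble `results` (one row per subset x
#'   seed) and `summary` (per-subset mean and sample sd of each metric).
#' @export
ablation_study <- function(graphs, config = train_config(),
                           seeds = config$seed) {
  stopifnot(inherits(graphs, "mfcp_graphs"))
  if (!all(MFCP_PATTERNS %in% graphs$patterns)) {
    stop("ablation requires all three patterns precomputed; have: ",
         paste(graphs$patterns, collapse = ", "))
  }
  subsets <- .pattern_subsets()
  rows <- list()
  for (s in seeds) {
    split <- stratified_split(graphs$labels, config$fractions, s)
    for (nm in names(subsets)) {
      cfg <- config
      cfg$seed <- s
      fit <- train_model(graphs, subsets[[nm]], cfg, split = split)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(patterns = nm, n_patterns = length(subsets[[nm]]),
                       seed = s,
                       head = paste0("[", 64L * length(subsets[[nm]]),
                                     ", 32, 16, 2]")),
        fit$metrics)
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$patterns, .data$n_patterns) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(.metric_cols),
                                   list(mean = ~mean(.x, na.rm = TRUE),
                                        sd = ~sd(.x, na.rm = TRUE))),
                     .groups = "drop") |>
    dplyr::arrange(.data$n_patterns, .data$patterns)
  structure(list(results = results, summary = summary, seeds = seeds),
            class = "mfcp_ablation")
}

#' @export
print.mfcp_ablation <- function(x, ...) {
  cat("<mfcp_ablation> 7 pattern subsets x", length(x$seeds),
      "seed(s) (mean +/- sample sd)\n")
  print(x$summary[, c("patterns", "accuracy_mean", "accuracy_sd", "auc_mean")])
  invisible(x)
}

#' Sensitivity sweep over the sparse-representation penalty
#'
#' Re-estimates the SR connectivity at each lambda on the grid, retrains
#' under the same fixed seed(s), and tabulates test metrics per grid
#' point. Patterns other than SR are estimated once and reused.
#'
#' @param cohort An `mfcp_cohort`.
#' @param grid Numeric vector of lambda values.
#' @param config A [train_config()].
#' @param patterns Branch subset to train (default `"SR"` only, the branch
#'   the penalty affects).
#' @param seeds Seeds; metrics are averaged over them per grid point.
#' @param lag_order,thresholds Passed to graph construction.
#' @return An `mfcp_sweep` tibble (one row per lambda x seed) with
#'   attribute `param = "lambda"`.
#' @export
sweep_lambda <- function(cohort, grid, config = train_config(),
                         patterns = "SR", seeds = config$seed,
                         lag_order = 1L, thresholds = default_thresholds()) {
  if (length(grid) == 0L) stop("lambda grid must be non-empty")
  patterns <- .check_patterns(patterns)
  other <- setdiff(patterns, "SR")
  raw_other <- if (length(other) > 0L) {
    estimate_raw_fcns(cohort, other, lag_order = lag_order)
  } else NULL
  rows <- list()
  for (lam in grid) {
    raw_sr <- if ("SR" %in% patterns) {
      estimate_raw_fcns(cohort, "SR", sr_cfg = sr_config(lambda = lam))
    } else NULL
    raw <- .merge_raw(raw_sr, raw_other, patterns)
    graphs <- graphs_from_raw(raw, thresholds, patterns)
    for (s in seeds) {
      cfg <- config
      cfg$seed <- s
      fit <- train_model(graphs, patterns, cfg)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(lambda = lam, seed = s), fit$metrics)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mfcp_sweep", class(out))
  attr(out, "param") <- "lambda"
  out
}

.merge_raw <- function(a, b, patterns) {
  src <- if (is.null(a)) b else a
  raw <- lapply(seq_along(src$raw), function(k) {
    c(if (!is.null(a)) a$raw[[k]] else NULL,
      if (!is.null(b)) b$raw[[k]] else NULL)
  })
  structure(list(raw = raw, labels = src$labels,
                 subject_ids = src$subject_ids, roi_labels = src$roi_labels,
                 patterns = patterns),
            class = "mfcp_raw_fcns")
}

#' Sensitivity sweep over the canonicalization threshold
#'
#' Raw estimates are computed once; each grid point re-canonicalizes the
#' chosen pattern's matrices at that threshold and retrains a
#' single-pattern model under fixed seed(s). A threshold that empties
#' every graph of the pattern is recorded as a degenerate row rather than
#' an error: metrics are NA (`degenerate = "invalid"`, default) or the
#' model is still trained on the empty graphs (`degenerate = "chance"`,
#' in which case the classifier can only use its biases and performs at
#' chance).
#'
#' @param cohort An `mfcp_cohort`.
#' @param pattern One of `"PC"`, `"SR"`, `"GCM"`.
#' @param grid Numeric thresholds in `[0, 1)`.
#' @param config A [train_config()].
#' @param seeds Seeds per grid point.
#' @param degenerate `"invalid"` or `"chance"` (see above).
#' @param sr_cfg,lag_order Estimator settings.
#' @param threshold_scale Passed to [canonicalize()]: `"rescaled"`
#'   (default) or `"raw"` magnitudes. Only the raw convention can empty
#'   graphs at thresholds below 1.
#' @return An `mfcp_sweep` tibble with columns threshold, seed, metrics
#'   and `degenerate` flag; attribute `param = "threshold"`.
#' @export
sweep_threshold <- function(cohort, pattern, grid, config = train_config(),
                            seeds = config$seed,
                            degenerate = c("invalid", "chance"),
                            sr_cfg = sr_config(), lag_order = 1L,
                            threshold_scale = "rescaled") {
  if (length(grid) == 0L) stop("threshold grid must be non-empty")
  pattern <- match.arg(pattern, MFCP_PATTERNS)
  degenerate <- match.arg(degenerate)
  raw <- estimate_raw_fcns(cohort, pattern, sr_cfg = sr_cfg,
                           lag_order = lag_order)
  rows <- list()
  for (th in grid) {
    thr <- stats::setNames(th, pattern)
    graphs <- graphs_from_raw(raw, thr, pattern, threshold_scale)
    empty <- vapply(graphs$graphs,
                    function(subj) max(subj[[pattern]]$adjacency$weights) == 0,
                    logical(1))
    all_empty <- all(empty)
    for (s in seeds) {
      if (all_empty && degenerate == "invalid") {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          threshold = th, seed = s,
          accuracy = NA_real_, precision = NA_real_, recall = NA_real_,
          f1 = NA_real_, auc = NA_real_,
          tp = NA_integer_, tn = NA_integer_, fp = NA_integer_,
          fn = NA_integer_, degenerate = TRUE)
        next
      }
      cfg <- config
      cfg$seed <- s
      fit <- train_model(graphs, pattern, cfg)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(threshold = th, seed = s), fit$metrics,
        tibble::tibble(degenerate = all_empty))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mfcp_sweep", class(out))
  attr(out, "param") <- "threshold"
  attr(out, "pattern") <- pattern
  out
}

#' Export fused graph embeddings per subject
#'
#' Runs the fitted model in eval mode and returns one row per subject:
#' id, label, and the fused `64 * n_branches` embedding (columns
#' `f001 ...`). Intended for external low-dimensional embedding or
#' plotting tools.
#'
#' @param model An `mfcp_model` (or `mfcp_fit`, whose model is used).
#' @param graphs An `mfcp_graphs`.
#' @return A tibble.
#' @export
export_embeddings <- function(model, graphs) {
  if (inherits(model, "mfcp_fit")) model <- model$model
  stopifnot(inherits(model, "mfcp_model"), inherits(graphs, "mfcp_graphs"))
  patterns <- model$config$patterns
  vecs <- t(vapply(graphs$graphs, function(subj) {
    cg <- lapply(subj[patterns], function(g) {
      P <- propagation_operator(g$adjacency)
      list(P = P, PX = P %*% g$node_features)
    })
    .forward_compiled(model, cg)$fused
  }, numeric(2L * model$config$conv_dim * length(patterns))))
  colnames(vecs) <- sprintf("f%03d", seq_len(ncol(vecs)))
  dplyr::bind_cols(
    tibble::tibble(subject_id = graphs$subject_ids, label = graphs$labels),
    tibble::as_tibble(vecs))
}

#' Write / read an embedding table losslessly
#'
#' Tab-delimited text with full floating precision (`%.17g`), so the round
#' trip reproduces the values bitwise.
#'
#' @param embeddings Tibble from [export_embeddings()].
#' @param path Output file.
#' @return `write_embeddings()` the path invisibly; `read_embeddings()`
#'   the tibble.
#' @export
write_embeddings <- function(embeddings, path) {
  num <- vapply(embeddings, is.numeric, logical(1)) &
    !(names(embeddings) %in% "label")
  out <- embeddings
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  # read numerics as text and convert with strtod so the %.17g round trip
  # is exact
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  num <- grepl("^f\\d+$", names(tbl))
  tbl[num] <- lapply(tbl[num], as.numeric)
  if ("label" %in% names(tbl)) tbl$label <- as.integer(tbl$label)
  tbl
}
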