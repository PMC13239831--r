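#' Connectivity matrix container
#'
#' An n x n weighted adjacency estimated under one connection pattern.
#' A *canonical* matrix is symmetric, entrywise non-negative, zero on the
#' diagonal, finite, and rescaled so its largest entry is 1 (unless all
#' zero); see [canonicalize()].
#'
#' @param weights Numeric n x n matrix.
#' @param pattern One of `"PC"`, `"SR"`, `"GCM"`.
#' @param canonical Logical flag.
#' @param roi_labels Length-n labels.
#' @param threshold_applied Threshold used during canonicalization, or NULL.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(weights, pattern, canonical = FALSE,
                                roi_labels = NULL, threshold_applied = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  pattern <- match.arg(pattern, MFCP_PATTERNS)
  if (!all(is.finite(weights))) stop("non-finite connectivity weights")
  if (is.null(roi_labels)) roi_labels <- paste0("ROI_", seq_len(ncol(weights)))
  structure(
    list(weights = unname(weights), pattern = pattern,
         canonical = isTRUE(canonical),
         threshold_applied = threshold_applied,
         roi_labels = as.character(roi_labels)),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix>", x$pattern, nrow(x$weights), "x", ncol(x$weights),
      if (x$canonical) "(canonical)" else "(raw)", "\n")
  invisible(x)
}

#' Pearson-correlation connectivity
#'
#' Edge weight between ROIs i and j is the Pearson correlation of their
#' time courses, i.e. the cosine of the mean-centred series. Zero-variance
#' ROIs get zero off-diagonal weights (with a warning naming the ROI)
#' rather than failing, so cohorts containing flat regressors still process.
#'
#' @param ts A [roi_time_series()].
#' @return A raw `connectivity_matrix` with pattern `"PC"`: symmetric,
#'   unit diagonal, entries in `[-1, 1]`.
#' @export
pearson_fcn <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  v <- ts$values
  sds <- apply(v, 2L, sd)
  w <- suppressWarnings(cor(v))
  if (any(sds == 0)) {
    flat <- which(sds == 0)
    warning("zero-variance ROI(s): ", paste(ts$roi_labels[flat], collapse = ", "),
            "; their off-diagonal weights set to 0")
    w[flat, ] <- 0
    w[, flat] <- 0
  }
  diag(w) <- 1
  connectivity_matrix(w, "PC", canonical = FALSE, roi_labels = ts$roi_labels)
}

#' Sparse-representation solver configuration
#'
#' @param lambda Non-negative L1 penalty (default 1).
#' @param max_iterations Maximum coordinate-descent sweeps per target ROI.
#' @param tolerance Convergence threshold on the per-sweep maximum
#'   coefficient change.
#' @return An `sr_config` object.
#' @export
sr_config <- function(lambda = 1, max_iterations = 500L, tolerance = 1e-8) {
  if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  if (tolerance <= 0) stop("tolerance must be positive")
  structure(list(lambda = lambda, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "sr_config")
}

#' Sparse-representation objective for one target ROI
#'
#' `||x_i - sum_{j != i} W_ij x_j||^2 + lambda * sum_{j != i} |W_ij|`,
#' the per-row objective minimised by [sparse_representation_fcn()].
#'
#' @param X t x n data matrix.
#' @param i Target ROI (column) index.
#' @param w Length-n coefficient vector with `w[i] == 0`.
#' @param lambda L1 penalty.
#' @return Scalar objective value.
#' @export
sr_objective <- function(X, i, w, lambda) {
  resid <- X[, i] - X %*% w
  sum(resid^2) + lambda * sum(abs(w[-i]))
}

.soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Cyclic coordinate descent for one lasso row.
# Minimises ||y - Z w||^2 + lambda ||w||_1 ; exact per-coordinate updates,
# so the objective is non-increasing at every step.
.sr_row <- function(G, c_vec, lambda, max_iter, tol) {
  p <- length(c_vec)
  w <- numeric(p)
  gd <- diag(G)
  objectives <- numeric(0)
  # objective up to the constant ||y||^2: w'Gw - 2 c'w + lambda||w||_1
  obj_part <- function(w) as.numeric(t(w) %*% G %*% w - 2 * sum(c_vec * w) +
                                       lambda * sum(abs(w)))
  converged <- FALSE
  it <- 0L
  Gw <- numeric(p)              # running G %*% w
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      if (gd[j] <= 0) next      # zero-variance regressor stays at 0
      r <- c_vec[j] - Gw[j] + gd[j] * w[j]
      w_new <- .soft_threshold(r, lambda / 2) / gd[j]
      d <- w_new - w[j]
      if (d != 0) {
        Gw <- Gw + G[, j] * d
        w[j] <- w_new
        delta_max <- max(delta_max, abs(d))
      }
    }
    objectives <- c(objectives, obj_part(w))
    if (delta_max < tol) { converged <- TRUE; break }
  }
  list(w = w, converged = converged, iterations = it, objectives = objectives)
}

#' Sparse-representation (L1-penalised regression) connectivity
#'
#' For each target ROI i, finds the coefficient row minimising
#' `||x_i - sum_{j != i} W_ij x_j||^2 + lambda * sum_{j != i} |W_ij|`
#' by cyclic coordinate descent with soft-thresholding. The resulting raw
#' matrix is asymmetric with a zero diagonal; conditional (partial-
#' correlation-like) dependence is captured because every other ROI
#' competes as a regressor.
#'
#' @param ts A [roi_time_series()].
#' @param config An [sr_config()].
#' @return A raw `connectivity_matrix` with pattern `"SR"`. Attributes
#'   `converged` (logical per row), `iterations` (integer per row) and
#'   `sweep_objectives` (list of per-sweep objective traces, constant
#'   offset `||x_i||^2` omitted) record solver diagnostics.
#' @export
sparse_representation_fcn <- function(ts, config = sr_config()) {
  stopifnot(inherits(ts, "roi_ts"), inherits(config, "sr_config"))
  X <- ts$values
  n <- ncol(X)
  G <- crossprod(X)
  W <- matrix(0, n, n)
  converged <- logical(n)
  iterations <- integer(n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    fit <- .sr_row(G[idx, idx, drop = FALSE], G[idx, i], config$lambda,
                   config$max_iterations, config$tolerance)
    W[i, idx] <- fit$w
    converged[i] <- fit$converged
    iterations[i] <- fit$iterations
    traces[[i]] <- fit$objectives
  }
  if (!all(converged)) {
    warning("sparse-representation solver did not converge for ",
            sum(!converged), " target ROI(s) within ",
            config$max_iterations, " sweeps")
  }
  out <- connectivity_matrix(W, "SR", canonical = FALSE,
                             roi_labels = ts$roi_labels)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iterations
  attr(out, "sweep_objectives") <- traces
  out
}

#' Pairwise Granger causality
#'
#' For every ordered ROI pair (x -> y), fits by least squares a restricted
#' autoregression of y on its own `lag_order` lags (plus intercept) and an
#' unrestricted model adding `lag_order` lags of x, both over the common
#' effective sample of `t - lag_order` points, and scores
#' `G(x -> y) = ln(RSS_restricted / RSS_unrestricted) >= 0`.
#'
#' @param ts A [roi_time_series()].
#' @param lag_order Positive integer model order (default 1).
#' @param rss_cap Value assigned when the unrestricted residual sum of
#'   squares underflows to zero (perfect fit), default `log(1e12)`.
#' @return A `directed_causality` object: `strengths` n x n matrix with
#'   entry `[i, j] = G(i -> j)` and zero diagonal, plus `lag_order` and
#'   `roi_labels`.
#' @export
granger_fcn <- function(ts, lag_order = 1L, rss_cap = log(1e12)) {
  stopifnot(inherits(ts, "roi_ts"))
  v <- ts$values
  t_len <- nrow(v)
  n <- ncol(v)
  p <- as.integer(lag_order)
  if (p < 1L) stop("lag_order must be >= 1")
  if (t_len <= 2L * p + 2L) {
    stop("need t > 2*lag_order + 2 (t = ", t_len, ", lag_order = ", p, ")")
  }
  rows <- (p + 1L):t_len
  Y <- v[rows, , drop = FALSE]
  # lag-k design blocks, shared across pairs
  lags <- lapply(seq_len(p), function(k) v[rows - k, , drop = FALSE])
  ones <- rep(1, length(rows))

  rss_fit <- function(Xd, y) {
    qr_x <- qr(Xd)
    if (qr_x$rank < ncol(Xd)) {
      # collinear design: ridge-stabilise the normal equations (jitter 1e-8)
      beta <- solve(crossprod(Xd) + diag(1e-8, ncol(Xd)), crossprod(Xd, y))
      sum((y - Xd %*% beta)^2)
    } else {
      sum(qr.resid(qr_x, y)^2)
    }
  }

  G <- matrix(0, n, n)
  flat <- which(apply(v, 2L, sd) == 0)
  if (length(flat) > 0L) {
    warning("zero-variance target ROI(s): ",
            paste(ts$roi_labels[flat], collapse = ", "),
            "; their causality entries set to 0")
  }
  capped <- FALSE
  rss_restricted <- numeric(n)
  designs_r <- vector("list", n)
  for (j in seq_len(n)) {
    if (j %in% flat) next
    Xr <- cbind(ones, do.call(cbind, lapply(lags, function(L) L[, j])))
    designs_r[[j]] <- Xr
    rss_restricted[j] <- rss_fit(Xr, Y[, j])
  }
  for (j in seq_len(n)) {
    if (j %in% flat) next
    for (i in seq_len(n)) {
      if (i == j) next
      Xu <- cbind(designs_r[[j]],
                  do.call(cbind, lapply(lags, function(L) L[, i])))
      rss_u <- rss_fit(Xu, Y[, j])
      if (rss_u < 1e-300) {
        G[i, j] <- rss_cap
        capped <- TRUE
      } else {
        G[i, j] <- max(log(rss_restricted[j] / rss_u), 0)
      }
    }
  }
  if (capped) warning("perfect unrestricted fit encountered; entries capped at ",
                      format(rss_cap))
  structure(list(strengths = G, lag_order = p, roi_labels = ts$roi_labels),
            class = "directed_causality")
}

#' @export
print.directed_causality <- function(x, ...) {
  cat("<directed_causality>", nrow(x$strengths), "ROIs, lag order",
      x$lag_order, "\n")
  invisible(x)
}

#' Symmetrize a directed causality matrix
#'
#' Aggregates bidirectional strengths into an undirected adjacency:
#' `A[i, j] = |G(i -> j) + G(j -> i)|` for i != j, zero diagonal.
#'
#' @param dc A `directed_causality` from [granger_fcn()].
#' @return A raw symmetric `connectivity_matrix` with pattern `"GCM"`.
#' @export
symmetrize_gcm <- function(dc) {
  stopifnot(inherits(dc, "directed_causality"))
  if (!all(is.finite(dc$strengths))) stop("non-finite causality strengths")
  A <- abs(dc$strengths + t(dc$strengths))
  diag(A) <- 0
  connectivity_matrix(A, "GCM", canonical = FALSE, roi_labels = dc$roi_labels)
}

#' Canonicalize a connectivity matrix
#'
#' Turns a raw estimate into a valid non-negative weighted adjacency:
#' (1) symmetrize by `(W + W')/2` if asymmetric; (2) absolute value;
#' (3) zero the diagonal; (4) rescale so the maximum entry is 1 (when the
#' maximum is positive); (5) zero every entry strictly below `threshold`,
#' keeping the surviving weights (weighted graph, not binarized).
#' Idempotent at a fixed threshold.
#'
#' With `threshold_scale = "raw"` the threshold is applied to the absolute
#' magnitudes *before* rescaling. This variant can empty a graph whose raw
#' weights are uniformly small — e.g. Granger log-RSS-ratio graphs collapse
#' entirely at moderate absolute thresholds — whereas under the default
#' rescaled convention the maximum entry (rescaled to 1) always survives
#' any threshold below 1.
#'
#' @param cm A `connectivity_matrix` (raw or canonical).
#' @param threshold Real in `[0, 1)`.
#' @param threshold_scale Apply the threshold to `"rescaled"` magnitudes
#'   (default) or to `"raw"` absolute magnitudes.
#' @return A canonical `connectivity_matrix`.
#' @export
canonicalize <- function(cm, threshold = 0,
                         threshold_scale = c("rescaled", "raw")) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  threshold_scale <- match.arg(threshold_scale)
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)")
  }
  W <- cm$weights
  W <- (W + t(W)) / 2
  W <- abs(W)
  diag(W) <- 0
  if (threshold_scale == "raw") W[W < threshold] <- 0
  mx <- max(W)
  if (mx > 0) W <- W / mx
  if (threshold_scale == "rescaled") W[W < threshold] <- 0
  if (max(W) == 0) {
    warning("all edges removed: ", cm$pattern,
            " graph is empty after thresholding at ", threshold)
  }
  connectivity_matrix(W, cm$pattern, canonical = TRUE,
                      roi_labels = cm$roi_labels,
                      threshold_applied = threshold)
}

#' Pattern graph: node features plus canonical adjacency
#'
#' The unit consumed by one GCN branch. Node features are each ROI's
#' connectivity profile, i.e. the rows of the canonical adjacency.
#'
#' @param adjacency A canonical `connectivity_matrix`.
#' @param node_features Optional n x f feature matrix; defaults to the
#'   adjacency rows.
#' @return A `pattern_graph` object.
#' @export
pattern_graph <- function(adjacency, node_features = NULL) {
  stopifnot(inherits(adjacency, "connectivity_matrix"))
  if (!adjacency$canonical) stop("adjacency must be canonical")
  if (is.null(node_features)) node_features <- adjacency$weights
  node_features <- as.matrix(node_features)
  if (nrow(node_features) != nrow(adjacency$weights)) {
    stop("feature rows (", nrow(node_features),
         ") must align with adjacency rows (", nrow(adjacency$weights), ")")
  }
  structure(list(node_features = node_features, adjacency = adjacency,
                 pattern = adjacency$pattern),
            class = "pattern_graph")
}

#' Default per-pattern canonicalization thresholds
#'
#' The package defaults are 0.1 for the correlation pattern and 0.2 for the
#' sparse-representation and Granger patterns, the values at which each
#' single-pattern classifier peaks in the sensitivity analysis.
#' @return Named numeric vector.
#' @export
default_thresholds <- function() c(PC = 0.1, SR = 0.2, GCM = 0.2)

# Raw (un-thresholded) estimates for one subject, per requested pattern.
.estimate_raw <- function(ts, patterns, sr_cfg, lag_order) {
  out <- list()
  if ("PC" %in% patterns) out$PC <- pearson_fcn(ts)
  if ("SR" %in% patterns) out$SR <- sparse_representation_fcn(ts, sr_cfg)
  if ("GCM" %in% patterns) out$GCM <- symmetrize_gcm(granger_fcn(ts, lag_order))
  out
}

#' Build the per-subject pattern graphs
#'
#' Runs each requested estimator, canonicalizes with that pattern's
#' threshold, and attaches each node's connectivity profile as its feature
#' vector. Patterns are always returned in the fixed order PC, SR, GCM.
#'
#' @param ts A [roi_time_series()].
#' @param patterns Non-empty subset of `c("PC", "SR", "GCM")`.
#' @param sr_cfg [sr_config()] for the SR estimator.
#' @param lag_order Granger lag order.
#' @param thresholds Named vector of per-pattern thresholds
#'   (default [default_thresholds()]).
#' @return Named list of [pattern_graph()] objects.
#' @export
build_pattern_graphs <- function(ts, patterns = MFCP_PATTERNS,
                                 sr_cfg = sr_config(), lag_order = 1L,
                                 thresholds = default_thresholds()) {
  patterns <- .check_patterns(patterns)
  raw <- .estimate_raw(ts, patterns, sr_cfg, lag_order)
  out <- lapply(patterns, function(p) {
    pattern_graph(canonicalize(raw[[p]], .threshold_for(thresholds, p)))
  })
  names(out) <- patterns
  out
}

.check_patterns <- function(patterns) {
  if (length(patterns) == 0L) stop("pattern set must be non-empty")
  patterns <- unique(match.arg(patterns, MFCP_PATTERNS, several.ok = TRUE))
  MFCP_PATTERNS[MFCP_PATTERNS %in% patterns]     # fixed branch order
}

.threshold_for <- function(thresholds, pattern) {
  if (!is.null(names(thresholds)) && pattern %in% names(thresholds)) {
    unname(thresholds[[pattern]])
  } else if (length(thresholds) == 1L) {
    unname(thresholds)
  } else {
    stop("no threshold given for pattern ", pattern)
  }
}

#' Estimate raw connectivity for a whole cohort
#'
#' Computes the un-thresholded estimates once per subject so threshold
#' sweeps can re-canonicalize cheaply.
#'
#' @param cohort An `mfcp_cohort`.
#' @inheritParams build_pattern_graphs
#' @return An `mfcp_raw_fcns` object (list of per-subject named lists of
#'   raw `connectivity_matrix`, plus labels and ids).
#' @export
estimate_raw_fcns <- function(cohort, patterns = MFCP_PATTERNS,
                              sr_cfg = sr_config(), lag_order = 1L) {
  stopifnot(inherits(cohort, "mfcp_cohort"))
  patterns <- .check_patterns(patterns)
  raw <- lapply(cohort$subjects, .estimate_raw, patterns = patterns,
                sr_cfg = sr_cfg, lag_order = lag_order)
  structure(list(raw = raw, labels = cohort$labels,
                 subject_ids = cohort$manifest$subject_id,
                 roi_labels = cohort$subjects[[1L]]$roi_labels,
                 patterns = patterns),
            class = "mfcp_raw_fcns")
}

#' Canonicalize cohort-level raw estimates into pattern graphs
#'
#' @param raw_fcns An `mfcp_raw_fcns` from [estimate_raw_fcns()].
#' @param thresholds Named per-pattern thresholds.
#' @param patterns Optional subset (defaults to all patterns present).
#' @param threshold_scale Passed to [canonicalize()].
#' @return An `mfcp_graphs` object: per-subject named lists of
#'   [pattern_graph()]s plus labels, ids and ROI labels.
#' @export
graphs_from_raw <- function(raw_fcns, thresholds = default_thresholds(),
                            patterns = NULL,
                            threshold_scale = "rescaled") {
  stopifnot(inherits(raw_fcns, "mfcp_raw_fcns"))
  patterns <- .check_patterns(patterns %||% raw_fcns$patterns)
  graphs <- lapply(raw_fcns$raw, function(subj) {
    gs <- lapply(patterns, function(p) {
      suppressWarnings(
        pattern_graph(canonicalize(subj[[p]], .threshold_for(thresholds, p),
                                   threshold_scale)))
    })
    names(gs) <- patterns
    gs
  })
  structure(list(graphs = graphs, labels = raw_fcns$labels,
                 subject_ids = raw_fcns$subject_ids,
                 roi_labels = raw_fcns$roi_labels, patterns = patterns,
                 thresholds = thresholds),
            class = "mfcp_graphs")
}

#' Build canonical pattern graphs for a whole cohort
#'
#' Convenience wrapper: [estimate_raw_fcns()] followed by
#' [graphs_from_raw()].
#'
#' @inheritParams estimate_raw_fcns
#' @inheritParams graphs_from_raw
#' @return An `mfcp_graphs` object.
#' @export
build_cohort_graphs <- function(cohort, patterns = MFCP_PATTERNS,
                                sr_cfg = sr_config(), lag_order = 1L,
                                thresholds = default_thresholds()) {
  graphs_from_raw(estimate_raw_fcns(cohort, patterns, sr_cfg, lag_order),
                  thresholds = thresholds, patterns = patterns)
}

#' @export
print.mfcp_graphs <- function(x, ...) {
  cat("<mfcp_graphs>", length(x$graphs), "subjects, patterns:",
      paste(x$patterns, collapse = ", "), "\n")
  invisible(x)
}
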