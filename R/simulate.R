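#' ROI time-series container
#'
#' Holds one subject's multivariate BOLD-like recording: a numeric matrix
#' with time points in rows and regions of interest (ROIs) in columns.
#'
#' @param values Numeric t x n matrix (time points x ROIs), all finite,
#'   with t >= 3 and n >= 2.
#' @param roi_labels Character vector of length n. Defaults to
#'   `ROI_1 ... ROI_n`.
#' @param subject_id Single string identifying the subject.
#'
#' @return An object of class `roi_ts` with fields `values`, `roi_labels`
#'   and `subject_id`.
#' @export
roi_time_series <- function(values, roi_labels = NULL, subject_id = "subject") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (nrow(values) < 3L) stop("need at least 3 time points, got ", nrow(values))
  if (ncol(values) < 2L) stop("need at least 2 ROIs, got ", ncol(values))
  if (!all(is.finite(values))) {
    stop("non-finite entries in time series for subject '", subject_id, "' (",
         sum(!is.finite(values)), " cells)")
  }
  if (is.null(roi_labels)) roi_labels <- paste0("ROI_", seq_len(ncol(values)))
  if (length(roi_labels) != ncol(values)) {
    stop("roi_labels length ", length(roi_labels), " != n ROIs ", ncol(values))
  }
  structure(
    list(values = unname(values), roi_labels = as.character(roi_labels),
         subject_id = as.character(subject_id)),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat("<roi_ts> subject", x$subject_id, ":", nrow(x$values), "time points x",
      ncol(x$values), "ROIs\n")
  invisible(x)
}

#' Simulation configuration for two-group VAR(1) cohorts
#'
#' Defines a stationary first-order vector autoregressive generative model
#' per group. Each subject's series follows
#' `x_t = A_g x_{t-1} + e_t`, `e_t ~ N(0, Sigma_g)`, where the lag matrix
#' `A_g` (entry `[i, j]` = influence of ROI j at time t-1 on ROI i at time t)
#' and the innovation covariance `Sigma_g` are group-specific. Groups can
#' therefore differ both in directed lagged influence (recoverable by
#' Granger causality) and in contemporaneous covariance (recoverable by
#' correlation-type estimators).
#'
#' @param n_subjects_per_group Subjects per group.
#' @param n_rois Number of ROIs (default 116, a whole-brain parcellation).
#' @param n_timepoints Time points retained per subject (default 232).
#'   Must be >= 10; t < n is allowed.
#' @param lag_control,lag_case n x n lag-coefficient matrices; spectral
#'   radius must be < 1 (stationarity).
#' @param cov_control,cov_case n x n symmetric positive definite innovation
#'   covariances.
#' @param noise_sd Positive scalar multiplying the innovation scale.
#' @param affected_rois Integer indices of ROIs whose coupling differs
#'   between groups (bookkeeping for planted-effect experiments).
#' @param seed Integer root seed; all randomness of [simulate_cohort()]
#'   flows from it.
#' @param burn_in Burn-in steps discarded before recording (>= 100).
#'
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_subjects_per_group,
                              n_rois = 116L,
                              n_timepoints = 232L,
                              lag_control = NULL,
                              lag_case = NULL,
                              cov_control = NULL,
                              cov_case = NULL,
                              noise_sd = 1,
                              affected_rois = integer(),
                              seed = 1L,
                              burn_in = 200L) {
  n <- as.integer(n_rois)
  if (n < 2L) stop("n_rois must be >= 2")
  if (n_timepoints < 10L) stop("n_timepoints must be >= 10")
  if (n_subjects_per_group < 1L) stop("need at least one subject per group")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be positive")
  if (burn_in < 100L) stop("burn_in must be >= 100")

  if (is.null(lag_control)) lag_control <- matrix(0, n, n)
  if (is.null(lag_case)) lag_case <- lag_control
  if (is.null(cov_control)) cov_control <- diag(n)
  if (is.null(cov_case)) cov_case <- cov_control

  for (g in c("control", "case")) {
    A <- if (g == "control") lag_control else lag_case
    S <- if (g == "control") cov_control else cov_case
    if (!all(dim(A) == c(n, n))) stop("lag_", g, " must be ", n, "x", n)
    if (!all(dim(S) == c(n, n))) stop("cov_", g, " must be ", n, "x", n)
    rho <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rho >= 1) {
      stop("lag matrix for group '", g, "' is non-stationary: spectral radius ",
           format(rho, digits = 6), " >= 1")
    }
    if (max(abs(S - t(S))) > 1e-8) stop("cov_", g, " is not symmetric")
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok) stop("cov_", g, " is not positive definite")
  }
  structure(
    list(n_subjects_per_group = as.integer(n_subjects_per_group),
         n_rois = n, n_timepoints = as.integer(n_timepoints),
         lag_control = lag_control, lag_case = lag_case,
         cov_control = cov_control, cov_case = cov_case,
         noise_sd = noise_sd,
         affected_rois = as.integer(affected_rois),
         seed = as.integer(seed), burn_in = as.integer(burn_in)),
    class = "simulation_config"
  )
}

#' Strong-effect two-group demo configuration
#'
#' Convenience constructor for the package's reference synthetic study: a
#' control group with independent self-lagged ROIs and a case group that
#' additionally carries (i) directed lag coupling between consecutive pairs
#' of the affected ROIs and (ii) equicorrelated contemporaneous innovations
#' among the affected ROIs. Under these conditions all three connectivity
#' patterns (correlation, sparse regression, Granger) carry group signal.
#'
#' @param n_rois Number of ROIs (default 20, the desk-scale study size).
#' @param n_subjects_per_group Default 30.
#' @param n_timepoints Default 232.
#' @param lag_strength Directed coupling added in the case group between
#'   affected ROI pairs (default 0.45).
#' @param cov_strength Contemporaneous correlation among affected ROIs in
#'   the case group (default 0.5).
#' @param n_affected Number of affected ROIs (default 6; the first
#'   `n_affected` indices).
#' @param self_lag Common AR(1) self-dependence in both groups (default 0.3).
#' @param noise_sd Innovation scale (default 1).
#' @param seed Root seed.
#' @param effect_scale Multiplier in `[0, 1]` applied to both
#'   `lag_strength` and `cov_strength`, for effect-size gradations.
#'
#' @return A [simulation_config()] object.
#' @export
mfcp_demo_config <- function(n_rois = 20L,
                             n_subjects_per_group = 30L,
                             n_timepoints = 232L,
                             lag_strength = 0.45,
                             cov_strength = 0.5,
                             n_affected = 6L,
                             self_lag = 0.3,
                             noise_sd = 1,
                             seed = 1L,
                             effect_scale = 1) {
  n <- as.integer(n_rois)
  n_affected <- min(as.integer(n_affected), n)
  affected <- seq_len(n_affected)
  lag_strength <- lag_strength * effect_scale
  cov_strength <- cov_strength * effect_scale

  lag_control <- diag(self_lag, n)
  lag_case <- lag_control
  if (n_affected >= 2L) {
    for (a in seq(1L, n_affected - 1L, by = 2L)) {
      # ROI affected[a] drives affected[a + 1] one step later
      lag_case[affected[a + 1L], affected[a]] <- lag_strength
    }
  }
  cov_control <- diag(n)
  cov_case <- diag(n)
  if (n_affected >= 2L) {
    cov_case[affected, affected] <- cov_strength
    diag(cov_case) <- 1
  }
  simulation_config(
    n_subjects_per_group = n_subjects_per_group, n_rois = n,
    n_timepoints = n_timepoints,
    lag_control = lag_control, lag_case = lag_case,
    cov_control = cov_control * noise_sd^2, cov_case = cov_case * noise_sd^2,
    noise_sd = noise_sd, affected_rois = affected, seed = seed
  )
}

# One stationary VAR(1) draw; innovations pre-generated for determinism.
.simulate_var1 <- function(A, chol_sigma, t_keep, burn_in) {
  n <- ncol(A)
  steps <- burn_in + t_keep
  eps <- matrix(rnorm(steps * n), steps, n) %*% chol_sigma
  x <- matrix(0, steps, n)
  x[1L, ] <- eps[1L, ]
  for (s in 2L:steps) x[s, ] <- as.vector(A %*% x[s - 1L, ]) + eps[s, ]
  x[(burn_in + 1L):steps, , drop = FALSE]
}

.zscore_cols <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  sdv[sdv == 0] <- 1          # flat column stays flat at zero
  sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
}

#' Simulate a two-group cohort of ROI time series
#'
#' Draws `n_subjects_per_group` independent subjects per group from the
#' group's stationary VAR(1) process, discards the burn-in, and z-scores
#' each subject's columns. Deterministic given `config$seed`: per-subject
#' seeds are derived from the root seed, so the draw for subject k does not
#' depend on how many subjects precede it being consumed elsewhere.
#'
#' @param config A [simulation_config()].
#' @return An `mfcp_cohort`: list with `subjects` (list of [roi_time_series()]),
#'   `labels` (integer, 1 = case, 0 = control) and a tibble `manifest`
#'   with columns `subject_id`, `label`, `group`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$n_subjects_per_group
  n <- config$n_rois
  roi_labels <- paste0("ROI_", seq_len(n))
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, 2L * m)

  chol_ctrl <- chol(config$cov_control)
  chol_case <- chol(config$cov_case)

  subjects <- vector("list", 2L * m)
  labels <- integer(2L * m)
  ids <- character(2L * m)
  for (k in seq_len(2L * m)) {
    is_case <- k > m
    set.seed(subject_seeds[k])
    x <- .simulate_var1(
      A = if (is_case) config$lag_case else config$lag_control,
      chol_sigma = if (is_case) chol_case else chol_ctrl,
      t_keep = config$n_timepoints, burn_in = config$burn_in
    )
    x <- .zscore_cols(x)
    id <- sprintf("%s_%03d", if (is_case) "case" else "ctrl",
                  if (is_case) k - m else k)
    subjects[[k]] <- roi_time_series(x, roi_labels, id)
    labels[k] <- as.integer(is_case)
    ids[k] <- id
  }
  structure(
    list(subjects = subjects, labels = labels,
         manifest = tibble::tibble(
           subject_id = ids, label = labels,
           group = ifelse(labels == 1L, "case", "control"))),
    class = "mfcp_cohort"
  )
}

#' @export
print.mfcp_cohort <- function(x, ...) {
  d <- dim(x$subjects[[1L]]$values)
  cat("<mfcp_cohort>", length(x$subjects), "subjects (",
      sum(x$labels == 1L), "case /", sum(x$labels == 0L), "control ),",
      d[1L], "x", d[2L], "each\n")
  invisible(x)
}

# full-precision numeric text: %.17g round-trips IEEE doubles exactly
.write_matrix_txt <- function(x, path) {
  lines <- apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
}

.read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE, sep = "\t",
                              colClasses = "numeric"))
}

#' Write / read a cohort as delimited text
#'
#' One tab-delimited file per subject (t rows x n columns, no header), a
#' `manifest.tsv` with columns `subject_id`, `label`, `file`, and a
#' `roi_labels.txt`. The round trip is lossless to full floating precision.
#'
#' @param cohort An `mfcp_cohort`.
#' @param directory Output directory (created if needed).
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns an `mfcp_cohort`.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "mfcp_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(cohort$manifest$subject_id, ".tsv")
  for (k in seq_along(cohort$subjects)) {
    .write_matrix_txt(cohort$subjects[[k]]$values, file.path(directory, files[k]))
  }
  writeLines(cohort$subjects[[1L]]$roi_labels,
             file.path(directory, "roi_labels.txt"))
  manifest <- dplyr::mutate(cohort$manifest[, c("subject_id", "label")],
                            file = files)
  manifest_path <- file.path(directory, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path)
  invisible(manifest_path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  manifest_path <- file.path(directory, "manifest.tsv")
  if (!file.exists(manifest_path)) stop("no manifest.tsv in ", directory)
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  need <- c("subject_id", "label", "file")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  bad_labels <- setdiff(unique(manifest$label), c(0L, 1L))
  if (length(bad_labels) > 0L) {
    stop("labels must be 0/1; found extra value(s): ",
         paste(bad_labels, collapse = ", "))
  }
  paths <- file.path(directory, manifest$file)
  missing <- manifest$file[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("manifest references missing file(s): ", paste(missing, collapse = ", "))
  }
  roi_path <- file.path(directory, "roi_labels.txt")
  roi_labels <- if (file.exists(roi_path)) readLines(roi_path) else NULL
  mats <- lapply(paths, .read_matrix_txt)
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) > 1L) {
    ref <- names(which.max(table(dims)))
    off <- manifest$file[dims != ref]
    stop("subject matrices differ in shape; offending file(s): ",
         paste(off, collapse = ", "))
  }
  subjects <- purrr::map2(mats, manifest$subject_id,
                          ~ roi_time_series(.x, roi_labels, .y))
  structure(
    list(subjects = subjects, labels = as.integer(manifest$label),
         manifest = tibble::tibble(
           subject_id = manifest$subject_id,
           label = as.integer(manifest$label),
           group = ifelse(manifest$label == 1L, "case", "control"))),
    class = "mfcp_cohort"
  )
}
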