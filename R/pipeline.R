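.default_pipeline_config <- function() {
  list(
    simulator = list(
      n_rois = 20L, n_subjects_per_group = 30L, n_timepoints = 232L,
      lag_strength = 0.45, cov_strength = 0.5, n_affected = 6L,
      self_lag = 0.3, noise_sd = 1, effect_scale = 1, seed = 1L
    ),
    fcn = list(
      patterns = c("PC", "SR", "GCM"),
      lambda = 1, sr_max_iterations = 500L, sr_tolerance = 1e-8,
      lag_order = 1L,
      threshold_pc = 0.1, threshold_sr = 0.2, threshold_gcm = 0.2
    ),
    model = list(conv_dim = 32L, dropout = 0.5),
    training = list(
      learning_rate = 0.0025, weight_decay = 1e-5, epochs = 150L,
      dropout = 0.5, seed = 1L,
      train_frac = 0.7, val_frac = 0.1, test_frac = 0.2,
      run_ablation = TRUE
    ),
    interpretation = list(target_class = "case", top_k = 5L)
  )
}

#' Pipeline configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()], merging
#' user overrides into the package defaults. Unknown keys at any level are
#' rejected. The resolved configuration records, per leaf, whether the
#' value is a package default or user-supplied; [write_pipeline_config()]
#' emits it (with those annotations) as YAML and
#' [read_pipeline_config()] ingests such a file back.
#'
#' @param ... Named sections (`simulator`, `fcn`, `model`, `training`,
#'   `interpretation`), each a named list of overrides.
#' @return A `pipeline_config`: the merged nested list, with a `provenance`
#'   attribute marking each leaf `"default"` or `"user"`.
#' @export
pipeline_config <- function(...) {
  defaults <- .default_pipeline_config()
  overrides <- list(...)
  if (length(overrides) > 0L &&
      (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop("all arguments must be named sections")
  }
  bad_sections <- setdiff(names(overrides), names(defaults))
  if (length(bad_sections) > 0L) {
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  }
  cfg <- defaults
  prov <- lapply(defaults, function(sec) {
    stats::setNames(rep("default", length(sec)), names(sec))
  })
  for (sec in names(overrides)) {
    o <- overrides[[sec]]
    bad <- setdiff(names(o), names(defaults[[sec]]))
    if (length(bad) > 0L) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
    for (key in names(o)) {
      cfg[[sec]][[key]] <- o[[key]]
      prov[[sec]][[key]] <- "user"
    }
  }
  structure(cfg, provenance = prov, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  payload <- unclass(config)
  attr(payload, "provenance") <- NULL
  yaml::write_yaml(list(config = payload,
                        provenance = attr(config, "provenance")), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sections <- if (!is.null(raw$config)) raw$config else raw
  do.call(pipeline_config, sections)
}

.config_hash <- function(config) {
  payload <- unclass(config)
  attr(payload, "provenance") <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(payload, tmp)
  unname(tools::md5sum(tmp))
}

.pipeline_stages <- c("simulate", "build-fcn", "train", "evaluate", "explain")

#' Run the end-to-end pipeline
#'
#' Composes the package stages on disk: `simulate` (write a synthetic
#' cohort), `build-fcn` (estimate and canonicalize the pattern graphs),
#' `train` (fit the multi-branch GCN and checkpoint it), `evaluate`
#' (test-set metrics as JSON, plus the pattern-subset ablation table when
#' `training$run_ablation` is TRUE) and `explain` (Grad-CAM importance
#' table). Stages run in that fixed order; each one reads its
#' predecessor's on-disk outputs, so the requested set must be
#' prefix-closed with respect to what already exists in `out_dir` — a
#' stage whose inputs are missing fails naming the stage to run first. A `run_manifest.json` records the
#' config hash, seed, package version and per-stage timings. Rerunning
#' with identical config and seed reproduces the metrics bitwise.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory (created if needed).
#' @param stages Subset of
#'   `c("simulate", "build-fcn", "train", "evaluate", "explain")`.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = .pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(expr) system.time(expr)[["elapsed"]]

  cohort_dir <- file.path(out_dir, "cohort")
  graphs_path <- file.path(out_dir, "graphs.rds")
  ckpt_path <- file.path(out_dir, "model.rds")

  sim <- config$simulator
  fcn <- config$fcn
  trn <- config$training

  if ("simulate" %in% stages) {
    timings$simulate <- clock({
      cohort <- simulate_cohort(mfcp_demo_config(
        n_rois = sim$n_rois, n_subjects_per_group = sim$n_subjects_per_group,
        n_timepoints = sim$n_timepoints, lag_strength = sim$lag_strength,
        cov_strength = sim$cov_strength, n_affected = sim$n_affected,
        self_lag = sim$self_lag, noise_sd = sim$noise_sd,
        effect_scale = sim$effect_scale, seed = sim$seed))
      write_cohort(cohort, cohort_dir)
    })
  }

  if ("build-fcn" %in% stages) {
    if (!file.exists(file.path(cohort_dir, "manifest.tsv"))) {
      stop("no cohort found in ", cohort_dir, "; run stage 'simulate' first")
    }
    timings$`build-fcn` <- clock({
      cohort <- read_cohort(cohort_dir)
      thresholds <- c(PC = fcn$threshold_pc, SR = fcn$threshold_sr,
                      GCM = fcn$threshold_gcm)
      graphs <- build_cohort_graphs(
        cohort, patterns = fcn$patterns,
        sr_cfg = sr_config(fcn$lambda, fcn$sr_max_iterations,
                           fcn$sr_tolerance),
        lag_order = fcn$lag_order, thresholds = thresholds)
      saveRDS(graphs, graphs_path)
      adj_dir <- file.path(out_dir, "adjacency")
      dir.create(adj_dir, showWarnings = FALSE)
      for (k in seq_along(graphs$graphs)) {
        for (p in graphs$patterns) {
          w <- graphs$graphs[[k]][[p]]$adjacency$weights
          dimnames(w) <- list(graphs$roi_labels, graphs$roi_labels)
          utils::write.table(
            format(w, digits = 17, trim = TRUE, scientific = TRUE),
            file.path(adj_dir, paste0(graphs$subject_ids[k], "_", p, ".tsv")),
            sep = "\t", quote = FALSE, col.names = NA)
        }
      }
    })
  }

  train_cfg <- train_config(
    learning_rate = trn$learning_rate, weight_decay = trn$weight_decay,
    epochs = trn$epochs, dropout = trn$dropout, seed = trn$seed,
    train_frac = trn$train_frac, val_frac = trn$val_frac,
    test_frac = trn$test_frac)

  if ("train" %in% stages) {
    if (!file.exists(graphs_path)) {
      stop("no pattern graphs found at ", graphs_path,
           "; run stage 'build-fcn' first")
    }
    timings$train <- clock({
      graphs <- readRDS(graphs_path)
      fit <- train_model(graphs, graphs$patterns, train_cfg)
      saveRDS(fit, ckpt_path)
      readr::write_tsv(fit$history, file.path(out_dir, "history.tsv"))
    })
  }

  if ("evaluate" %in% stages) {
    if (!file.exists(ckpt_path) || !file.exists(graphs_path)) {
      stop("no model checkpoint at ", ckpt_path, "; run stage 'train' first")
    }
    timings$evaluate <- clock({
      graphs <- readRDS(graphs_path)
      fit <- readRDS(ckpt_path)
      metrics <- evaluate_model(fit$model, graphs, fit$split$test)
      jsonlite::write_json(as.list(metrics),
                           file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      if (isTRUE(trn$run_ablation) &&
          all(MFCP_PATTERNS %in% graphs$patterns)) {
        ab <- ablation_study(graphs, train_cfg, seeds = trn$seed)
        readr::write_tsv(ab$results, file.path(out_dir, "ablation.tsv"))
      }
    })
  }

  if ("explain" %in% stages) {
    if (!file.exists(ckpt_path) || !file.exists(graphs_path)) {
      stop("no model checkpoint at ", ckpt_path, "; run stage 'train' first")
    }
    timings$explain <- clock({
      graphs <- readRDS(graphs_path)
      fit <- readRDS(ckpt_path)
      imp <- gradcam_cohort(fit, graphs, indices = fit$split$test,
                            target_class = config$interpretation$target_class)
      top <- top_k_rois(imp, k = config$interpretation$top_k)
      readr::write_tsv(
        dplyr::select(top, "roi_label", "pattern", "mean_score", "rank"),
        file.path(out_dir, "importance.tsv"))
    })
  }

  manifest <- list(
    config_hash = .config_hash(config),
    seeds = list(simulator = sim$seed, training = trn$seed),
    package_version = as.character(utils::packageVersion("mfcpnet")),
    stages = stages,
    timings_seconds = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = 6)
  write_pipeline_config(config, file.path(out_dir, "resolved_config.yaml"))
  invisible(out_dir)
}

#' Validate an on-disk cohort directory
#'
#' Checks the manifest schema, the label domain (0/1, both classes
#' present), file existence, matrix shape consistency and finiteness.
#' Problems are collected into a machine-readable report rather than
#' thrown.
#'
#' @param path Cohort directory.
#' @return An `mfcp_validation`: list with tibbles `errors` and `warnings`
#'   (columns `item`, `message`) and logical `ok`.
#' @export
validate_inputs <- function(path) {
  errors <- list()
  warnings <- list()
  note <- function(store, item, message) {
    c(store, list(tibble::tibble(item = item, message = message)))
  }
  manifest_path <- file.path(path, "manifest.tsv")
  if (!dir.exists(path)) {
    errors <- note(errors, path, "directory does not exist")
  } else if (!file.exists(manifest_path)) {
    errors <- note(errors, "manifest.tsv", "manifest not found")
  } else {
    manifest <- tryCatch(readr::read_tsv(manifest_path, show_col_types = FALSE),
                         error = function(e) NULL)
    if (is.null(manifest)) {
      errors <- note(errors, "manifest.tsv", "manifest is unreadable")
    } else {
      missing_cols <- setdiff(c("subject_id", "label", "file"),
                              names(manifest))
      if (length(missing_cols) > 0L) {
        errors <- note(errors, "manifest.tsv",
                       paste("missing column(s):",
                             paste(missing_cols, collapse = ", ")))
      } else {
        bad <- setdiff(unique(manifest$label), c(0L, 1L))
        if (length(bad) > 0L) {
          errors <- note(errors, "manifest.tsv",
                         paste("labels outside {0, 1}:",
                               paste(bad, collapse = ", ")))
        }
        if (length(unique(manifest$label)) < 2L) {
          warnings <- note(warnings, "manifest.tsv",
                           "only one class present")
        }
        shapes <- character(nrow(manifest))
        for (k in seq_len(nrow(manifest))) {
          f <- manifest$file[k]
          fp <- file.path(path, f)
          if (!file.exists(fp)) {
            errors <- note(errors, f, "file referenced by manifest is missing")
            next
          }
          m <- tryCatch(.read_matrix_txt(fp), error = function(e) NULL,
                        warning = function(w) NULL)
          if (is.null(m)) {
            errors <- note(errors, f, "file is unreadable as a numeric matrix")
            next
          }
          shapes[k] <- paste(dim(m), collapse = "x")
          n_bad <- sum(!is.finite(m))
          if (n_bad > 0L) {
            errors <- note(errors, f,
                           paste0("subject ", manifest$subject_id[k], " has ",
                                  n_bad, " non-finite cell(s)"))
          }
        }
        seen <- shapes[shapes != ""]
        if (length(unique(seen)) > 1L) {
          ref <- names(which.max(table(seen)))
          off <- manifest$file[shapes != ref & shapes != ""]
          errors <- note(errors, paste(off, collapse = ", "),
                         paste0("matrix shape differs from modal shape ", ref))
        }
      }
    }
  }
  bind_or_empty <- function(x) {
    if (length(x) == 0L) tibble::tibble(item = character(), message = character())
    else dplyr::bind_rows(x)
  }
  structure(list(errors = bind_or_empty(errors),
                 warnings = bind_or_empty(warnings),
                 ok = length(errors) == 0L),
            class = "mfcp_validation")
}

#' @export
print.mfcp_validation <- function(x, ...) {
  cat("<mfcp_validation>", if (x$ok) "OK" else "FAILED",
      "-", nrow(x$errors), "error(s),", nrow(x$warnings), "warning(s)\n")
  if (nrow(x$errors) > 0L) print(x$errors)
  if (nrow(x$warnings) > 0L) print(x$warnings)
  invisible(x)
}
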