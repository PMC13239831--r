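#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.0025
#' and weight decay 1e-5, cross-entropy loss, 150 epochs, dropout 0.5 in
#' the fully connected head, and a stratified 70/10/20 train/validation/
#' test split. Gradient steps are full-batch by default (cohorts here are
#' at most a few hundred subjects); set `batch_size` for mini-batching.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 regularization factor added to gradients.
#' @param epochs Number of training epochs (>= 1).
#' @param dropout Head dropout rate.
#' @param seed Integer seed governing split, initialization and dropout.
#' @param train_frac,val_frac,test_frac Split fractions; must sum to 1.
#' @param batch_size NULL for full batch, else a positive integer.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.0025, weight_decay = 1e-5,
                         epochs = 150L, dropout = 0.5, seed = 1L,
                         train_frac = 0.7, val_frac = 0.1, test_frac = 0.2,
                         batch_size = NULL) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-8) {
    stop("split fractions must sum to 1")
  }
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), dropout = dropout,
                 seed = as.integer(seed),
                 fractions = c(train = train_frac, val = val_frac,
                               test = test_frac),
                 batch_size = batch_size),
            class = "train_config")
}

#' Stratified train/validation/test split
#'
#' Shuffles each class independently and allocates subjects to the three
#' subsets by largest-remainder rounding of the per-class fractions, so
#' class proportions in every subset are within one subject of exact
#' stratification. Deterministic given `seed`.
#'
#' @param labels Integer 0/1 labels.
#' @param fractions Named numeric `c(train=, val=, test=)` summing to 1.
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `val`, `test`
#'   (disjoint, exhaustive).
#' @export
stratified_split <- function(labels, fractions = c(train = 0.7, val = 0.1,
                                                   test = 0.2),
                             seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < 3L)) {
    stop("each class needs >= 3 members for a three-way split; counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  set.seed(seed)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    n_c <- length(idx)
    exact <- fractions * n_c
    sizes <- floor(exact)
    rem <- n_c - sum(sizes)
    if (rem > 0L) {
      # give leftovers to the largest fractional parts; ties in the fixed
      # order train, val, test
      extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    if (any(sizes == 0 & fractions > 0)) {
      stop("cannot stratify class ", cl, " (", n_c,
           " members) into non-empty subsets at fractions ",
           paste(round(fractions, 3), collapse = "/"))
    }
    grp <- factor(rep(seq_along(sizes), times = sizes), levels = 1:3)
    splits <- split(idx, grp)
    out$train <- c(out$train, splits[[1L]])
    out$val <- c(out$val, splits[[2L]])
    out$test <- c(out$test, splits[[3L]])
  }
  lapply(out, sort)
}

#' Classification metrics from scores and labels
#'
#' Hard predictions by arg-max score (positive class = case). Accuracy,
#' precision, recall and F1 come from the confusion counts; AUC is the
#' rank-based (Mann-Whitney) probability that a random case outscores a
#' random control, counting ties 1/2. With a single-class evaluation set
#' the AUC is undefined and reported as NA.
#'
#' @param scores Numeric case-class scores (probabilities or logits).
#' @param predicted Integer 0/1 predictions.
#' @param labels Integer 0/1 truth.
#' @return One-row tibble with accuracy, precision, recall, f1, auc and
#'   the confusion counts tp, tn, fp, fn.
#' @export
classification_metrics <- function(scores, predicted, labels) {
  tp <- sum(predicted == 1L & labels == 1L)
  tn <- sum(predicted == 0L & labels == 0L)
  fp <- sum(predicted == 1L & labels == 0L)
  fn <- sum(predicted == 0L & labels == 1L)
  metrics_from_confusion(tp, fp, fn, tn,
                         auc = auc_rank(scores, labels))
}

#' @rdname classification_metrics
#' @param tp,fp,fn,tn Confusion counts.
#' @param auc Optional AUC to carry through.
#' @export
metrics_from_confusion <- function(tp, fp, fn, tn, auc = NA_real_) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  tibble::tibble(
    accuracy = (tp + tn) / (tp + fn + fp + tn),
    precision = prec, recall = rec, f1 = f1, auc = auc,
    tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' @param scores Case-class scores.
#' @param labels Integer 0/1 truth.
#' @return AUC in `[0, 1]`, or NA if either class is absent.
#' @export
auc_rank <- function(scores, labels) {
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)                       # average ranks give half-tie credit
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a model on a subject subset
#'
#' @param model An `mfcp_model`.
#' @param graphs An `mfcp_graphs` object.
#' @param indices Subject indices to evaluate (default: all).
#' @return One-row metrics tibble (see [classification_metrics()]).
#' @export
evaluate_model <- function(model, graphs, indices = NULL) {
  indices <- indices %||% seq_along(graphs$graphs)
  sub <- graphs
  sub$graphs <- graphs$graphs[indices]
  labels <- graphs$labels[indices]
  scores <- predict(model, sub, type = "score")
  probs <- apply(scores, 1L, function(s) .softmax(s)[2L])
  predicted <- as.integer(scores[, 2L] > scores[, 1L])
  classification_metrics(probs, predicted, labels)
}

# ---- Adam over a flat list of tensors -------------------------------------

.flatten_params <- function(model) {
  out <- list()
  for (p in names(model$branches)) {
    out[[paste0("branch.", p, ".W0")]] <- model$branches[[p]]$W0
    out[[paste0("branch.", p, ".W1")]] <- model$branches[[p]]$W1
  }
  for (nm in names(model$head)) out[[paste0("head.", nm)]] <- model$head[[nm]]
  out
}

.unflatten_params <- function(model, flat) {
  for (p in names(model$branches)) {
    model$branches[[p]]$W0 <- flat[[paste0("branch.", p, ".W0")]]
    model$branches[[p]]$W1 <- flat[[paste0("branch.", p, ".W1")]]
  }
  for (nm in names(model$head)) model$head[[nm]] <- flat[[paste0("head.", nm)]]
  model
}

.flatten_grads <- function(grads) {
  out <- list()
  for (p in names(grads$branches)) {
    out[[paste0("branch.", p, ".W0")]] <- grads$branches[[p]]$W0
    out[[paste0("branch.", p, ".W1")]] <- grads$branches[[p]]$W1
  }
  for (nm in names(grads$head)) out[[paste0("head.", nm)]] <- grads$head[[nm]]
  out
}

.adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(flat, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]] + wd * flat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

# ---- training --------------------------------------------------------------

#' Train the multi-branch GCN classifier
#'
#' Full-batch Adam on the mean cross-entropy of the softmaxed class scores,
#' with dropout in the head during training. After every epoch the model is
#' evaluated on the validation set; the parameters with the highest
#' validation accuracy are checkpointed (ties resolved by lower validation
#' loss, then by earlier epoch) and restored before the final test-set
#' evaluation. Fully reproducible given `config$seed`.
#'
#' @param graphs An `mfcp_graphs` object covering every requested pattern.
#' @param patterns Branch subset to train on (fixed order PC, SR, GCM).
#' @param config A [train_config()].
#' @param split Optional list of index vectors `train`, `val`, `test`;
#'   computed by [stratified_split()] from `config` when NULL.
#' @return An `mfcp_fit`: the checkpointed `model`, per-epoch `history`
#'   tibble (epoch, train_loss, val_loss, val_accuracy), `best_epoch`,
#'   `split`, test-set `metrics`, `patterns` and `config`.
#' @export
train_model <- function(graphs, patterns = graphs$patterns,
                        config = train_config(), split = NULL) {
  stopifnot(inherits(graphs, "mfcp_graphs"))
  patterns <- .check_patterns(patterns)
  if (!all(patterns %in% graphs$patterns)) {
    stop("graphs are missing pattern(s): ",
         paste(setdiff(patterns, graphs$patterns), collapse = ", "))
  }
  labels <- graphs$labels
  if (is.null(split)) {
    split <- stratified_split(labels, config$fractions, config$seed)
  }
  if (length(split$val) == 0L) stop("validation set is empty")

  set.seed(config$seed)
  model <- mfcp_model(feature_dim = ncol(graphs$graphs[[1L]][[patterns[1L]]]$node_features),
                      patterns = patterns, dropout = config$dropout)
  cg <- .compile_graphs(graphs, patterns)
  flat <- .flatten_params(model)
  adam <- .adam_init(flat)
  keep <- 1 - config$dropout

  n_train <- length(split$train)
  batches <- if (is.null(config$batch_size)) {
    list(split$train)
  } else {
    split(split$train, ceiling(seq_len(n_train) / config$batch_size))
  }

  eval_set <- function(mdl, idx) {
    losses <- numeric(length(idx))
    correct <- logical(length(idx))
    for (q in seq_along(idx)) {
      k <- idx[q]
      fw <- .forward_compiled(mdl, cg[[k]])
      pr <- .softmax(fw$scores)
      y <- labels[k] + 1L
      losses[q] <- -log(max(pr[y], 1e-12))
      correct[q] <- which.max(fw$scores) == y
    }
    c(loss = mean(losses), accuracy = mean(correct))
  }

  history <- matrix(NA_real_, config$epochs, 3L,
                    dimnames = list(NULL, c("train_loss", "val_loss",
                                            "val_accuracy")))
  best <- list(acc = -Inf, loss = Inf, epoch = NA_integer_, flat = flat)

  for (epoch in seq_len(config$epochs)) {
    epoch_loss <- 0
    for (batch in batches) {
      grad_sum <- NULL
      for (k in batch) {
        masks <- if (config$dropout > 0) {
          list(m1 = stats::rbinom(32L, 1L, keep) / keep,
               m2 = stats::rbinom(16L, 1L, keep) / keep)
        } else NULL
        fw <- .forward_compiled(model, cg[[k]], masks)
        pr <- .softmax(fw$scores)
        y <- labels[k] + 1L
        epoch_loss <- epoch_loss - log(max(pr[y], 1e-12))
        dscores <- pr
        dscores[y] <- dscores[y] - 1
        bw <- .backward_compiled(model, cg[[k]], fw, dscores)
        g <- .flatten_grads(bw$grads)
        grad_sum <- if (is.null(grad_sum)) g
                    else purrr::map2(grad_sum, g, `+`)
      }
      grad_mean <- lapply(grad_sum, function(x) x / length(batch))
      step <- .adam_step(flat, grad_mean, adam, config$learning_rate,
                         config$weight_decay)
      flat <- step$flat
      adam <- step$state
      model <- .unflatten_params(model, flat)
    }
    val <- eval_set(model, split$val)
    history[epoch, ] <- c(epoch_loss / n_train, val["loss"], val["accuracy"])
    better <- val["accuracy"] > best$acc ||
      (val["accuracy"] == best$acc && val["loss"] < best$loss)
    if (better) {
      best <- list(acc = unname(val["accuracy"]), loss = unname(val["loss"]),
                   epoch = epoch, flat = flat)
    }
  }

  model <- .unflatten_params(model, best$flat)
  fit <- structure(
    list(model = model,
         history = tibble::tibble(epoch = seq_len(config$epochs),
                                  train_loss = history[, 1L],
                                  val_loss = history[, 2L],
                                  val_accuracy = history[, 3L]),
         best_epoch = best$epoch, split = split, patterns = patterns,
         config = config),
    class = "mfcp_fit")
  fit$metrics <- evaluate_model(model, graphs, split$test)
  fit
}

#' @export
print.mfcp_fit <- function(x, ...) {
  cat("<mfcp_fit> patterns:", paste(x$patterns, collapse = "+"),
      "| best epoch", x$best_epoch,
      "| test accuracy", round(x$metrics$accuracy, 4), "\n")
  invisible(x)
}

#' Repeat training over independent seeds
#'
#' Each repetition redraws both the stratified split and the weight
#' initialization from its own seed (derived deterministically from
#' `base_seed`) and reports per-run test metrics plus their mean and
#' sample standard deviation (n - 1).
#'
#' @param graphs An `mfcp_graphs`.
#' @param patterns Branch subset.
#' @param config A [train_config()] (its `seed` is overridden per run).
#' @param n_repetitions Number of repetitions (>= 2).
#' @param base_seed Root seed for deriving per-run seeds.
#' @param shuffle_labels If TRUE, labels are randomly permuted per run
#'   (null-calibration experiments).
#' @return An `mfcp_runs` object with tibbles `runs` (per-run metrics) and
#'   `summary` (metric, mean, sd; sd is the sample standard deviation).
#' @export
repeated_runs <- function(graphs, patterns = graphs$patterns,
                          config = train_config(), n_repetitions = 30L,
                          base_seed = 1L, shuffle_labels = FALSE) {
  if (n_repetitions < 2L) stop("n_repetitions must be >= 2")
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_repetitions)
  rows <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    cfg <- config
    cfg$seed <- seeds[r]
    g <- graphs
    if (shuffle_labels) {
      set.seed(seeds[r])
      g$labels <- sample(g$labels)
    }
    fit <- train_model(g, patterns, cfg)
    rows[[r]] <- dplyr::bind_cols(
      tibble::tibble(rep = r, seed = seeds[r]), fit$metrics)
  }
  runs <- dplyr::bind_rows(rows)
  metric_cols <- c("accuracy", "precision", "recall", "f1", "auc")
  summary <- tidyr::pivot_longer(runs[, metric_cols], dplyr::everything(),
                                 names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  structure(list(runs = runs, summary = summary,
                 patterns = patterns, sd_convention = "sample (n-1)"),
            class = "mfcp_runs")
}

#' @export
print.mfcp_runs <- function(x, ...) {
  cat("<mfcp_runs>", nrow(x$runs), "repetitions, patterns:",
      paste(x$patterns, collapse = "+"),
      "(mean +/- sample sd)\n")
  print(x$summary)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Partitions subjects into k stratified folds. Within each fold's training
#' portion, one eighth (stratified) is held out as the validation set used
#' for epoch checkpoint selection, mirroring the 70/10 ratio of the
#' single-split protocol. Reports per-fold and mean +/- sample-sd metrics.
#'
#' @param graphs An `mfcp_graphs`.
#' @param patterns Branch subset.
#' @param config A [train_config()].
#' @param k Number of folds (default 5); must not exceed the smaller
#'   class size.
#' @param seed Seed for fold assignment (training seeds derive from it).
#' @return An `mfcp_cv` object with `folds` (per-fold metrics tibble),
#'   `summary`, and the fold assignment vector.
#' @export
cross_validate <- function(graphs, patterns = graphs$patterns,
                           config = train_config(), k = 5L, seed = 1L) {
  labels <- graphs$labels
  counts <- table(labels)
  if (k > min(counts) && k != length(labels)) {
    # k = n (leave-one-out) is allowed as a special case
    stop("k = ", k, " exceeds the smallest class size (", min(counts), ")")
  }
  set.seed(seed)
  fold_of <- integer(length(labels))
  if (k == length(labels)) {
    fold_of <- sample(k)              # leave-one-out: one subject per fold
  } else {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    pool <- which(fold_of != f)
    # stratified 1/8 of the training portion as validation
    val_idx <- integer(0)
    for (cl in sort(unique(labels))) {
      cl_pool <- pool[labels[pool] == cl]
      n_val <- max(1L, round(length(cl_pool) / 8))
      val_idx <- c(val_idx, cl_pool[seq_len(n_val)])
    }
    train_idx <- setdiff(pool, val_idx)
    cfg <- config
    cfg$seed <- seed + f
    fit <- train_model(graphs, patterns, cfg,
                       split = list(train = train_idx, val = val_idx,
                                    test = test_idx))
    rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), fit$metrics)
  }
  folds <- dplyr::bind_rows(rows)
  metric_cols <- c("accuracy", "precision", "recall", "f1", "auc")
  summary <- tidyr::pivot_longer(folds[, metric_cols], dplyr::everything(),
                                 names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  structure(list(folds = folds, summary = summary, fold_of = fold_of,
                 patterns = patterns, k = k,
                 sd_convention = "sample (n-1) across folds"),
            class = "mfcp_cv")
}

#' @export
print.mfcp_cv <- function(x, ...) {
  cat("<mfcp_cv>", x$k, "folds, patterns:", paste(x$patterns, collapse = "+"),
      "(mean +/- sample sd across folds)\n")
  print(x$summary)
  invisible(x)
}
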