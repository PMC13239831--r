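# ---- Pearson pattern -------------------------------------------------------

test_that("perfect linear dependence saturates the correlation pattern", {
  x <- rnorm(30)
  M <- cbind(x, 2 * x + 3, 5 * x - 1)
  w <- pearson_fcn(roi_time_series(M))$weights
  expect_equal(w, matrix(1, 3, 3), tolerance = 1e-12)
  w2 <- pearson_fcn(roi_time_series(cbind(x, -x, rnorm(30))))$weights
  expect_equal(w2[1, 2], -1, tolerance = 1e-12)
  expect_equal(diag(w2), rep(1, 3))
})

test_that("correlation weights match the centred dot-product formula", {
  set.seed(21)
  for (trial in 1:20) {
    M <- matrix(rnorm(50 * 8), 50, 8)
    w <- pearson_fcn(roi_time_series(M))$weights
    oracle <- matrix(NA_real_, 8, 8)
    for (i in 1:8) for (j in 1:8) {
      xi <- M[, i] - mean(M[, i])
      xj <- M[, j] - mean(M[, j])
      oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
    expect_lt(max(abs(w - oracle)), 1e-10)
    expect_lt(max(abs(w - t(w))), 1e-14)
  }
})

test_that("zero-variance ROIs are zeroed with a warning naming them", {
  M <- cbind(rnorm(20), rep(4, 20), rnorm(20))
  expect_warning(cm <- pearson_fcn(roi_time_series(M, c("a", "flat", "c"))),
                 "flat")
  expect_equal(cm$weights[2, c(1, 3)], c(0, 0))
  expect_equal(cm$weights[2, 2], 1)
})

# ---- Sparse-representation pattern ----------------------------------------

test_that("a dominating penalty drives all SR coefficients to zero", {
  set.seed(4)
  ts <- roi_time_series(scale(matrix(rnorm(60 * 5), 60, 5)))
  big <- 1e6 * max(abs(crossprod(ts$values)))
  W <- sparse_representation_fcn(ts, sr_config(lambda = big))
  expect_equal(W$weights, matrix(0, 5, 5))
  expect_true(all(attr(W, "converged")))
})

test_that("the unpenalized solution matches ordinary least squares", {
  set.seed(9)
  X <- scale(matrix(rnorm(80 * 6), 80, 6))
  W <- sparse_representation_fcn(
    roi_time_series(X),
    sr_config(lambda = 0, max_iterations = 5000, tolerance = 1e-12))$weights
  for (i in 1:6) {
    idx <- setdiff(1:6, i)
    ols <- solve(crossprod(X[, idx]), crossprod(X[, idx], X[, i]))
    expect_lt(max(abs(W[i, idx] - as.vector(ols))), 1e-6)
  }
  expect_equal(diag(W), rep(0, 6))
})

test_that("no random candidate beats the solver's per-row objective", {
  set.seed(14)
  X <- scale(matrix(rnorm(40 * 3), 40, 3))
  lam <- 0.5
  fit <- sparse_representation_fcn(roi_time_series(X), sr_config(lambda = lam))
  for (i in 1:3) {
    w_hat <- fit$weights[i, ]
    best <- sr_objective(X, i, w_hat, lam)
    cand <- matrix(rnorm(10000 * 2, sd = 0.5), 10000, 2)
    idx <- setdiff(1:3, i)
    worst_gap <- min(apply(cand, 1, function(cw) {
      w <- numeric(3); w[idx] <- cw
      sr_objective(X, i, w, lam)
    })) - best
    expect_gte(worst_gap, -1e-8)
  }
})

test_that("the SR objective never increases across solver sweeps", {
  set.seed(2)
  ts <- roi_time_series(scale(matrix(rnorm(50 * 6), 50, 6)))
  fit <- sparse_representation_fcn(ts, sr_config(lambda = 0.3))
  for (trace in attr(fit, "sweep_objectives")) {
    expect_true(all(diff(trace) <= 1e-10))
  }
})

test_that("total L1 mass shrinks along an increasing lambda path", {
  set.seed(5)
  ts <- roi_time_series(scale(matrix(rnorm(60 * 6), 60, 6)))
  mass <- sapply(c(0, 0.5, 1, 5, 20), function(lam) {
    sum(abs(sparse_representation_fcn(ts, sr_config(lambda = lam))$weights))
  })
  expect_true(all(diff(mass) <= 1e-8))
})

test_that("SR coefficients agree with an independent lasso solver", {
  skip_if_not_installed("glmnet")
  set.seed(77)
  X <- scale(matrix(rnorm(100 * 5), 100, 5))
  lam <- 2
  W <- sparse_representation_fcn(
    roi_time_series(X), sr_config(lambda = lam, tolerance = 1e-10))$weights
  t_len <- nrow(X)
  for (i in 1:5) {
    idx <- setdiff(1:5, i)
    # glmnet minimises 1/(2n)||y - Zb||^2 + lambda_g ||b||_1
    gfit <- glmnet::glmnet(X[, idx], X[, i], lambda = lam / (2 * t_len),
                           standardize = FALSE, intercept = FALSE,
                           thresh = 1e-14)
    expect_lt(max(abs(W[i, idx] - as.vector(gfit$beta))), 1e-4)
  }
})

# ---- Granger causality pattern --------------------------------------------

test_that("independent white noise yields causality below its permutation null", {
  set.seed(12)
  t_len <- 500
  x <- rnorm(t_len); y <- rnorm(t_len)
  g_obs <- granger_fcn(roi_time_series(cbind(x, y)))$strengths[1, 2]
  null <- sapply(1:200, function(s) {
    shift <- 1 + (s * 7) %% (t_len - 2)
    xs <- c(x[(shift + 1):t_len], x[1:shift])      # circular shift
    granger_fcn(roi_time_series(cbind(xs, y)))$strengths[1, 2]
  })
  expect_lt(g_obs, quantile(null, 0.99))
})

test_that("a lagged driver is detected in the correct direction", {
  set.seed(8)
  t_len <- 500
  x <- rnorm(t_len + 1)
  y <- 0.6 * x[1:t_len] + rnorm(t_len)
  G <- granger_fcn(roi_time_series(cbind(x = x[2:(t_len + 1)], y = y)))$strengths
  expect_gt(G[1, 2], G[2, 1])
  expect_true(all(G >= 0))
  expect_equal(diag(G), c(0, 0))
})

test_that("causality agrees with an independent Granger test statistic", {
  skip_if_not_installed("lmtest")
  set.seed(19)
  t_len <- 300
  x <- rnorm(t_len + 1)
  y <- 0.4 * x[1:t_len] + rnorm(t_len)
  xv <- x[2:(t_len + 1)]
  G <- granger_fcn(roi_time_series(cbind(xv, y)), lag_order = 1)$strengths
  # F = (exp(G) - 1) * df_resid / p for the nested RSS comparison
  f_ours <- (exp(G[1, 2]) - 1) * (t_len - 1 - 3) / 1
  gt <- lmtest::grangertest(y ~ xv, order = 1)
  expect_equal(f_ours, gt$F[2], tolerance = 1e-8)
})

test_that("a constant target ROI is flagged and zeroed", {
  M <- cbind(rnorm(60), rep(2, 60), rnorm(60))
  expect_warning(dc <- granger_fcn(roi_time_series(M, c("a", "flat", "c"))),
                 "flat")
  expect_equal(dc$strengths[, 2], rep(0, 3))
})

test_that("short series are rejected for the requested lag order", {
  M <- matrix(rnorm(6 * 3), 6, 3)
  expect_error(granger_fcn(roi_time_series(M), lag_order = 2),
               "t > 2\\*lag_order \\+ 2")
})

# ---- GCM symmetrization ----------------------------------------------------

test_that("bidirectional strengths aggregate additively and symmetrically", {
  G <- matrix(0, 3, 3)
  G[1, 2] <- 0.3; G[2, 1] <- 0.1
  dc <- structure(list(strengths = G, lag_order = 1L,
                       roi_labels = c("a", "b", "c")),
                  class = "directed_causality")
  A <- symmetrize_gcm(dc)$weights
  expect_equal(A[1, 2], 0.4)
  expect_equal(A[2, 1], 0.4)
  expect_equal(diag(A), rep(0, 3))

  zero <- structure(list(strengths = matrix(0, 4, 4), lag_order = 1L,
                         roi_labels = paste0("r", 1:4)),
                    class = "directed_causality")
  expect_equal(symmetrize_gcm(zero)$weights, matrix(0, 4, 4))

  set.seed(3)
  R <- matrix(abs(rnorm(25)), 5, 5); diag(R) <- 0
  dc2 <- structure(list(strengths = R, lag_order = 1L,
                        roi_labels = paste0("r", 1:5)),
                   class = "directed_causality")
  A2 <- symmetrize_gcm(dc2)$weights
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) if (i != j) oracle[i, j] <- abs(R[i, j] + R[j, i])
  expect_equal(A2, oracle)
  expect_identical(A2, t(A2))
})

# ---- canonicalization ------------------------------------------------------

test_that("canonicalization takes magnitudes, rescales and thresholds", {
  W <- matrix(c(1, -0.8, 0.05, -0.8, 1, 0.4, 0.05, 0.4, 1), 3, 3)
  cm <- connectivity_matrix(W, "PC")
  can <- canonicalize(cm, 0.1)
  expect_true(can$canonical)
  expect_equal(can$weights[1, 2], 0.8 / 0.8)   # max off-diagonal is 0.8
  expect_equal(can$weights[1, 3], 0)           # 0.05/0.8 < 0.1 removed
  expect_equal(diag(can$weights), rep(0, 3))

  # threshold 0: no edges removed, only sign/diagonal/scale normalization
  can0 <- canonicalize(cm, 0)
  expect_equal(sum(can0$weights > 0), 6)

  expect_error(canonicalize(cm, 1), "\\[0, 1\\)")
})

test_that("surviving edge counts match a brute-force count", {
  set.seed(6)
  W <- matrix(rnorm(100), 10, 10)
  cm <- connectivity_matrix(W, "SR")
  can <- canonicalize(cm, 0.2)
  S <- abs((W + t(W)) / 2); diag(S) <- 0; S <- S / max(S)
  expect_equal(sum(can$weights > 0), sum(S >= 0.2))
})

test_that("canonicalization is exactly idempotent", {
  set.seed(7)
  cm <- connectivity_matrix(matrix(rnorm(64), 8, 8), "GCM")
  once <- canonicalize(cm, 0.25)
  twice <- canonicalize(once, 0.25)
  expect_identical(once$weights, twice$weights)
})

test_that("raw-scale thresholding can empty a uniformly weak graph", {
  W <- matrix(0.01, 4, 4); diag(W) <- 0
  cm <- connectivity_matrix(W, "GCM")
  expect_warning(can <- canonicalize(cm, 0.5, threshold_scale = "raw"),
                 "empty")
  expect_equal(max(can$weights), 0)
  # rescaled convention keeps the maximum entry at any threshold < 1
  keep <- canonicalize(cm, 0.99)
  expect_gt(max(keep$weights), 0)
})

# ---- ROI permutation consistency ------------------------------------------

test_that("estimators commute with ROI reordering", {
  set.seed(23)
  M <- scale(matrix(rnorm(150 * 6), 150, 6))
  perm <- sample(6)
  ts <- roi_time_series(M)
  ts_p <- roi_time_series(M[, perm])

  pc <- pearson_fcn(ts)$weights
  pc_p <- pearson_fcn(ts_p)$weights
  expect_lt(max(abs(pc_p - pc[perm, perm])), 1e-12)

  sr_cfgx <- sr_config(lambda = 0.4, tolerance = 1e-11)
  sr <- sparse_representation_fcn(ts, sr_cfgx)$weights
  sr_p <- sparse_representation_fcn(ts_p, sr_cfgx)$weights
  expect_lt(max(abs(sr_p - sr[perm, perm])), 1e-5)

  gc <- granger_fcn(ts)$strengths
  gc_p <- granger_fcn(ts_p)$strengths
  expect_lt(max(abs(gc_p - gc[perm, perm])), 1e-8)
})

# ---- graph assembly --------------------------------------------------------

test_that("pattern graphs come back in fixed order with profile features", {
  s <- tiny_cohort()$subjects[[1]]
  gs <- build_pattern_graphs(s, sr_cfg = sr_config(max_iterations = 200))
  expect_named(gs, c("PC", "SR", "GCM"))
  expect_equal(ncol(gs$PC$node_features), 8)
  expect_identical(gs$PC$node_features, gs$PC$adjacency$weights)

  # the three estimators disagree pairwise on generic input
  d <- function(a, b) sqrt(sum((gs[[a]]$adjacency$weights -
                                  gs[[b]]$adjacency$weights)^2))
  expect_gt(d("PC", "SR"), 0)
  expect_gt(d("PC", "GCM"), 0)
  expect_gt(d("SR", "GCM"), 0)

  one <- build_pattern_graphs(s, patterns = "PC")
  expect_named(one, "PC")
  expect_error(build_pattern_graphs(s, patterns = character(0)), "non-empty")
})
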