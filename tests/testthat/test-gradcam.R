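test_that("scores are non-negative and normalized to a unit maximum", {
  set.seed(61)
  gs <- list(PC = rand_pattern_graph(7, "PC", seed = 61),
             SR = rand_pattern_graph(7, "SR", seed = 62),
             GCM = rand_pattern_graph(7, "GCM", seed = 63))
  m <- mfcp_model(7, c("PC", "SR", "GCM"))
  imp <- gradcam_node_importance(m, gs, "case")
  expect_equal(nrow(imp), 21)
  expect_true(all(imp$score >= 0))
  for (p in c("PC", "SR", "GCM")) {
    s <- imp$score[imp$pattern == p]
    if (!any(imp$degenerate[imp$pattern == p])) expect_equal(max(s), 1)
  }
})

test_that("a branch the head ignores gets all-zero degenerate scores", {
  set.seed(64)
  gs <- list(PC = rand_pattern_graph(6, "PC", seed = 65),
             SR = rand_pattern_graph(6, "SR", seed = 66))
  m <- mfcp_model(6, c("PC", "SR"))
  # positively-signed head so the surviving branch's scores cannot all
  # rectify away
  m$head$A1 <- abs(m$head$A1)
  m$head$A2 <- abs(m$head$A2)
  m$head$A3 <- abs(m$head$A3)
  m$head$A1[65:128, ] <- 0       # sever the SR branch from the head
  imp <- gradcam_node_importance(m, gs, "case")
  sr <- imp[imp$pattern == "SR", ]
  expect_equal(sr$score, rep(0, 6))
  expect_true(all(sr$degenerate))
  expect_false(any(sr$normalized))
  pc <- imp[imp$pattern == "PC", ]
  expect_gt(max(pc$score), 0)
})

test_that("duplicated ROIs in symmetric roles receive equal importance", {
  set.seed(67)
  n <- 4
  A <- rand_canonical(n, seed = 68)
  # make nodes 3 and 4 exchangeable: equal rows outside the pair
  A[3, 1:2] <- A[4, 1:2] <- c(0.5, 0.2)
  A[1:2, 3] <- A[1:2, 4] <- c(0.5, 0.2)
  A[3, 4] <- A[4, 3] <- 0.7
  diag(A) <- 0
  X <- matrix(rnorm(n * n), n, n)
  X[4, ] <- X[3, ]               # identical feature rows
  g <- pattern_graph(connectivity_matrix(A / max(A), "PC", canonical = TRUE),
                     node_features = X)
  m <- mfcp_model(n, "PC")
  imp <- gradcam_node_importance(m, list(PC = g), "case")
  expect_lt(abs(imp$score[3] - imp$score[4]), 1e-6)
})

test_that("a three-node network matches a hand-worked chain-rule evaluation", {
  # Path graph 1-2-3 with unit edges; 1-dim features and 2-channel convs,
  # hand-set weights everywhere; head reduced to a pure linear map.
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1
  g <- pattern_graph(connectivity_matrix(A, "PC", canonical = TRUE),
                     node_features = matrix(c(1, 2, 3), 3, 1))
  m <- mfcp_model(1, "PC", conv_dim = 2)
  m$branches$PC$W0 <- matrix(c(1, 0.5), 1, 2)
  m$branches$PC$W1 <- matrix(c(1, 0, 0.25, 0.5), 2, 2)
  m$head$A1 <- matrix(0, 4, 32); m$head$A1[1, 1] <- 1; m$head$A1[2, 2] <- 1
  m$head$A1[3, 3] <- 1; m$head$A1[4, 4] <- 1
  m$head$b1 <- rep(0, 32)
  m$head$A2 <- matrix(0, 32, 16); m$head$A2[1:4, 1] <- c(1, 2, 3, 4)
  m$head$b2 <- rep(0, 16)
  m$head$A3 <- matrix(0, 16, 2); m$head$A3[1, 2] <- 1
  m$head$b3 <- c(0, 0)

  # ---- oracle, written out step by step ----
  P <- diag(1 / sqrt(c(2, 3, 2))) %*% (A + diag(3)) %*%
    diag(1 / sqrt(c(2, 3, 2)))
  X <- matrix(c(1, 2, 3), 3, 1)
  H1 <- pmax(P %*% X %*% m$branches$PC$W0, 0)
  H2 <- pmax(P %*% H1 %*% m$branches$PC$W1, 0)      # 3 x 2, all positive here
  # y_case = a2[1] (A3[1,2]=1) = z2[1] (positive) with
  # z2[1] = 1*mean(H2[,1]) + 2*mean(H2[,2]) + 3*max(H2[,1]) + 4*max(H2[,2])
  amax <- apply(H2, 2, which.max)
  dH2 <- matrix(0, 3, 2)
  dH2[, 1] <- 1 / 3; dH2[, 2] <- 2 / 3
  dH2[amax[1], 1] <- dH2[amax[1], 1] + 3
  dH2[amax[2], 2] <- dH2[amax[2], 2] + 4
  alpha <- colMeans(dH2)
  S_hand <- pmax(H2 %*% alpha, 0)
  S_hand <- S_hand / max(S_hand)

  imp <- gradcam_node_importance(m, list(PC = g), "case")
  expect_equal(imp$score, as.vector(S_hand), tolerance = 1e-12)
})

test_that("channel scaling propagates linearly through the attribution formula", {
  set.seed(70)
  H <- matrix(abs(rnorm(6 * 4)), 6, 4)
  g <- matrix(rnorm(6 * 4), 6, 4)
  base <- mfcpnet:::.gradcam_scores(H, g)
  for (c_scale in c(0.5, 2, 10)) {
    Hs <- H; Hs[, 2] <- Hs[, 2] * c_scale
    scaled <- mfcpnet:::.gradcam_scores(Hs, g)
    contrib_base <- H[, 2] * mean(g[, 2])
    pre_base <- as.vector(H %*% colMeans(g))
    pre_scaled <- as.vector(Hs %*% colMeans(g))
    expect_equal(pre_scaled - pre_base, (c_scale - 1) * contrib_base,
                 tolerance = 1e-12)
    expect_true(all(scaled >= 0))
  }
})

test_that("importance is deterministic across calls in eval mode", {
  set.seed(71)
  gs <- list(PC = rand_pattern_graph(5, "PC", seed = 72))
  m <- mfcp_model(5, "PC")
  i1 <- gradcam_node_importance(m, gs, "case")
  i2 <- gradcam_node_importance(m, gs, "case")
  expect_identical(i1, i2)
})

test_that("top-k ranking equals a brute-force sort of the mean scores", {
  set.seed(73)
  imp <- dplyr::bind_rows(lapply(1:10, function(s) {
    tibble::tibble(subject_id = paste0("s", s), pattern = "PC",
                   target_class = "case", roi = 1:12,
                   roi_label = paste0("R", 1:12),
                   score = runif(12), normalized = TRUE, degenerate = FALSE)
  }))
  top <- top_k_rois(imp, k = 5)
  means <- tapply(imp$score, imp$roi, mean)
  oracle <- as.integer(names(sort(means, decreasing = TRUE)))[1:5]
  expect_equal(top$roi, oracle)
  expect_equal(top$rank, 1:5)

  full <- top_k_rois(imp, k = 12)
  expect_setequal(full$roi, 1:12)

  one <- imp[imp$subject_id == "s1", ]
  one$score <- rev(sort(one$score))
  expect_equal(top_k_rois(one, k = 5)$roi, 1:5)
})

test_that("the report quantifies top-set overlap between patterns", {
  mk <- function(pattern, scores) {
    tibble::tibble(subject_id = "s1", pattern = pattern,
                   target_class = "case", roi = 1:10,
                   roi_label = paste0("R", 1:10), score = scores,
                   normalized = TRUE, degenerate = FALSE)
  }
  s <- seq(1, 0.1, length.out = 10)
  same <- dplyr::bind_rows(mk("PC", s), mk("SR", s))
  rep_same <- importance_report(same, k = 5)
  expect_equal(rep_same$overlap$overlap, 5L)

  disjoint <- dplyr::bind_rows(mk("PC", s), mk("SR", rev(s)))
  rep_disj <- importance_report(disjoint, k = 5)
  expect_equal(rep_disj$overlap$overlap, 0L)

  expect_error(top_k_rois(dplyr::bind_rows(
    mk("PC", s),
    dplyr::mutate(mk("PC", s), subject_id = "s2",
                  roi_label = paste0("Q", 1:10)))),
    "inconsistent ROI labels")
})
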