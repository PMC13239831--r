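# ---- propagation operator --------------------------------------------------

test_that("an empty graph propagates as the identity", {
  A <- connectivity_matrix(matrix(0, 5, 5), "PC", canonical = TRUE)
  expect_equal(propagation_operator(A), diag(5), tolerance = 1e-15)
})

test_that("the unit-weight triangle normalizes to 1/3 everywhere", {
  A <- matrix(1, 3, 3); diag(A) <- 0
  P <- propagation_operator(connectivity_matrix(A, "PC", canonical = TRUE))
  expect_equal(P, matrix(1 / 3, 3, 3), tolerance = 1e-15)
})

test_that("the operator matches a brute-force composition of its formula", {
  set.seed(13)
  for (trial in 1:10) {
    A <- rand_canonical(7, seed = trial)
    P <- propagation_operator(A)
    Ahat <- A + diag(7)
    Dhalf <- diag(1 / sqrt(rowSums(Ahat)))
    expect_lt(max(abs(P - Dhalf %*% Ahat %*% Dhalf)), 1e-12)
    expect_lt(max(abs(P - t(P))), 1e-15)
  }
})

test_that("operator eigenvalues stay within [-1, 1]", {
  for (seed in 1:10) {
    n <- sample(5:30, 1)
    P <- propagation_operator(rand_canonical(n, seed = 100 + seed))
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
  }
})

test_that("the normalized Laplacian is the identity-minus-normalized form", {
  A <- rand_canonical(6, seed = 2)
  L <- normalized_laplacian(A)
  dh <- 1 / sqrt(rowSums(A))
  oracle <- diag(6) - A * (dh %o% dh)
  expect_equal(L, oracle, tolerance = 1e-12)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10 & ev <= 2 + 1e-10))
})

# ---- branch forward --------------------------------------------------------

test_that("zero node features give a zero branch output", {
  g <- rand_pattern_graph(6, seed = 3, features = matrix(0, 6, 6))
  set.seed(1)
  w <- list(W0 = matrix(rnorm(6 * 32), 6, 32),
            W1 = matrix(rnorm(32 * 32), 32, 32))
  expect_equal(branch_forward(g, w), matrix(0, 6, 32))
})

test_that("branch forward is equivariant to node permutations", {
  set.seed(5)
  n <- 9
  A <- rand_canonical(n, seed = 5)
  X <- matrix(rnorm(n * 4), n, 4)
  w <- list(W0 = matrix(rnorm(4 * 32), 4, 32),
            W1 = matrix(rnorm(32 * 32), 32, 32))
  g <- pattern_graph(connectivity_matrix(A, "PC", canonical = TRUE), X)
  H <- branch_forward(g, w)
  perm <- sample(n)
  g_p <- pattern_graph(
    connectivity_matrix(A[perm, perm], "PC", canonical = TRUE), X[perm, ])
  H_p <- branch_forward(g_p, w)
  expect_lt(max(abs(H_p - H[perm, ])), 1e-6)
})

test_that("a two-node graph with unit weights reproduces hand arithmetic", {
  # A = [[0, 1], [1, 0]]; Ahat = A + I has degree 2 everywhere, so every
  # entry of P is 1/2. Features x = (1, 3)'; W0 = W1 = [1] (1x1).
  A <- connectivity_matrix(matrix(c(0, 1, 1, 0), 2, 2), "PC",
                           canonical = TRUE)
  g <- pattern_graph(A, node_features = matrix(c(1, 3), 2, 1))
  w <- list(W0 = matrix(1, 1, 1), W1 = matrix(1, 1, 1))
  # layer 1: P x = (2, 2)'; ReLU keeps it; layer 2: P (2,2)' = (2, 2)'
  expect_equal(branch_forward(g, w), matrix(c(2, 2), 2, 1))
})

test_that("feature-width mismatches fail with a shape diagnostic", {
  g <- rand_pattern_graph(5, seed = 1)
  w <- list(W0 = matrix(0, 3, 32), W1 = matrix(0, 32, 32))
  expect_error(branch_forward(g, w), "feature width 5")
})

# ---- readout ---------------------------------------------------------------

test_that("readout concatenates columnwise mean and max", {
  set.seed(6)
  H <- matrix(rnorm(5 * 32), 5, 32)
  r <- readout(H)
  expect_length(r, 64)
  expect_equal(r[1:32], colMeans(H))
  expect_equal(r[33:64], apply(H, 2, max))

  v <- rnorm(32)
  same <- matrix(rep(v, each = 4), 4, 32)
  expect_equal(readout(same), c(v, v))

  expect_error(readout(matrix(numeric(0), 0, 32)), "empty graph")
})

test_that("readout is invariant to node permutations", {
  set.seed(7)
  H <- matrix(rnorm(12 * 32), 12, 32)
  expect_equal(readout(H), readout(H[sample(12), ]), tolerance = 1e-12)
})

# ---- head / fusion ---------------------------------------------------------

test_that("head widths follow the branch count", {
  set.seed(8)
  m1 <- mfcp_model(20, "PC")
  expect_equal(dim(m1$head$A1), c(64L, 32L))
  expect_equal(m1$config$head_widths, c(64L, 32L, 16L, 2L))
  m3 <- mfcp_model(20, c("PC", "SR", "GCM"))
  expect_equal(dim(m3$head$A1), c(192L, 32L))
  expect_equal(dim(m3$head$A2), c(32L, 16L))
  expect_equal(dim(m3$head$A3), c(16L, 2L))

  out <- fuse_and_classify(list(rnorm(64), rnorm(64), rnorm(64)), m3$head)
  expect_length(out$fused, 192)
  expect_length(out$scores, 2)
  expect_error(fuse_and_classify(list(rnorm(64)), m3$head), "branch count")
})

test_that("evaluation-mode scoring is deterministic", {
  set.seed(9)
  m <- mfcp_model(8, c("PC", "SR"))
  e <- list(rnorm(64), rnorm(64))
  s1 <- fuse_and_classify(e, m$head, training = FALSE)
  s2 <- fuse_and_classify(e, m$head, training = FALSE)
  expect_identical(s1$scores, s2$scores)
})

# ---- full network gradients and reproducibility ---------------------------

test_that("analytic gradients match central finite differences", {
  set.seed(31)
  n <- 5
  gs <- list(PC = rand_pattern_graph(n, "PC", seed = 41),
             SR = rand_pattern_graph(n, "SR", seed = 42))
  model <- mfcp_model(n, c("PC", "SR"))
  cg <- lapply(gs, function(g) {
    P <- propagation_operator(g$adjacency)
    list(P = P, PX = P %*% g$node_features)
  })
  fw <- mfcpnet:::.forward_compiled(model, cg)
  pr <- mfcpnet:::.softmax(fw$scores)
  y <- 2L
  ds <- pr; ds[y] <- ds[y] - 1
  analytic <- mfcpnet:::.flatten_grads(
    mfcpnet:::.backward_compiled(model, cg, fw, ds)$grads)
  flat <- mfcpnet:::.flatten_params(model)
  loss_at <- function(f) {
    m2 <- mfcpnet:::.unflatten_params(model, f)
    -log(mfcpnet:::.softmax(mfcpnet:::.forward_compiled(m2, cg)$scores)[y])
  }
  eps <- 1e-6
  worst <- 0
  set.seed(32)
  for (nm in names(flat)) {
    for (q in sample(length(flat[[nm]]), min(4, length(flat[[nm]])))) {
      f <- flat
      f[[nm]][q] <- f[[nm]][q] + eps; up <- loss_at(f)
      f[[nm]][q] <- f[[nm]][q] - 2 * eps; dn <- loss_at(f)
      worst <- max(worst, abs((up - dn) / (2 * eps) - analytic[[nm]][q]))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("the eval-mode forward pass is bitwise reproducible", {
  set.seed(33)
  g <- list(PC = rand_pattern_graph(6, "PC", seed = 51))
  m <- mfcp_model(6, "PC")
  p1 <- predict(m, g, type = "score")
  p2 <- predict(m, g, type = "score")
  expect_identical(p1, p2)
  pr <- predict(m, g, type = "prob")
  expect_true(pr >= 0 && pr <= 1)
})
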