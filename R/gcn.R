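#' Renormalized propagation operator
#'
#' Computes `P = Dhat^{-1/2} (A + I) Dhat^{-1/2}` with
#' `Dhat_ii = sum_j (A + I)_ij`, the self-loop-augmented, symmetrically
#' degree-normalized adjacency used by each graph convolution. Its
#' eigenvalues lie in `[-1, 1]`; the self-loops guarantee strictly positive
#' degrees even for empty graphs (for which P is the identity).
#'
#' @param adjacency A canonical [connectivity_matrix()] or a plain
#'   non-negative symmetric matrix with zero diagonal.
#' @return An n x n symmetric matrix.
#' @export
propagation_operator <- function(adjacency) {
  A <- if (inherits(adjacency, "connectivity_matrix")) {
    if (!adjacency$canonical) stop("adjacency must be canonical")
    adjacency$weights
  } else {
    as.matrix(adjacency)
  }
  Ahat <- A + diag(nrow(A))
  dh <- 1 / sqrt(rowSums(Ahat))
  P <- Ahat * (dh %o% dh)
  (P + t(P)) / 2
}

#' Normalized graph Laplacian (derived quantity)
#'
#' `I - D^{-1/2} A D^{-1/2}` with `D_ii = sum_j A_ij`. Exposed for
#' inspection and testing; propagation itself uses the self-loop
#' renormalization of [propagation_operator()]. Isolated nodes (zero
#' degree) contribute identity rows.
#'
#' @inheritParams propagation_operator
#' @return An n x n symmetric matrix.
#' @export
normalized_laplacian <- function(adjacency) {
  A <- if (inherits(adjacency, "connectivity_matrix")) adjacency$weights
       else as.matrix(adjacency)
  d <- rowSums(A)
  dh <- ifelse(d > 0, 1 / sqrt(d), 0)
  diag(nrow(A)) - A * (dh %o% dh)
}

.relu <- function(x) pmax(x, 0)

.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialise a multi-branch GCN classifier
#'
#' One GCN branch per connection pattern (two bias-free 32-unit graph
#' convolution layers with rectifier activations, mean/max readout to a
#' 64-vector), followed by a fused fully connected head of widths
#' `64 * n_branches -> 32 -> 16 -> 2` with biases, rectifiers between
#' layers, and dropout after the first two head layers during training.
#' Weights are Glorot-uniform; draws come from the current RNG state, so
#' seed before calling for reproducibility.
#'
#' @param feature_dim Node feature width f (= n ROIs under the
#'   connectivity-profile convention).
#' @param patterns Branch patterns in fixed order, subset of
#'   `c("PC", "SR", "GCM")`.
#' @param conv_dim Graph-convolution width (default 32).
#' @param dropout Dropout rate in the head (default 0.5).
#' @return An `mfcp_model` object.
#' @export
mfcp_model <- function(feature_dim, patterns = MFCP_PATTERNS,
                       conv_dim = 32L, dropout = 0.5) {
  patterns <- .check_patterns(patterns)
  n_branches <- length(patterns)
  fused_dim <- 2L * conv_dim * n_branches
  branches <- lapply(patterns, function(p) {
    list(W0 = .glorot(feature_dim, conv_dim),
         W1 = .glorot(conv_dim, conv_dim))
  })
  names(branches) <- patterns
  head_widths <- c(fused_dim, 32L, 16L, 2L)
  head <- list(A1 = .glorot(head_widths[1L], head_widths[2L]),
               b1 = numeric(head_widths[2L]),
               A2 = .glorot(head_widths[2L], head_widths[3L]),
               b2 = numeric(head_widths[3L]),
               A3 = .glorot(head_widths[3L], head_widths[4L]),
               b3 = numeric(head_widths[4L]))
  structure(list(branches = branches, head = head,
                 config = list(patterns = patterns, conv_dim = conv_dim,
                               feature_dim = feature_dim, dropout = dropout,
                               head_widths = head_widths)),
            class = "mfcp_model")
}

#' @export
print.mfcp_model <- function(x, ...) {
  cat("<mfcp_model>", length(x$branches), "branch(es):",
      paste(names(x$branches), collapse = ", "),
      "| head [", paste(x$config$head_widths, collapse = ", "), "]\n")
  invisible(x)
}

#' One-branch graph convolution forward pass
#'
#' Two rounds of propagate -> linear map -> rectifier:
#' `H2 = ReLU(P ReLU(P X W0) W1)` with P the renormalized operator of the
#' graph's adjacency.
#'
#' @param graph A [pattern_graph()].
#' @param weights List with matrices `W0` (f x d) and `W1` (d x d).
#' @return n x d node-embedding matrix.
#' @export
branch_forward <- function(graph, weights) {
  stopifnot(inherits(graph, "pattern_graph"))
  X <- graph$node_features
  if (ncol(X) != nrow(weights$W0)) {
    stop("feature width ", ncol(X), " does not match W0 input dimension ",
         nrow(weights$W0))
  }
  P <- propagation_operator(graph$adjacency)
  H1 <- .relu(P %*% X %*% weights$W0)
  .relu(P %*% H1 %*% weights$W1)
}

#' Mean/max graph readout
#'
#' Concatenates the columnwise mean and columnwise maximum of the node
#' embeddings: a 2d-vector (64 for d = 32), invariant to node order.
#'
#' @param node_embeddings n x d numeric matrix, n >= 1.
#' @return Numeric vector of length 2d.
#' @export
readout <- function(node_embeddings) {
  node_embeddings <- as.matrix(node_embeddings)
  if (nrow(node_embeddings) < 1L) stop("empty graph: no nodes to read out")
  c(colMeans(node_embeddings), apply(node_embeddings, 2L, max))
}

#' Fuse branch embeddings and score classes
#'
#' Concatenates the per-branch readout vectors in fixed branch order and
#' pushes them through the three-layer fully connected head (rectifiers
#' between layers, dropout after the first two layers in training mode).
#' The final layer emits two unnormalized class scores.
#'
#' @param embeddings List of readout vectors, one per branch.
#' @param head Head weight list (`A1`, `b1`, `A2`, `b2`, `A3`, `b3`).
#' @param training Logical; when TRUE, inverted dropout with rate
#'   `dropout` is applied (draws from the current RNG).
#' @param dropout Dropout rate.
#' @return List with `scores` (length 2) and `fused` (the concatenated
#'   embedding).
#' @export
fuse_and_classify <- function(embeddings, head, training = FALSE,
                              dropout = 0.5) {
  fused <- unlist(embeddings, use.names = FALSE)
  if (length(fused) != nrow(head$A1)) {
    stop("fused embedding length ", length(fused),
         " does not match head input width ", nrow(head$A1),
         " (branch count mismatch?)")
  }
  keep <- 1 - dropout
  a1 <- .relu(as.vector(fused %*% head$A1) + head$b1)
  if (training && dropout > 0) {
    a1 <- a1 * (stats::rbinom(length(a1), 1L, keep) / keep)
  }
  a2 <- .relu(as.vector(a1 %*% head$A2) + head$b2)
  if (training && dropout > 0) {
    a2 <- a2 * (stats::rbinom(length(a2), 1L, keep) / keep)
  }
  scores <- as.vector(a2 %*% head$A3) + head$b3
  list(scores = scores, fused = fused)
}

# ---- internal compiled forward/backward used by training and Grad-CAM ----

# Precompute per-subject, per-pattern static quantities.
.compile_graphs <- function(graphs, patterns) {
  lapply(graphs$graphs, function(subj) {
    lapply(subj[patterns], function(g) {
      P <- propagation_operator(g$adjacency)
      list(P = P, PX = P %*% g$node_features)
    })
  })
}

# Full forward pass with cache. masks: NULL (eval) or list(m1, m2) already
# scaled by 1/keep.
.forward_compiled <- function(model, cg, masks = NULL) {
  patterns <- model$config$patterns
  branch_caches <- lapply(patterns, function(p) {
    w <- model$branches[[p]]
    PX <- cg[[p]]$PX
    Z1 <- PX %*% w$W0
    H1 <- .relu(Z1)
    PH1 <- cg[[p]]$P %*% H1
    Z2 <- PH1 %*% w$W1
    H2 <- .relu(Z2)
    amax <- apply(H2, 2L, which.max)
    f <- c(colMeans(H2), H2[cbind(amax, seq_len(ncol(H2)))])
    list(Z1 = Z1, H1 = H1, PH1 = PH1, Z2 = Z2, H2 = H2, amax = amax, f = f)
  })
  names(branch_caches) <- patterns
  fused <- unlist(lapply(branch_caches, `[[`, "f"), use.names = FALSE)
  h <- model$head
  z1 <- as.vector(fused %*% h$A1) + h$b1
  a1 <- .relu(z1)
  if (!is.null(masks)) a1 <- a1 * masks$m1
  z2 <- as.vector(a1 %*% h$A2) + h$b2
  a2 <- .relu(z2)
  if (!is.null(masks)) a2 <- a2 * masks$m2
  scores <- as.vector(a2 %*% h$A3) + h$b3
  list(scores = scores, fused = fused, branch = branch_caches,
       z1 = z1, a1 = a1, z2 = z2, a2 = a2, masks = masks)
}

.softmax <- function(s) { e <- exp(s - max(s)); e / sum(e) }

# Backward pass from dscores; returns gradient list mirroring the model and,
# for Grad-CAM, the per-branch gradient w.r.t. H2.
.backward_compiled <- function(model, cg, fw, dscores, want_dH2 = FALSE) {
  h <- model$head
  patterns <- model$config$patterns
  d <- model$config$conv_dim
  grads <- list(head = list(), branches = list())

  grads$head$A3 <- fw$a2 %o% dscores
  grads$head$b3 <- dscores
  da2 <- as.vector(h$A3 %*% dscores)
  if (!is.null(fw$masks)) da2 <- da2 * fw$masks$m2
  da2 <- da2 * (fw$z2 > 0)
  grads$head$A2 <- fw$a1 %o% da2
  grads$head$b2 <- da2
  da1 <- as.vector(h$A2 %*% da2)
  if (!is.null(fw$masks)) da1 <- da1 * fw$masks$m1
  da1 <- da1 * (fw$z1 > 0)
  grads$head$A1 <- fw$fused %o% da1
  grads$head$b1 <- da1
  dfused <- as.vector(h$A1 %*% da1)

  dH2_list <- if (want_dH2) vector("list", length(patterns)) else NULL
  off <- 0L
  for (bi in seq_along(patterns)) {
    p <- patterns[bi]
    bc <- fw$branch[[p]]
    df <- dfused[(off + 1L):(off + 2L * d)]
    off <- off + 2L * d
    dmean <- df[seq_len(d)]
    dmax <- df[d + seq_len(d)]
    n <- nrow(bc$H2)
    dH2 <- matrix(rep(dmean / n, each = n), n, d)
    dH2[cbind(bc$amax, seq_len(d))] <- dH2[cbind(bc$amax, seq_len(d))] + dmax
    if (want_dH2) dH2_list[[bi]] <- dH2
    dZ2 <- dH2 * (bc$Z2 > 0)
    w <- model$branches[[p]]
    gW1 <- crossprod(bc$PH1, dZ2)
    dH1 <- (cg[[p]]$P %*% dZ2) %*% t(w$W1)
    dZ1 <- dH1 * (bc$Z1 > 0)
    gW0 <- crossprod(cg[[p]]$PX, dZ1)
    grads$branches[[p]] <- list(W0 = gW0, W1 = gW1)
  }
  if (want_dH2) names(dH2_list) <- patterns
  list(grads = grads, dH2 = dH2_list)
}

#' Predict with a fitted multi-branch GCN
#'
#' Deterministic eval-mode forward pass (dropout off).
#'
#' @param object An `mfcp_model`.
#' @param graphs An `mfcp_graphs` object (or a single subject's named list
#'   of [pattern_graph()]s).
#' @param type `"prob"` (case-class probability), `"class"` (0/1 hard
#'   label) or `"score"` (matrix of the two unnormalized logits).
#' @param ... Unused.
#' @return Vector (prob/class) or matrix (score) over subjects.
#' @export
predict.mfcp_model <- function(object, graphs, type = c("prob", "class", "score"),
                               ...) {
  type <- match.arg(type)
  subj_list <- if (inherits(graphs, "mfcp_graphs")) graphs$graphs
               else list(graphs)
  patterns <- object$config$patterns
  cg_all <- lapply(subj_list, function(subj) {
    lapply(subj[patterns], function(g) {
      P <- propagation_operator(g$adjacency)
      list(P = P, PX = P %*% g$node_features)
    })
  })
  scores <- t(vapply(cg_all, function(cg) {
    .forward_compiled(object, cg)$scores
  }, numeric(2L)))
  colnames(scores) <- c("control", "case")
  switch(type,
         score = scores,
         prob = apply(scores, 1L, function(s) .softmax(s)[2L]),
         class = as.integer(apply(scores, 1L, which.max) == 2L))
}
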