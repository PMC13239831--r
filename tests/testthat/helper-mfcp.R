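# Shared fixtures, all generated in code. Heavier objects are memoised so
# several test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# random canonical adjacency (symmetric, non-negative, zero diagonal, max 1)
rand_canonical <- function(n, seed = 1L) {
  set.seed(seed)
  W <- matrix(runif(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W / max(W)
}

rand_pattern_graph <- function(n, pattern = "PC", seed = 1L,
                               features = NULL) {
  A <- connectivity_matrix(rand_canonical(n, seed), pattern,
                           canonical = TRUE)
  pattern_graph(A, node_features = features)
}

# small quick cohort: 8 ROIs, 10 per group, 120 time points
tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    simulate_cohort(mfcp_demo_config(n_rois = 8, n_subjects_per_group = 10,
                                     n_timepoints = 120, seed = 101))
  })
}

tiny_graphs <- function() {
  memo("tiny_graphs", function() {
    build_cohort_graphs(tiny_cohort(),
                        sr_cfg = sr_config(max_iterations = 200))
  })
}

fast_cfg <- function(seed = 1L, epochs = 25L) {
  train_config(epochs = epochs, seed = seed)
}

# the reference strong-effect study cohort and its graphs (desk scale)
demo_cohort <- function() {
  memo("demo_cohort", function() simulate_cohort(mfcp_demo_config(seed = 11)))
}

demo_graphs <- function() {
  memo("demo_graphs", function() build_cohort_graphs(demo_cohort()))
}
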