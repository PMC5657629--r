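# Shared fixtures, built once per test run.
#
# The cross-subject benchmark (5 classes x 8 subjects x 2 reps, odd
# subjects training) is used by several recognition and evaluation
# tests; it is expensive enough (~5 s) to be worth caching in the
# session.

.cache <- new.env(parent = emptyenv())

benchmark_fixture <- function() {
  if (is.null(.cache$bench)) {
    ds <- generate_dataset(default_templates(), n_subjects = 8,
                           reps_per_subject = 2, seed = 101)
    sp <- cross_subject_split(ds)
    fit <- suppressWarnings(action_knn(sp$train))
    .cache$bench <- list(ds = ds, split = sp, fit = fit)
  }
  .cache$bench
}

# a small random walk sequence on the default topology
random_sequence <- function(frames = 12, seed = 1, topology = default_topology()) {
  set.seed(seed)
  n <- length(topology$joint_names)
  coords <- array(stats::rnorm(frames * n * 3), c(frames, n, 3))
  skeleton_sequence(coords, topology, sequence_id = paste0("rnd", seed))
}

# minimal labelled descriptor index for KNN-level tests
toy_index <- function(n = 60, classes = c("a", "b", "c"), dim = 10,
                      seed = 42) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * dim), n, dim)
  info <- data.frame(
    frame = seq_len(n) - 1L,
    time_label = sample(0:29, n, replace = TRUE),
    action_label = sample(classes, n, replace = TRUE),
    source_id = paste0("s", sample(1:6, n, replace = TRUE)),
    subject_id = 1L,
    edge = FALSE,
    frame_confidence = 1,
    stringsAsFactors = FALSE)
  idx <- list(X = X, info = info,
              class_weights = class_weights(info$action_label),
              src_rank = match(info$source_id, sort(unique(info$source_id))),
              metric = "euclidean")
  class(idx) <- "training_index"
  idx
}
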