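brute_knn <- function(x, idx, K, window = NULL) {
  d <- sqrt(colSums((t(idx$X) - x)^2))
  if (!is.null(window))
    d[idx$info$time_label < window[1] | idx$info$time_label > window[2]] <- Inf
  order(d, idx$src_rank, idx$info$time_label)[seq_len(K)]
}

test_that("knn_query returns exact neighbours with deterministic ties", {
  idx <- toy_index(n = 60)
  q <- knn_query(idx$X[17, ], idx, K = 1)
  expect_identical(q$idx, 17L)
  expect_equal(q$dist, 0)

  all60 <- knn_query(idx$X[1, ], idx, K = 60)
  expect_setequal(all60$idx, 1:60)
  expect_true(!is.unsorted(all60$dist))
  expect_error(knn_query(idx$X[1, ], list(X = matrix(0, 0, 10)), K = 1),
               "empty")

  # exact ties broken by source id then time label
  X <- rbind(c(0, 0), c(1, 0), c(1, 0), c(1, 0))
  info <- data.frame(frame = 0:3, time_label = c(0L, 5L, 2L, 2L),
                     action_label = "a",
                     source_id = c("s1", "s3", "s2", "s2"),
                     stringsAsFactors = FALSE)
  tie <- list(X = X, info = info,
              src_rank = match(info$source_id, sort(unique(info$source_id))))
  got <- knn_query(c(0, 0), tie, K = 3)
  expect_identical(got$idx, c(1L, 3L, 4L))  # s2/t2 before s2/t2? then s3
})

test_that("knn_query agrees with the brute-force oracle", {
  idx <- toy_index(n = 300, dim = 10, seed = 7)
  set.seed(8)
  for (i in 1:50) {
    x <- stats::rnorm(10)
    for (K in c(1, 5, 20)) {
      expect_identical(knn_query(x, idx, K)$idx, brute_knn(x, idx, K))
    }
  }
})

test_that("time windows restrict neighbours and widen when too narrow", {
  idx <- toy_index(n = 100, seed = 3)
  x <- stats::rnorm(10)
  q <- knn_query(x, idx, K = 5, time_window = c(4, 6))
  expect_true(all(q$info$time_label >= 4 & q$info$time_label <= 6))
  expect_false(q$widened)
  expect_identical(q$idx, brute_knn(x, idx, 5, c(4, 6)))
  # impossible window must widen symmetrically until K fit
  lone <- idx
  lone$info$time_label <- c(rep(0L, 99), 50L)
  qw <- knn_query(x, lone, K = 2, time_window = c(50, 50), widen_step = 10)
  expect_true(qw$widened)
  expect_length(qw$idx, 2L)
})

test_that("time-label estimation is the binned neighbour mode", {
  # K = 1: exactly the nearest frame's label
  idx <- toy_index(n = 40, seed = 9)
  i <- 12
  e1 <- estimate_time_label(idx$X[i, ] + 1e-7, idx, K = 1)
  expect_identical(e1$T_i, idx$info$time_label[i])

  # mode of {10, 11, 10, 40, 10} is 10
  X <- matrix(seq(0, 0.4, by = 0.1), ncol = 1)
  info <- data.frame(frame = 0:4, time_label = c(10L, 11L, 10L, 40L, 10L),
                     action_label = "a", source_id = paste0("s", 1:5),
                     stringsAsFactors = FALSE)
  idx2 <- list(X = X, info = info, src_rank = 1:5)
  expect_identical(estimate_time_label(0.2, idx2, K = 5)$T_i, 10L)

  # ties go to the smaller label
  info$time_label <- c(3L, 3L, 7L, 7L, 40L)
  idx3 <- list(X = X, info = info, src_rank = 1:5)
  expect_identical(estimate_time_label(0.2, idx3, K = 4)$T_i, 3L)
})

test_that("segmented classification: degenerate cases and permutation
           invariance", {
  b <- benchmark_fixture()
  idx <- b$fit$index

  # single-class index -> that class with score 1
  keep <- idx$info$action_label == "wave"
  idx1 <- idx
  idx1$X <- idx$X[keep, , drop = FALSE]
  idx1$info <- idx$info[keep, , drop = FALSE]
  idx1$src_rank <- match(idx1$info$source_id,
                         sort(unique(idx1$info$source_id)))
  idx1$class_weights <- c(wave = 1)
  dec <- classify_segmented(idx$X[1:8, ], idx1)
  expect_identical(dec$label, "wave")
  expect_equal(unname(dec$scores[["wave"]]), 1)

  # permuting input frames cannot change the vote sums
  Q <- idx$X[41:60, ]
  d1 <- classify_segmented(Q, idx)
  d2 <- classify_segmented(Q[20:1, ], idx)
  expect_identical(d1$label, d2$label)
  expect_equal(sort(d1$votes), sort(d2$votes))

  expect_error(classify_segmented(idx$X[0, , drop = FALSE], idx),
               "no input frames")
})

test_that("stream gate: no decision before T_th, then fraction rule", {
  b <- benchmark_fixture()
  idx <- b$fit$index
  seqs <- b$split$test
  s <- seqs[[1]]
  sm <- gaussian_smooth(s)
  d <- build_descriptors(sm, estimate_bone_lengths(sm), b$fit$control)

  # huge T_th: the gate can never fire
  res <- classify_stream(d$X, idx, T_th = 10000)
  expect_identical(nrow(res$events), 0L)

  res2 <- classify_stream(d$X, idx, T_th = 15, alpha_dec = 0.5)
  if (nrow(res2$events)) {
    expect_true(all(res2$events$tally_frames > 15))
    expect_true(all(res2$events$fraction > 0.5))
  }
})

test_that("lowering alpha_dec never delays the first decision and
           raising T_th never accelerates it", {
  b <- benchmark_fixture()
  idx <- b$fit$index
  s <- b$split$test[[3]]
  sm <- gaussian_smooth(s)
  d <- build_descriptors(sm, estimate_bone_lengths(sm), b$fit$control)
  first_frame <- function(alpha, tth) {
    ev <- classify_stream(d$X, idx, T_th = tth, alpha_dec = alpha)$events
    if (nrow(ev)) ev$frame[1] else Inf
  }
  f_easy <- first_frame(0.3, 15)
  f_hard <- first_frame(0.7, 15)
  expect_lte(f_easy, f_hard)
  f_short <- first_frame(0.5, 10)
  f_long <- first_frame(0.5, 40)
  expect_lte(f_short, f_long)
})
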