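test_that("motion statistic equals the windowed population variance", {
  topo <- default_topology()
  # single monitored joint, known x-window 0..4, constant y,z
  coords <- array(0, c(5, 20, 3))
  coords[, 4, 1] <- 0:4                    # "head"
  s <- skeleton_sequence(coords, topo)
  pr <- motion_statistic(s, monitored_joints = "head", T_window = 5)
  expect_equal(unname(pr$S[3, ]), c(2, 0, 0))   # var{0..4} = 2

  # two joints with different variances average
  coords[, 6, 1] <- c(0, 2, 4, 6, 8) / sqrt(2)  # var = 4
  s2 <- skeleton_sequence(coords, topo)
  pr2 <- motion_statistic(s2, monitored_joints = c("head", "elbow_left"),
                          T_window = 5)
  expect_equal(unname(pr2$S[3, 1]), 3)

  # constant sequence: exactly zero everywhere
  sc <- skeleton_sequence(array(1.7, c(9, 20, 3)), topo)
  expect_true(all(motion_statistic(sc)$S == 0))
})

test_that("motion statistic matches a brute-force oracle on random windows", {
  topo <- default_topology()
  set.seed(31)
  for (case in 1:100) {
    nj <- sample(2:5, 1)
    joints <- sample(topo$joint_names[-1], nj)
    coords <- array(stats::rnorm(5 * 20 * 3), c(5, 20, 3))
    s <- skeleton_sequence(coords, topo)
    pr <- motion_statistic(s, monitored_joints = joints, T_window = 5)
    ji <- match(joints, topo$joint_names)
    oracle <- sapply(1:3, function(d) {
      mean(sapply(ji, function(j) {
        x <- coords[, j, d]
        mean(x^2) - mean(x)^2
      }))
    })
    expect_equal(unname(pr$S[3, ]), oracle, tolerance = 1e-12)
  }
})

test_that("motion statistic is translation invariant and scales as s^2", {
  s <- random_sequence(frames = 9, seed = 13)
  pr <- motion_statistic(s)
  s2 <- s; s2$coords <- s$coords + 5.5
  expect_equal(motion_statistic(s2)$S, pr$S, tolerance = 1e-9)
  s3 <- s; s3$coords <- s$coords * 2
  expect_equal(motion_statistic(s3)$S, 4 * pr$S, tolerance = 1e-9)
})

test_that("onset detection: idle yields none, Th = 0 fires immediately", {
  tpl <- default_templates()[["push"]]
  prof <- subject_profile(1, noise_sd = 1e-3)
  idle <- generate_action_sequence(tpl, prof, idle_prefix = 60,
                                   repetitions = 1, seed = 8)
  idle$coords <- idle$coords[1:50, , ]     # idle frames only
  pr <- motion_statistic(gaussian_smooth(idle))
  expect_true(is.na(detect_onset(pr, Th = 0.005)))
  expect_identical(detect_onset(pr, Th = 0), pr$interior[1L])
})

test_that("onset is recovered near the idle/action boundary", {
  tpl <- default_templates()
  for (i in 1:10) {
    prof <- with_seed(i, subject_profile(
      1, scale = stats::runif(1, 0.85, 1.25),
      speed = stats::runif(1, 0.9, 1.1)))
    s <- generate_action_sequence(tpl[[(i %% 5) + 1]], prof,
                                  idle_prefix = 30, seed = i)
    t0 <- detect_onset(motion_statistic(gaussian_smooth(s)), 0.005)
    expect_lte(abs(t0 - s$meta$ground_truth$onset), 3)
  }
})

test_that("regularization trims and re-bases deterministically", {
  s <- random_sequence(frames = 100, seed = 21)
  r <- regularize_sequence(s, t_start = 27)
  expect_identical(dim(r$coords)[1L], 73L)
  expect_identical(r$meta$regularization$t_start, 27)
  expect_identical(r$meta$regularization$new_frames, 0:72)
  expect_identical(r$coords[1, , ], s$coords[28, , ])
  r0 <- regularize_sequence(s, t_start = 0)
  expect_identical(r0$coords, s$coords)
  expect_error(regularize_sequence(s, NA_integer_), "no motion onset")
})

test_that("sequences without onset are excluded from training with a warning", {
  tpl <- default_templates()[1:2]
  ds <- generate_dataset(tpl, n_subjects = 2, reps_per_subject = 1, seed = 5)
  # one all-idle impostor
  idle <- ds$sequences[[1]]
  idle$coords <- idle$coords[rep(1, 40), , ] +
    with_seed(4, array(stats::rnorm(40 * 60, sd = 1e-3), c(40, 20, 3)))
  idle$sequence_id <- "idle_impostor"
  expect_warning(fit <- action_knn(c(ds$sequences, list(idle))),
                 "idle_impostor")
  expect_identical(fit$excluded, "idle_impostor")
})

test_that("class weights balance by inverse frequency", {
  labs <- c(rep("a", 30), rep("b", 10))
  w <- class_weights(labs)
  expect_equal(w[["a"]], 40 / (2 * 30))
  expect_equal(w[["b"]], 40 / (2 * 10))
  expect_equal(unname(class_weights(rep(c("x", "y"), 10))), c(1, 1))
})

test_that("frame confidence equals w(A) * K_t / K against a brute oracle", {
  idx <- toy_index(n = 60)
  out <- compute_frame_confidence(idx, K = 5)
  conf <- out$info$confidence
  w <- out$class_weights
  expect_true(all(conf >= 0 & conf <= max(w) + 1e-12))
  # brute-force recount
  for (i in seq_len(60)) {
    d <- sqrt(colSums((t(idx$X) - idx$X[i, ])^2))
    d[idx$info$source_id == idx$info$source_id[i]] <- Inf
    o <- order(d, idx$src_rank, idx$info$time_label)[1:5]
    K_t <- sum(idx$info$action_label[o] == idx$info$action_label[i])
    expect_equal(conf[i], w[[idx$info$action_label[i]]] * K_t / 5)
  }
  expect_error(compute_frame_confidence(toy_index(n = 4), K = 5), "K")
})

test_that("unanimous and partial neighbourhoods give the textbook values", {
  # 6 points: query's 5 nearest all share its class, w = 1
  X <- matrix(c(0, 0.1, 0.2, 0.3, 0.4, 0.5), ncol = 1)
  info <- data.frame(frame = 0:5, time_label = 0:5,
                     action_label = rep("a", 6),
                     source_id = paste0("s", 1:6), subject_id = 1,
                     edge = FALSE, frame_confidence = 1,
                     stringsAsFactors = FALSE)
  idx <- list(X = X, info = info, class_weights = c(a = 1),
              src_rank = 1:6)
  out <- compute_frame_confidence(idx, K = 5)
  expect_equal(out$info$confidence, rep(1, 6))

  # 3 of K=4 neighbours share the class -> 0.75 (w = 1 forced)
  info$action_label <- c("a", "a", "a", "a", "b", "b")
  idx2 <- list(X = X, info = info, class_weights = c(a = 1, b = 1),
               src_rank = 1:6)
  out2 <- compute_frame_confidence(idx2, K = 4)
  expect_equal(out2$info$confidence[1], 1 * 3 / 4)
})

test_that("idle rest frames earn less confidence than mid-action frames", {
  # the trailing idle frames of every training sequence are a rest pose
  # shared by all classes, so the confidence KNN must downweight them
  b <- benchmark_fixture()
  info <- b$fit$index$info
  last_label <- stats::ave(info$time_label, info$source_id, FUN = max)
  rest <- info$time_label >= last_label - 4
  mid <- info$time_label >= 10 & info$time_label <= 30
  expect_gt(mean(info$confidence[mid]), mean(info$confidence[rest]))
  expect_lt(mean(info$confidence[rest]), 0.6)
})
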