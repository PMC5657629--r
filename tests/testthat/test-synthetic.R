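test_that("generation is a pure function of template, profile and seed", {
  tpl <- default_templates()[["kick"]]
  prof <- subject_profile(3, scale = 1.1, speed = 0.95)
  a <- generate_action_sequence(tpl, prof, seed = 77)
  b <- generate_action_sequence(tpl, prof, seed = 77)
  expect_identical(a$coords, b$coords)
  c2 <- generate_action_sequence(tpl, prof, seed = 78)
  expect_false(identical(a$coords, c2$coords))
})

test_that("noise-free idle prefixes are exactly constant", {
  tpl <- default_templates()[["wave"]]
  s <- generate_action_sequence(tpl, subject_profile(1), idle_prefix = 30,
                                seed = 2, noise_sd = 0)
  for (t in 2:30)
    expect_identical(s$coords[t, , ], s$coords[1, , ])
  # first action frame starts at the idle pose (continuity at onset)
  expect_equal(s$coords[31, , ], s$coords[30, , ], tolerance = 1e-12)
})

test_that("ground truth anatomy: onset, labels, segments, repetitions", {
  tpl <- default_templates()[["push"]]
  s <- generate_action_sequence(tpl, subject_profile(1), idle_prefix = 25,
                                idle_gap = 8, repetitions = 2, seed = 4)
  gt <- s$meta$ground_truth
  expect_identical(gt$onset, 25L)
  expect_identical(nrow(gt$segments), 2L)
  expect_identical(gt$segments$start[1], 25L)
  expect_true(all(is.na(gt$labels[1:25])))
  expect_identical(gt$labels[26], 0L)
  # second performance begins after the gap
  expect_identical(gt$segments$start[2],
                   gt$segments$end[1] + 8L + 1L)
})

test_that("dataset counts, balance, and split disjointness", {
  ds <- generate_dataset(default_templates(), n_subjects = 8,
                         reps_per_subject = 2, seed = 6)
  expect_length(ds$sequences, 80L)
  labs <- sapply(ds$sequences, function(s) s$action_label)
  expect_true(all(table(labs) == 16L))
  sp <- cross_subject_split(ds)
  tr <- unique(sapply(sp$train, function(s) s$subject_id))
  te <- unique(sapply(sp$test, function(s) s$subject_id))
  expect_length(intersect(tr, te), 0L)
  expect_identical(sort(c(tr, te)), 1:8)
  # reproducible end to end
  ds2 <- generate_dataset(default_templates(), n_subjects = 8,
                          reps_per_subject = 2, seed = 6)
  expect_identical(ds$sequences[[37]]$coords, ds2$sequences[[37]]$coords)
})

test_that("push and pull traverse the same pose path in opposite order", {
  tpl <- default_templates()
  prof <- subject_profile(1, noise_sd = 0, speed = 1)
  a <- generate_action_sequence(tpl$push, prof, idle_prefix = 0,
                                idle_suffix = 0, seed = 1, noise_sd = 0)
  b <- generate_action_sequence(tpl$pull, prof, idle_prefix = 0,
                                idle_suffix = 0, seed = 1, noise_sd = 0)
  nf <- dim(a$coords)[1]
  expect_equal(b$coords, a$coords[nf:1, , , drop = FALSE],
               tolerance = 1e-12)
})

test_that("idle variance sits far below Th and action variance above", {
  tpl <- default_templates()
  for (nm in names(tpl)) {
    s <- generate_action_sequence(tpl[[nm]], subject_profile(1), seed = 9)
    pr <- motion_statistic(gaussian_smooth(s))
    idle_peak <- max(apply(pr$S[3:26, ], 1, min))
    act_typ <- stats::median(apply(pr$S[35:65, ], 1, min))
    expect_lt(idle_peak, 0.005 / 10)
    expect_gt(act_typ, 0.005)
  }
})

test_that("streams concatenate ground truth with correct offsets", {
  ds <- generate_dataset(default_templates()[1:3], n_subjects = 2,
                         reps_per_subject = 1, seed = 12)
  st <- generate_stream(ds$sequences[1:3])
  nf <- sum(sapply(ds$sequences[1:3], function(s) dim(s$coords)[1]))
  expect_identical(dim(st$coords)[1L], nf)
  gt <- st$meta$ground_truth
  expect_identical(length(gt$frame_class), nf)
  expect_identical(nrow(gt$segments), 3L)
  seg <- gt$segments
  for (r in 1:3) {
    expect_identical(unique(gt$frame_class[(seg$start[r]:seg$end[r]) + 1]),
                     seg$class[r])
  }
})

test_that("seed mixing is deterministic, coordinate-sensitive and in range", {
  expect_identical(mix_seed(1, 2, 3), mix_seed(1, 2, 3))
  expect_false(mix_seed(1, 2, 3) == mix_seed(1, 3, 2))
  expect_false(mix_seed(7) == mix_seed(8))
  s <- sapply(1:500, function(i) mix_seed(42, i))
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(anyDuplicated(s), 0L)
})
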