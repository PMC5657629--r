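constant_sequence <- function(frames = 11) {
  topo <- default_topology()
  pose <- matrix(stats::rnorm(60), 20, 3)
  coords <- aperm(array(pose, c(20, 3, frames)), c(3, 1, 2))
  skeleton_sequence(coords, topo)
}

test_that("gaussian smoothing preserves constants and affine ramps", {
  set.seed(5)
  s <- constant_sequence()
  sm <- gaussian_smooth(s)
  expect_equal(sm$coords, s$coords, tolerance = 1e-12)
  expect_identical(sm$meta$smoothing$group_delay, 2L)

  # linear ramp: interior frames are unchanged by a symmetric kernel
  ramp <- random_sequence(frames = 9, seed = 2)
  b <- stats::rnorm(1)
  ramp$coords[] <- rep(0:8 * b, times = 60)
  smr <- gaussian_smooth(ramp)
  expect_equal(smr$coords[3:7, , ], ramp$coords[3:7, , ], tolerance = 1e-12)

  expect_error(gaussian_smooth(s, width = 4), "odd")
  expect_error(gaussian_smooth(random_sequence(frames = 3), width = 5),
               "does not fit")
})

test_that("unit impulse reproduces the normalized 5-tap sigma-1 kernel", {
  s <- constant_sequence(frames = 21)
  s$coords[] <- 0
  s$coords[11, 1, 1] <- 1
  sm <- gaussian_smooth(s, width = 5, sigma = 1)
  k <- exp(-((-2:2)^2) / 2)
  k <- k / sum(k)
  expect_equal(sm$coords[9:13, 1, 1], k, tolerance = 1e-12)
  expect_equal(sum(sm$coords[, 1, 1]), 1, tolerance = 1e-12)
})

test_that("hip-relative normalization maps the hip to the origin and
           cancels uniform scale", {
  s <- random_sequence(frames = 6, seed = 9)
  topo <- s$topology
  topo$hip_segment_length <- 0.5
  rel <- to_relative_normalized(s, topo, eta = 1)
  expect_true(all(abs(rel$coords[, topo$hip_center, ]) < 1e-14))

  # worked example: hip (1,1,1), joint (1,2,1), L = 0.5, eta = 1 -> (0,2,0)
  s2 <- s
  s2$coords[1, topo$hip_center, ] <- c(1, 1, 1)
  s2$coords[1, 2, ] <- c(1, 2, 1)
  rel2 <- to_relative_normalized(s2, topo, eta = 1)
  expect_equal(rel2$coords[1, 2, ], c(0, 2, 0))

  # uniform scaling of coordinates and L leaves the result unchanged
  s3 <- s
  s3$coords <- s$coords * 3.7
  topo3 <- topo
  topo3$hip_segment_length <- topo$hip_segment_length * 3.7
  expect_equal(to_relative_normalized(s3, topo3, 1)$coords, rel$coords,
               tolerance = 1e-12)

  topo$hip_segment_length <- -1
  expect_error(to_relative_normalized(s, topo), "positive")
})

test_that("finite differences match the closed forms of the stencil", {
  topo <- default_topology()
  frames <- 12
  t0 <- 0:(frames - 1)
  for (rep in 1:5) {
    set.seed(rep)
    a <- stats::rnorm(1); b <- stats::rnorm(1); c2 <- stats::rnorm(1)
    coords <- array(0, c(frames, 20, 3))
    coords[, , 1] <- a + b * t0            # linear in x
    coords[, , 2] <- c2 * t0^2             # quadratic in y
    s <- skeleton_sequence(coords, topo)
    fd <- finite_differences(s)
    int <- 3:(frames - 2)
    expect_equal(fd$d1[int, 1, 1], rep(2 * b, length(int)), tolerance = 1e-9)
    expect_equal(fd$d2[int, 1, 1], rep(0, length(int)), tolerance = 1e-9)
    expect_equal(fd$d1[int, 1, 2], 2 * c2 * 2 * t0[int],  # P' = 4 c t
                 tolerance = 1e-9)
    expect_equal(fd$d2[int, 1, 2], rep(8 * c2, length(int)), tolerance = 1e-9)
  }
})

test_that("hand-worked stencil example: series 0,1,4,9,16", {
  topo <- default_topology()
  coords <- array(0, c(5, 20, 3))
  coords[, 1, 1] <- c(0, 1, 4, 9, 16)
  fd <- finite_differences(skeleton_sequence(coords, topo))
  expect_equal(fd$d1[3, 1, 1], 8)          # 9 - 1
  expect_equal(fd$d2[3, 1, 1], 8)          # 16 + 0 - 2*4
  expect_identical(fd$interior, c(2L, 2L))
})

test_that("angular kinematics divide by the joint's bone length", {
  topo <- default_topology()
  d1 <- array(0, c(5, 20, 3)); d1[3, 2, ] <- c(8, 0, 0)
  d2 <- array(0, c(5, 20, 3))
  topo$bone_lengths[] <- 2
  ak <- angular_kinematics(d1, d2, topo)
  expect_equal(ak$omega[3, 2, ], c(4, 0, 0))
  expect_true(all(ak$alpha == 0, na.rm = TRUE))
  topo$bone_lengths[3] <- 0
  expect_error(angular_kinematics(d1, d2, topo), "positive")
})

test_that("select_joints keeps order, d_i, and rejects unknown names", {
  s <- random_sequence(frames = 6, seed = 11)
  all20 <- select_joints(s, s$topology$joint_names)
  expect_identical(all20$coords, s$coords)
  sub <- select_joints(s, c("head", "hand_left", "hand_right",
                            "foot_left", "foot_right"))
  expect_identical(dim(sub$coords)[2L], 5L)
  expect_identical(sub$topology$joint_names[1L], "head")
  expect_equal(sub$topology$bone_lengths[["head"]],
               s$topology$bone_lengths[["head"]])
  expect_error(select_joints(s, "flipper"), "unknown joint")
})

test_that("descriptor layout: 9 entries per selected joint, zeros when frozen", {
  s <- constant_sequence(frames = 8)
  ctl <- action_knn_control(selected_joints = c(
    "head", "hand_left", "hand_right", "elbow_left", "elbow_right",
    "knee_left", "knee_right", "foot_left"))
  d <- build_descriptors(gaussian_smooth(s), default_topology(), ctl)
  expect_identical(ncol(d$X), 72L)         # 9 * 8
  expect_identical(nrow(d$X), 4L)          # edges dropped
  # frozen pose: omega and alpha blocks vanish, pose block does not
  expect_true(all(abs(d$X[, 25:72]) < 1e-10))
  expect_gt(max(abs(d$X[, 1:24])), 0)
})

test_that("descriptors are invariant to body scale and translation", {
  tpl <- default_templates()[["twist"]]
  base <- subject_profile(1, scale = 1, noise_sd = 0)
  big <- subject_profile(2, scale = 1.5, noise_sd = 0)
  ctl <- action_knn_control()
  desc_of <- function(prof, shift = 0) {
    s <- generate_action_sequence(tpl, prof, seed = 5, noise_sd = 0)
    s$coords <- s$coords + shift
    sm <- gaussian_smooth(s)
    build_descriptors(sm, estimate_bone_lengths(sm), ctl)$X
  }
  X1 <- desc_of(base)
  X2 <- desc_of(big)
  expect_equal(X2, X1, tolerance = 1e-9)
  X3 <- desc_of(base, shift = 11.3)
  expect_equal(X3, X1, tolerance = 1e-9)
})
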