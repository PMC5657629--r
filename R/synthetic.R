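#' Define a synthetic action template
#'
#' An action template is a sinusoidal joint-angle program on the
#' kinematic chain: each listed joint carries an amplitude 3-vector (the
#' peak rotation in radians about the x, y and z axes of its parent
#' frame), a frequency in cycles per performance, and a phase.  The
#' `direction` sign plays the pose path forwards or backwards: with
#' zero phase and integer frequencies the two directions traverse the
#' identical set of poses, so a template and its reversal (think push
#' versus pull) are distinguishable only through velocity and
#' acceleration — exactly the situation the angular descriptor is built
#' for.  Sinusoids keep the motion band-limited, which the five-frame
#' derivative stencil assumes.
#'
#' @param class_id character class label.
#' @param moves named list: for each actuated joint, a list with `amp`
#'   (length-3 numeric, radians), and optionally `freq` (default 1) and
#'   `phase` (default 0).
#' @param duration nominal number of frames of one performance (>= 5).
#' @param direction +1 or -1; -1 time-reverses the pose path.
#' @return An object of class `action_template`.
#' @export
action_template <- function(class_id, moves, duration = 40L,
                            direction = 1L) {
  if (duration < 5L) stop("duration must be at least 5 frames")
  if (!length(moves)) stop("a template needs at least one actuated joint")
  moves <- lapply(moves, function(m) {
    m$amp <- as.numeric(m$amp)
    if (length(m$amp) != 3L) stop("each move needs an amplitude 3-vector")
    if (is.null(m$freq)) m$freq <- 1
    if (is.null(m$phase)) m$phase <- 0
    m
  })
  if (all(vapply(moves, function(m) all(m$amp == 0), logical(1))))
    stop("at least one joint must have nonzero amplitude")
  structure(list(class_id = as.character(class_id), moves = moves,
                 duration = as.integer(duration),
                 direction = sign(direction)),
            class = "action_template")
}

#' Reverse the direction of an action template
#'
#' @param template an [action_template()].
#' @param class_id label for the reversed class.
#' @return The reversed template.
#' @export
reverse_template <- function(template, class_id = paste0(template$class_id,
                                                         "_rev")) {
  template$direction <- -template$direction
  template$class_id <- as.character(class_id)
  template
}

#' Subject profile for the synthetic generator
#'
#' Captures the between-subject variation the method is supposed to
#' absorb: a global skeleton scale, small per-bone length jitter, a
#' speed factor near 1 (the method assumes subjects perform the same
#' action at similar speeds), and the sensor noise level.
#'
#' @param subject_id integer id.
#' @param scale global bone-length scale (> 0).
#' @param speed speed factor; one performance takes
#'   `round(duration / speed)` frames.
#' @param noise_sd standard deviation of additive isotropic Gaussian
#'   jitter on every coordinate.
#' @param bone_jitter length-20 multiplicative per-bone perturbation
#'   (e.g. in ±5%), applied on top of `scale`.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, scale = 1, speed = 1,
                            noise_sd = 0.002, bone_jitter = rep(0, 20L)) {
  if (scale <= 0) stop("scale must be positive")
  structure(list(subject_id = subject_id, scale = scale, speed = speed,
                 noise_sd = noise_sd, bone_jitter = bone_jitter),
            class = "subject_profile")
}

# joint angles (20 x 3) of a template at normalized phase u in [0, 1];
# multiple components for the same joint (duplicate names) add up
.template_angles <- function(template, u, joint_names) {
  th <- matrix(0, length(joint_names), 3L,
               dimnames = list(joint_names, NULL))
  if (template$direction < 0) u <- 1 - u
  nms <- names(template$moves)
  for (i in seq_along(template$moves)) {
    m <- template$moves[[i]]
    th[nms[i], ] <- th[nms[i], ] +
      m$amp * sin(2 * pi * m$freq * u + m$phase)
  }
  th
}

# forward kinematics: joint positions (n x 3) for local rotation angles
.fk_pose <- function(angles, topology, offsets) {
  n <- nrow(offsets)
  pos <- matrix(0, n, 3L)
  Racc <- vector("list", n)
  for (j in seq_len(n)) {
    pa <- topology$parents[j]
    Rloc <- if (any(angles[j, ] != 0)) rot3(angles[j, ]) else diag(3L)
    if (pa == j) {
      pos[j, ] <- 0
      Racc[[j]] <- Rloc
    } else {
      pos[j, ] <- pos[pa, ] + as.numeric(Racc[[pa]] %*% offsets[j, ])
      Racc[[j]] <- Racc[[pa]] %*% Rloc
    }
  }
  pos
}

#' Generate one synthetic action sequence with ground truth
#'
#' Drives the 20-joint kinematic chain with the template's joint-angle
#' program, scaled by the subject profile: an idle prefix frozen at the
#' rest pose, `repetitions` performances separated by short idle gaps,
#' and an idle suffix, all overlaid with Gaussian sensor jitter.  The
#' same (template, profile, seed) triple always produces a bitwise
#' identical sequence.
#'
#' @param template an [action_template()].
#' @param profile a [subject_profile()].
#' @param idle_prefix,idle_suffix,idle_gap idle frame counts before,
#'   after and between performances.
#' @param repetitions number of performances in the sequence.
#' @param seed integer seed for the jitter.
#' @param noise_sd overrides the profile's noise level when given.
#' @return A [skeleton_sequence()] whose `meta$ground_truth` records the
#'   0-based `onset` (first active frame), per-frame regularized
#'   `labels` (frame − onset, `NA` before onset), the logical `active`
#'   mask, the active `segments` (data.frame of 0-based start/end), and
#'   the `class`.
#' @export
generate_action_sequence <- function(template, profile,
                                     idle_prefix = 30L, idle_suffix = 10L,
                                     idle_gap = 10L, repetitions = 1L,
                                     seed = 1L, noise_sd = NULL) {
  idle_prefix <- as.integer(idle_prefix)
  idle_suffix <- as.integer(idle_suffix)
  idle_gap <- as.integer(idle_gap)
  topo <- make_topology()
  k <- .kinect20
  lengths <- k$lengths * profile$scale * (1 + profile$bone_jitter)
  offsets <- k$directions * lengths
  perf_len <- max(5L, as.integer(round(template$duration / profile$speed)))
  blocks <- list(rep(NA_real_, idle_prefix))
  for (r in seq_len(repetitions)) {
    blocks[[length(blocks) + 1L]] <- seq(0, 1, length.out = perf_len)
    if (r < repetitions)
      blocks[[length(blocks) + 1L]] <- rep(NA_real_, idle_gap)
  }
  blocks[[length(blocks) + 1L]] <- rep(NA_real_, idle_suffix)
  u <- unlist(blocks)
  nf <- length(u)
  coords <- array(0, c(nf, 20L, 3L))
  rest <- .fk_pose(matrix(0, 20L, 3L), topo, offsets)
  for (t in seq_len(nf)) {
    coords[t, , ] <- if (is.na(u[t])) rest
    else .fk_pose(.template_angles(template, u[t], topo$joint_names),
                  topo, offsets)
  }
  sdn <- if (is.null(noise_sd)) profile$noise_sd else noise_sd
  if (sdn > 0)
    coords <- coords + with_seed(seed, array(stats::rnorm(length(coords),
                                                          sd = sdn),
                                             dim(coords)))
  onset <- idle_prefix
  active <- !is.na(u)
  seg_starts <- which(active & !c(FALSE, active[-nf]))
  seg_ends <- which(active & !c(active[-1L], FALSE))
  topo$bone_lengths <- c(NA_real_, lengths[-1L])
  names(topo$bone_lengths) <- topo$joint_names
  topo$hip_segment_length <- topo$bone_lengths[[topo$hip_segment_joint]]
  skeleton_sequence(
    coords, topo,
    subject_id = profile$subject_id,
    action_label = template$class_id,
    sequence_id = sprintf("%s_s%02d_seed%d", template$class_id,
                          as.integer(profile$subject_id), as.integer(seed)),
    meta = list(ground_truth = list(
      onset = onset,
      labels = ifelse(seq_len(nf) - 1L >= onset,
                      seq_len(nf) - 1L - onset, NA_integer_),
      active = active,
      segments = data.frame(start = seg_starts - 1L, end = seg_ends - 1L),
      class = template$class_id)))
}

#' Default five-class synthetic benchmark templates
#'
#' Five whole-body action programs exercising the properties the method
#' relies on: `push` and `pull` share the identical pose path and differ
#' only in direction (they are separable only through the angular
#' velocity/acceleration blocks); `wave`, `kick` and `twist` differ in
#' which joints move, about which axes, and at which frequencies.  All
#' templates actuate joints about several axes so the onset detector's
#' minimum-dimension criterion is meaningful; angular speeds are a few
#' tenths of a radian per frame, deliberately vigorous so the
#' action-segment motion statistic sits well above the idle noise
#' floor.
#'
#' @param duration nominal frames per performance.
#' @return Named list of five [action_template()]s.
#' @export
default_templates <- function(duration = 40L) {
  # every class carries a whole-body sway at the root (people shift
  # their trunk while acting); two components at different frequencies
  # keep the sway's velocity nulls from ever coinciding, so all three
  # dimensions of the motion statistic stay excited throughout a
  # performance
  sway <- function(a1, f1, a2, f2) list(
    hip_center = list(amp = a1, freq = f1),
    hip_center = list(amp = a2, freq = f2))
  push <- action_template("push", duration = duration, moves = c(
    sway(c(0.28, 0.26, 0.24), 2, c(0.18, 0.20, 0.16), 3), list(
    spine          = list(amp = c(0.90, 1.10, 1.20), freq = 2),
    shoulder_left  = list(amp = c(1.60, 1.10, 1.80), freq = 3),
    shoulder_right = list(amp = c(1.60, -1.10, -1.80), freq = 3),
    elbow_left     = list(amp = c(1.10, 0.80, 1.20), freq = 4),
    elbow_right    = list(amp = c(1.10, -0.80, -1.20), freq = 4),
    hip_left       = list(amp = c(0.80, 0.70, 1.00), freq = 2),
    hip_right      = list(amp = c(0.80, -0.70, -1.00), freq = 2),
    knee_left      = list(amp = c(1.00, 0.40, 0.50), freq = 3),
    knee_right     = list(amp = c(1.00, -0.40, -0.50), freq = 3))))
  pull <- reverse_template(push, "pull")
  wave <- action_template("wave", duration = duration, moves = c(
    sway(c(0.24, 0.28, 0.26), 3, c(0.20, 0.16, 0.18), 2), list(
    shoulder_center = list(amp = c(0.70, 0.90, 0.60), freq = 2),
    shoulder_left   = list(amp = c(0.80, 1.70, 1.60), freq = 3),
    shoulder_right  = list(amp = c(0.80, -1.70, 1.60), freq = 4),
    elbow_left      = list(amp = c(1.40, 0.80, 1.10), freq = 4),
    elbow_right     = list(amp = c(1.40, -0.80, 1.10), freq = 3),
    hip_left        = list(amp = c(0.60, 0.60, 0.70), freq = 2),
    hip_right       = list(amp = c(0.60, -0.60, 0.70), freq = 2))))
  kick <- action_template("kick", duration = duration, moves = c(
    sway(c(0.26, 0.24, 0.28), 2, c(0.16, 0.18, 0.20), 3), list(
    spine          = list(amp = c(0.60, 1.10, 0.90), freq = 2),
    hip_left       = list(amp = c(1.70, 1.00, 1.50), freq = 3),
    hip_right      = list(amp = c(1.70, -1.00, -1.50), freq = 3,
                          phase = pi),
    knee_left      = list(amp = c(1.40, 0.80, 1.10), freq = 4),
    knee_right     = list(amp = c(1.40, -0.80, -1.10), freq = 4,
                          phase = pi),
    shoulder_left  = list(amp = c(0.70, 0.60, 0.80), freq = 2),
    shoulder_right = list(amp = c(0.70, -0.60, -0.80), freq = 2))))
  twist <- action_template("twist", duration = duration, moves = c(
    sway(c(0.22, 0.26, 0.28), 3, c(0.18, 0.20, 0.14), 2), list(
    spine          = list(amp = c(0.50, 1.80, 0.70), freq = 2),
    shoulder_left  = list(amp = c(1.00, 0.90, 1.50), freq = 3),
    shoulder_right = list(amp = c(1.00, 0.90, -1.50), freq = 3),
    hip_left       = list(amp = c(0.90, 0.80, 0.70), freq = 4),
    hip_right      = list(amp = c(0.90, 0.80, -0.70), freq = 4),
    knee_left      = list(amp = c(0.80, 0.40, 0.60), freq = 2),
    knee_right     = list(amp = c(0.80, 0.40, -0.60), freq = 2))))
  list(push = push, pull = pull, wave = wave, kick = kick, twist = twist)
}

#' Generate a labelled synthetic benchmark dataset
#'
#' Builds the full cross-subject benchmark: for every template x subject
#' x repetition a sequence is generated with the subject's scale, bone
#' jitter, speed factor and noise, under a seed derived from the master
#' seed and the (class, subject, repetition) coordinates, so the dataset
#' is a pure function of its arguments.  Subject profiles draw a global
#' scale in \[0.85, 1.25\], per-bone jitter in ±5%, and a speed factor
#' in \[0.9, 1.1\].
#'
#' @param templates list of [action_template()]s (>= 2).
#' @param n_subjects number of subjects (>= 2).
#' @param reps_per_subject sequences per (class, subject).
#' @param seed master seed.
#' @param noise_sd sensor jitter standard deviation.
#' @param idle_prefix,idle_suffix idle padding per sequence.
#' @return An object of class `synthetic_dataset`: `sequences` (list of
#'   [skeleton_sequence()]), `profiles`, `templates`, `seed`, and
#'   `split` metadata (odd subjects as default training side).
#' @export
generate_dataset <- function(templates, n_subjects = 8L,
                             reps_per_subject = 2L, seed = 1L,
                             noise_sd = 0.002, idle_prefix = 30L,
                             idle_suffix = 10L) {
  if (length(templates) < 2L) stop("need at least 2 templates")
  if (n_subjects < 2L) stop("need at least 2 subjects")
  profiles <- lapply(seq_len(n_subjects), function(s) {
    with_seed(mix_seed(seed, 9001, s), subject_profile(
      subject_id = s,
      scale = stats::runif(1, 0.85, 1.25),
      speed = stats::runif(1, 0.9, 1.1),
      noise_sd = noise_sd,
      bone_jitter = stats::runif(20L, -0.05, 0.05)))
  })
  seqs <- list()
  for (ci in seq_along(templates)) for (s in seq_len(n_subjects))
    for (r in seq_len(reps_per_subject)) {
      sq <- generate_action_sequence(
        templates[[ci]], profiles[[s]],
        idle_prefix = idle_prefix, idle_suffix = idle_suffix,
        seed = mix_seed(seed, ci, s, r))
      sq$sequence_id <- sprintf("%s_s%02d_r%d",
                                templates[[ci]]$class_id, s, r)
      seqs[[length(seqs) + 1L]] <- sq
    }
  subjects <- seq_len(n_subjects)
  structure(list(sequences = seqs, profiles = profiles,
                 templates = templates, seed = seed,
                 split = list(train_subjects = subjects[subjects %% 2L == 1L],
                              test_subjects = subjects[subjects %% 2L == 0L])),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic action dataset:", length(x$sequences), "sequences,",
      length(x$templates), "classes,", length(x$profiles), "subjects",
      "(seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Concatenate sequences into an unsegmented stream with ground truth
#'
#' Joins the given sequences (typically one subject's test recordings,
#' so the skeleton is consistent throughout) end to end; each
#' sequence's own idle prefix/suffix becomes the idle gap between
#' actions.  The stream's ground truth carries the per-frame class (`NA`
#' during idle), the active mask, and the segment table with classes and
#' 0-based frame ranges.
#'
#' @param sequences list of [skeleton_sequence()] from one subject.
#' @return A [skeleton_sequence()] with `meta$ground_truth` as above.
#' @export
generate_stream <- function(sequences) {
  if (!length(sequences)) stop("no sequences to concatenate")
  coords <- do.call(abind_frames,
                    lapply(sequences, function(s) s$coords))
  cls <- character(0); active <- logical(0); segs <- list(); off <- 0L
  for (s in sequences) {
    gt <- s$meta$ground_truth
    nf <- n_frames(s)
    a <- if (!is.null(gt)) gt$active else rep(TRUE, nf)
    active <- c(active, a)
    cls <- c(cls, ifelse(a, as.character(s$action_label), NA_character_))
    if (!is.null(gt)) {
      sg <- gt$segments
      sg$start <- sg$start + off; sg$end <- sg$end + off
      sg$class <- as.character(s$action_label)
      segs[[length(segs) + 1L]] <- sg
    }
    off <- off + nf
  }
  skeleton_sequence(
    coords, sequences[[1L]]$topology,
    subject_id = sequences[[1L]]$subject_id,
    sequence_id = paste0("stream_s",
                         as.integer(sequences[[1L]]$subject_id)),
    meta = list(ground_truth = list(
      frame_class = cls, active = active,
      segments = if (length(segs)) do.call(rbind, segs) else NULL)))
}

abind_frames <- function(...) {
  arrs <- list(...)
  nf <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1)))
  out <- array(NA_real_, c(nf, dim(arrs[[1L]])[2L], 3L))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}
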