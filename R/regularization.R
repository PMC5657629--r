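#' Sliding-window motion statistic S(t)
#'
#' For each frame, computes per coordinate dimension the population
#' variance of each monitored joint's positions over the centred
#' `T`-frame window, averaged over the monitored joints:
#' `S_d(t) = (1/m) * sum_i [ mean(P_{i,d}^2) - mean(P_{i,d})^2 ]`.
#' `S(t)` is a 3-vector describing how much the limbs and head fluctuate
#' around frame `t`; idle frames produce values on the order of the
#' squared sensor noise, moving frames values orders of magnitude
#' larger.  It is translation invariant and scales as `s^2` under
#' coordinate scaling by `s`, so the onset threshold is in squared
#' coordinate units.  Boundary frames (where the window does not fit)
#' copy the nearest interior value.
#'
#' @param seq a (smoothed) [skeleton_sequence()] in absolute coordinates.
#' @param monitored_joints joint names to monitor; default the
#'   head-and-limbs descriptor subset.
#' @param T_window odd window length (default 5).
#' @param rms if `TRUE` return the square root of the variance.
#' @return Object of class `motion_profile`: matrix `S` (frames x 3),
#'   the window, monitored joints, and the 0-based interior frame range.
#' @export
motion_statistic <- function(seq, monitored_joints = NULL, T_window = 5L,
                             rms = FALSE) {
  if (T_window %% 2L == 0L) stop("the window length T must be odd")
  nf <- n_frames(seq)
  if (nf < T_window)
    stop("sequence shorter than the motion-statistic window")
  if (is.null(monitored_joints)) {
    monitored_joints <- intersect(default_selected_joints(),
                                  seq$topology$joint_names)
    if (!length(monitored_joints)) monitored_joints <- seq$topology$joint_names
  }
  idx <- joint_index(seq$topology, monitored_joints)
  P <- seq$coords[, idx, , drop = FALSE]
  m <- length(idx)
  h <- (T_window - 1L) %/% 2L
  int <- (h + 1L):(nf - h)                 # 1-based interior
  flat <- matrix(P, nrow = nf)             # nf x (m*3)
  win_mean <- function(x) {
    cs <- rbind(0, apply(x, 2L, cumsum))
    (cs[int + h + 1L, , drop = FALSE] - cs[int - h, , drop = FALSE]) / T_window
  }
  m1 <- win_mean(flat)
  m2 <- win_mean(flat^2)
  v <- pmax(m2 - m1^2, 0)                  # interior x (m*3)
  dim(v) <- c(length(int), m, 3L)
  S_int <- apply(v, c(1L, 3L), mean)
  if (rms) S_int <- sqrt(S_int)
  S <- matrix(NA_real_, nf, 3L, dimnames = list(NULL, c("x", "y", "z")))
  S[int, ] <- S_int
  S[seq_len(h), ] <- rep(S_int[1L, ], each = h)
  S[(nf - h + 1L):nf, ] <- rep(S_int[nrow(S_int), ], each = h)
  structure(list(S = S, T_window = as.integer(T_window),
                 monitored_joints = monitored_joints,
                 interior = c(h, nf - h - 1L), rms = isTRUE(rms)),
            class = "motion_profile")
}

#' @export
print.motion_profile <- function(x, ...) {
  cat("Motion profile:", nrow(x$S), "frames, window T =", x$T_window,
      ",", length(x$monitored_joints), "monitored joints\n")
  invisible(x)
}

#' Plot a motion profile with its onset threshold
#'
#' @param x a `motion_profile`.
#' @param Th threshold drawn as a horizontal line.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.motion_profile <- function(x, Th = 0.005, ...) {
  graphics::matplot(seq_len(nrow(x$S)) - 1L, x$S, type = "l", lty = 1,
                    xlab = "frame", ylab = "S(t)", ...)
  graphics::abline(h = Th, lty = 2)
  t0 <- detect_onset(x, Th)
  if (!is.na(t0)) graphics::abline(v = t0, col = "grey40", lty = 3)
  invisible(x)
}

#' Detect the motion onset frame
#'
#' The action is considered to begin at the first interior frame whose
#' minimum per-dimension motion statistic exceeds the threshold:
#' `T_start = min { t : min_d S_d(t) > Th }`.  Requiring all three
#' dimensions to fluctuate rejects pure sensor jitter (isotropic but
#' tiny) as well as one-dimensional drift.
#'
#' @param profile a `motion_profile` from [motion_statistic()].
#' @param Th onset threshold in squared coordinate units (or coordinate
#'   units when the profile was built with `rms = TRUE`).
#' @return 0-based onset frame index, or `NA` when the sequence never
#'   becomes active.
#' @export
detect_onset <- function(profile, Th = 0.005) {
  int <- (profile$interior[1L]:profile$interior[2L]) + 1L  # 1-based
  active <- apply(profile$S[int, , drop = FALSE], 1L, min) > Th
  if (!any(active)) return(NA_integer_)
  int[which(active)[1L]] - 1L
}

#' Trim a sequence to its detected onset and re-base time labels
#'
#' Drops the idle frames before `t_start` so that frame 0 of the result
#' is the first active frame; the old-to-new frame mapping is recorded
#' in the sequence metadata.  Training descriptors re-based this way get
#' comparable "global time" coordinates across irregularly segmented
#' recordings.
#'
#' @param seq a [skeleton_sequence()].
#' @param t_start 0-based onset frame, or a `motion_profile` (combined
#'   with `Th`) from which to detect it.
#' @param Th threshold used when `t_start` is a profile.
#' @return The trimmed [skeleton_sequence()].
#' @export
regularize_sequence <- function(seq, t_start, Th = 0.005) {
  if (inherits(t_start, "motion_profile")) t_start <- detect_onset(t_start, Th)
  if (is.na(t_start))
    stop("no motion onset found; sequence cannot be regularized")
  nf <- n_frames(seq)
  if (t_start < 0L || t_start >= nf) stop("t_start out of range")
  keep <- (t_start + 1L):nf
  seq$coords <- seq$coords[keep, , , drop = FALSE]
  if (!is.null(seq$confidence))
    seq$confidence <- seq$confidence[keep, , drop = FALSE]
  seq$meta$regularization <- list(t_start = t_start,
                                  old_frames = keep - 1L,
                                  new_frames = seq_along(keep) - 1L)
  seq
}

#' Inverse-frequency class weights w(A)
#'
#' Balances classes whose sequences differ in duration:
#' `w(A) = N_total / (C * N_A)` where `N_A` is the number of training
#' frames of class `A` and `C` the number of classes, so balanced data
#' gets `w(A) = 1` for every class.
#'
#' @param labels character vector of per-frame class labels.
#' @return Named numeric vector of weights.
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  w <- length(labels) / (length(tab) * as.numeric(tab))
  names(w) <- names(tab)
  w
}

#' Per-frame training confidence via the first modified KNN
#'
#' Treats every training frame's label as unknown and asks how well its
#' `K` nearest neighbours — drawn from *other* source sequences only, to
#' avoid trivial matches between adjacent frames of the same recording —
#' agree with its true class `A`: with `K_t` of `K` neighbours sharing
#' the class, the confidence is `c(X_t) = w(A) * K_t / K`.  Frames in
#' idle or style-shared segments that look alike across classes score
#' low and therefore carry little weight in the voting classifier.
#'
#' @param index a `training_index` (see [action_knn()]) or a list with
#'   elements `X` (descriptor matrix), `info` (with `action_label`,
#'   `source_id`) and optionally `class_weights`.
#' @param K neighbour count.
#' @return The index with `info$confidence` filled and `class_weights`
#'   attached.
#' @export
compute_frame_confidence <- function(index, K = 5L) {
  X <- index$X
  info <- index$info
  N <- nrow(X)
  if (K >= N) stop("K = ", K, " but only ", N, " training descriptors")
  w <- index$class_weights
  if (is.null(w)) w <- class_weights(info$action_label)
  D2 <- dist2_matrix(X, X)
  src <- info$source_id
  tlab <- info$time_label
  src_rank <- match(src, sort(unique(src)))
  conf <- numeric(N)
  for (i in seq_len(N)) {
    d <- D2[i, ]
    d[src == src[i]] <- Inf               # exclude own source sequence
    if (sum(is.finite(d)) < K)
      stop("fewer than K eligible neighbours outside the source sequence")
    o <- order(d, src_rank, tlab)[seq_len(K)]
    K_t <- sum(info$action_label[o] == info$action_label[i])
    conf[i] <- w[[info$action_label[i]]] * K_t / K
  }
  index$info$confidence <- conf
  index$class_weights <- w
  index$K <- as.integer(K)
  index
}
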