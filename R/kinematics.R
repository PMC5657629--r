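#' Control parameters for descriptor computation and recognition
#'
#' Collects every tunable of the pipeline in one place, in the spirit of
#' `glm.control()`.  Defaults follow the method's reference settings:
#' descriptor weights `lambda = 0.8`, `epsilon = 0.6`; pose normalization
#' constant `eta = 1`; a 5-tap Gaussian smoother with standard deviation
#' 1; a 5-frame motion-statistic window with onset threshold
#' `Th = 0.005` (squared coordinate units); `K = 5` neighbours for all
#' three KNNs; voting-window half-width `w_t = 5` frames; time-label bin
#' width `b = 1`; stream decision gate `alpha_dec = 0.5` after
#' `T_th = 15` frames.
#'
#' @param lambda nonnegative weight of the angular-velocity block.
#' @param epsilon nonnegative weight of the angular-acceleration block.
#' @param eta positive pose-normalization constant (absorbed by the KNN
#'   distance scale; 1 is a neutral choice).
#' @param selected_joints ordered joint-name subset entering the
#'   descriptor; `NULL` means [default_selected_joints()].  Must not
#'   include the hip centre (identically zero after centring).
#' @param smooth_width odd Gaussian window length (frames).
#' @param smooth_sigma Gaussian standard deviation (frames).
#' @param stat_window odd motion-statistic window length `T` (frames).
#' @param monitored_joints joints entering the motion statistic; `NULL`
#'   means the descriptor subset.
#' @param Th onset threshold on the minimum per-dimension window variance
#'   (squared coordinate units).
#' @param K neighbour count shared by the confidence, time-label and
#'   classification KNNs.
#' @param w_t classification voting-window half-width (frames around the
#'   estimated time label).
#' @param bin_width time-label vote bin width `b` (frames).
#' @param alpha_dec stream decision threshold on the winning class's
#'   confidence fraction, in (0, 1\].
#' @param T_th minimum frames observed before a stream decision.
#' @param metric KNN distance metric; only `"euclidean"` is implemented.
#' @param edge_policy handling of the first/last two frames whose 5-frame
#'   stencil does not fit: `"drop"` (default) or `"copy"` the nearest
#'   interior kinematics (flagged in the descriptor info).
#' @param rms if `TRUE`, the motion statistic is the root of the window
#'   variance instead of the variance itself.
#' @param bone_length_source `"sequence"` (estimate `d_i` and `L` from
#'   each sequence, the default, which makes descriptors body-size
#'   invariant) or `"topology"` (use the fixed lengths in the topology).
#' @param use_confidence_weights if `TRUE`, votes are additionally scaled
#'   by the frame's mean sensor confidence.
#' @param reset_policy after a stream decision: `"reset"` the vote tally
#'   or `"decay"` it by `decay_factor`.
#' @param decay_factor multiplicative tally decay used when
#'   `reset_policy = "decay"`.
#' @return A list of class `action_knn_control`.
#' @export
action_knn_control <- function(lambda = 0.8, epsilon = 0.6, eta = 1,
                               selected_joints = NULL,
                               smooth_width = 5L, smooth_sigma = 1,
                               stat_window = 5L, monitored_joints = NULL,
                               Th = 0.005, K = 5L, w_t = 5L,
                               bin_width = 1L, alpha_dec = 0.5, T_th = 15L,
                               metric = "euclidean",
                               edge_policy = c("drop", "copy"),
                               rms = FALSE,
                               bone_length_source = c("sequence", "topology"),
                               use_confidence_weights = FALSE,
                               reset_policy = c("reset", "decay"),
                               decay_factor = 0.5) {
  if (lambda < 0 || epsilon < 0) stop("lambda and epsilon must be >= 0")
  if (eta <= 0) stop("eta must be > 0")
  if (smooth_width %% 2L == 0L || smooth_width < 3L)
    stop("smooth_width must be odd and >= 3")
  if (stat_window %% 2L == 0L) stop("stat_window must be odd")
  if (alpha_dec <= 0 || alpha_dec > 1) stop("alpha_dec must be in (0, 1]")
  metric <- match.arg(metric, "euclidean")
  structure(list(
    lambda = lambda, epsilon = epsilon, eta = eta,
    selected_joints = selected_joints,
    smooth_width = as.integer(smooth_width), smooth_sigma = smooth_sigma,
    stat_window = as.integer(stat_window),
    monitored_joints = monitored_joints,
    Th = Th, K = as.integer(K), w_t = as.integer(w_t),
    bin_width = as.integer(bin_width), alpha_dec = alpha_dec,
    T_th = as.integer(T_th), metric = metric,
    edge_policy = match.arg(edge_policy), rms = isTRUE(rms),
    bone_length_source = match.arg(bone_length_source),
    use_confidence_weights = isTRUE(use_confidence_weights),
    reset_policy = match.arg(reset_policy), decay_factor = decay_factor),
    class = "action_knn_control")
}

.gauss_kernel <- function(width, sigma) {
  h <- (width - 1L) %/% 2L
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian-smooth a skeleton sequence
#'
#' Convolves every joint/coordinate channel with a sampled, normalized
#' Gaussian kernel (default 5 taps, sigma = 1).  Boundary frames use the
#' truncated kernel renormalized to sum 1, so the output has the same
#' number of frames as the input.  The half-window group delay (2 frames
#' for a 5-tap filter, relevant when frames are consumed causally) is
#' recorded in the sequence metadata.
#'
#' @param seq a [skeleton_sequence()].
#' @param width odd kernel length, at least 3.
#' @param sigma Gaussian standard deviation in frames.
#' @return The smoothed [skeleton_sequence()].
#' @export
gaussian_smooth <- function(seq, width = 5L, sigma = 1) {
  if (width %% 2L == 0L || width < 3L)
    stop("smoothing width must be odd and >= 3")
  nf <- n_frames(seq)
  if (nf < width)
    stop("sequence has ", nf, " frames; smoothing window of ", width,
         " does not fit")
  k <- .gauss_kernel(width, sigma)
  h <- (width - 1L) %/% 2L
  P <- seq$coords
  out <- P
  nj <- dim(P)[2L]
  flat <- matrix(P, nrow = nf)            # nf x (nj*3)
  sm <- matrix(0, nf, ncol(flat))
  for (t in seq_len(nf)) {
    lo <- max(1L, t - h); hi <- min(nf, t + h)
    kk <- k[(lo - t + h + 1L):(hi - t + h + 1L)]
    kk <- kk / sum(kk)
    sm[t, ] <- kk %*% flat[lo:hi, , drop = FALSE]
  }
  seq$coords <- array(sm, dim(P))
  seq$meta$smoothing <- list(width = width, sigma = sigma, group_delay = h)
  seq
}

#' Restrict a sequence to a configured joint subset
#'
#' Returns the sequence reduced to `joints`, in the given order, with a
#' matching reduced topology that keeps each retained joint's original
#' parent-bone length `d_i` (parent links of dropped joints are rewired
#' to the nearest retained ancestor for bookkeeping; `d_i` values are
#' preserved, not recomputed).
#'
#' @param seq a [skeleton_sequence()].
#' @param joints character vector of joint names to keep, in output order.
#' @return The restricted [skeleton_sequence()].
#' @export
select_joints <- function(seq, joints) {
  topo <- seq$topology
  idx <- joint_index(topo, joints)
  keep_plus_root <- union(topo$hip_center, idx)
  # rewire each kept joint's parent to its nearest kept ancestor
  new_parent <- vapply(idx, function(j) {
    k <- topo$parents[j]
    while (!(k %in% idx) && k != topo$hip_center) k <- topo$parents[k]
    if (k %in% idx) match(k, idx) else match(j, idx)  # orphan -> own root
  }, integer(1))
  sub <- structure(
    list(joint_names = joints, parents = new_parent,
         hip_center = NA_integer_,  # hip centre typically excluded
         bone_lengths = if (!is.null(topo$bone_lengths))
           topo$bone_lengths[idx] else NULL,
         hip_segment_length = topo$hip_segment_length,
         hip_segment_joint = topo$hip_segment_joint,
         parent_topology = topo),
    class = "skeleton_topology")
  out <- seq
  out$coords <- seq$coords[, idx, , drop = FALSE]
  if (!is.null(seq$confidence))
    out$confidence <- seq$confidence[, idx, drop = FALSE]
  out$topology <- sub
  out
}

#' Convert to hip-relative, size-normalized coordinates
#'
#' Re-expresses every joint relative to the hip centre and rescales by
#' `eta / L`, where `L` is the hip-segment length: `p_i` becomes
#' `eta/L * (p_i - p_hip)`.  The hip centre maps to the origin, and the
#' result is invariant to uniform scaling of coordinates and `L`
#' together, which is how skeletons of different body sizes become
#' comparable without per-frame normalization.
#'
#' @param seq a [skeleton_sequence()] (full topology, hip centre present).
#' @param topology topology supplying the hip-centre index and `L`.
#' @param eta positive proportionality constant.
#' @return The normalized [skeleton_sequence()].
#' @export
to_relative_normalized <- function(seq, topology = seq$topology, eta = 1) {
  L <- topology$hip_segment_length
  if (is.null(L) || !is.finite(L) || L <= 0)
    stop("hip segment length L must be positive (estimate it first)")
  hip <- seq$coords[, topology$hip_center, , drop = FALSE]
  seq$coords <- (seq$coords - hip[, rep(1L, dim(seq$coords)[2L]), ,
                                  drop = FALSE]) * (eta / L)
  seq
}

#' Central finite differences over the five-frame stencil
#'
#' First and second differences of the joint trajectories on the 5-frame
#' sliding window centred at each frame: `P'(t) = P(t+1) - P(t-1)` and
#' `P''(t) = P(t+2) + P(t-2) - 2 P(t)`.  Both are per-frame quantities
#' (no division by the frame period).  They are defined for interior
#' frames `t` in `[2, frames-3]` (0-based); outside that range the
#' result is `NA` under the `"drop"` edge policy or copied from the
#' nearest interior frame under `"copy"`.
#'
#' @param seq a [skeleton_sequence()] with at least 5 frames.
#' @param edge_policy `"drop"` (edges `NA`) or `"copy"`.
#' @return List with arrays `d1`, `d2` shaped like `seq$coords`, and
#'   `interior`, the 0-based interior frame range.
#' @export
finite_differences <- function(seq, edge_policy = c("drop", "copy")) {
  edge_policy <- match.arg(edge_policy)
  P <- seq$coords
  nf <- dim(P)[1L]
  if (nf < 5L) stop("at least 5 frames are required (got ", nf, ")")
  d1 <- array(NA_real_, dim(P))
  d2 <- array(NA_real_, dim(P))
  int <- 3:(nf - 2L)                      # 1-based interior
  d1[int, , ] <- P[int + 1L, , , drop = FALSE] - P[int - 1L, , , drop = FALSE]
  d2[int, , ] <- P[int + 2L, , , drop = FALSE] + P[int - 2L, , , drop = FALSE] -
    2 * P[int, , , drop = FALSE]
  if (edge_policy == "copy") {
    for (t in 1:2) { d1[t, , ] <- d1[3L, , ]; d2[t, , ] <- d2[3L, , ] }
    for (t in (nf - 1L):nf) { d1[t, , ] <- d1[nf - 2L, , ]; d2[t, , ] <- d2[nf - 2L, , ] }
  }
  list(d1 = d1, d2 = d2, interior = c(2L, nf - 3L))
}

#' Bone-length-normalized angular velocity and acceleration
#'
#' Divides the finite differences of each joint by that joint's
#' parent-bone length `d_i`, turning linear displacement rates into
#' angle-like rates that are comparable across body sizes:
#' `omega = P'/d_i`, `alpha = P''/d_i` (componentwise).
#'
#' @param d1,d2 difference arrays from [finite_differences()].
#' @param topology topology whose `bone_lengths` match the array's joint
#'   dimension.
#' @return List with arrays `omega` and `alpha`.
#' @export
angular_kinematics <- function(d1, d2, topology) {
  d_i <- topology$bone_lengths
  if (is.null(d_i)) stop("topology has no bone lengths d_i")
  nj <- dim(d1)[2L]
  if (length(d_i) != nj) stop("d_i length does not match joint count")
  if (any(!is.finite(d_i) | d_i <= 0))
    stop("all d_i must be positive and finite for the angular normalization")
  scale <- rep(rep(1 / d_i, each = dim(d1)[1L]), times = 3L)
  list(omega = d1 * scale, alpha = d2 * scale)
}

#' Build per-frame angular spatio-temporal descriptors
#'
#' Computes, for each interior frame of a smoothed sequence, the
#' descriptor `X_t = [pose, lambda * omega, epsilon * alpha]` over the
#' selected joints: the hip-relative size-normalized pose block,
#' the angular velocity `P'(t)/d_i`, and the angular acceleration
#' `P''(t)/d_i`.  The derivative blocks are computed on the raw
#' (smoothed, absolute) coordinates, matching the printed form of the
#' descriptor; only the pose block carries the `eta/L` normalization.
#' The descriptor is invariant to global translation and to uniform
#' scaling of coordinates, bone lengths and `L`.
#'
#' @param seq a smoothed [skeleton_sequence()] on the full topology.
#' @param topology topology carrying `d_i` and `L`; defaults to the
#'   sequence's own, or to per-sequence estimates when the control says
#'   `bone_length_source = "sequence"` and lengths are absent.
#' @param control an [action_knn_control()].
#' @return A list of class `frame_descriptors`: `X` (matrix, one row per
#'   retained frame, `9 * m_sel` columns), `info` (data.frame with
#'   0-based `frame`, `time_label` (= frame until regularized),
#'   `action_label`, `source_id`, `edge` flag, `frame_confidence`), plus
#'   the config actually used (`d_i`, `L`, joints, weights).
#' @export
build_descriptors <- function(seq, topology = NULL,
                              control = action_knn_control()) {
  if (n_frames(seq) < 5L)
    stop("at least 5 frames are required for the descriptor window")
  if (is.null(topology)) {
    topology <- seq$topology
    if (control$bone_length_source == "sequence" ||
        is.null(topology$bone_lengths) ||
        is.null(topology$hip_segment_length))
      topology <- estimate_bone_lengths(seq, topology)
  }
  joints <- control$selected_joints
  if (is.null(joints)) joints <- default_selected_joints()
  if (topology$joint_names[topology$hip_center] %in% joints)
    stop("selected_joints must not include the hip centre ",
         "(identically zero after centring)")
  # pose block: hip-relative, eta/L-normalized, then restricted
  rel <- to_relative_normalized(seq, topology, control$eta)
  pose_sel <- select_joints(rel, joints)
  # derivative blocks: raw smoothed coordinates, then restricted
  raw_sel <- select_joints(seq, joints)
  raw_sel$topology$bone_lengths <- topology$bone_lengths[joint_index(topology, joints)]
  fd <- finite_differences(raw_sel, control$edge_policy)
  ak <- angular_kinematics(fd$d1, fd$d2, raw_sel$topology)
  nf <- n_frames(seq)
  m <- length(joints)
  flatten <- function(a) matrix(a, nrow = nf)   # nf x (m*3), joint-major per axis
  X <- cbind(flatten(pose_sel$coords),
             control$lambda * flatten(ak$omega),
             control$epsilon * flatten(ak$alpha))
  frames0 <- seq_len(nf) - 1L
  edge <- frames0 < fd$interior[1L] | frames0 > fd$interior[2L]
  keep <- if (control$edge_policy == "drop") !edge else rep(TRUE, nf)
  fconf <- if (!is.null(seq$confidence))
    rowMeans(seq$confidence[, joint_index(seq$topology, joints), drop = FALSE])
  else rep(1, nf)
  info <- data.frame(
    frame = frames0[keep],
    time_label = frames0[keep],
    action_label = rep(as.character(seq$action_label), sum(keep)),
    source_id = rep(as.character(seq$sequence_id), sum(keep)),
    subject_id = rep(seq$subject_id, sum(keep)),
    edge = edge[keep],
    frame_confidence = fconf[keep],
    stringsAsFactors = FALSE)
  structure(list(
    X = X[keep, , drop = FALSE],
    info = info,
    joints = joints,
    d_i = raw_sel$topology$bone_lengths,
    L = topology$hip_segment_length,
    lambda = control$lambda, epsilon = control$epsilon, eta = control$eta),
    class = "frame_descriptors")
}

#' Export descriptors as CSV with a JSON sidecar
#'
#' Writes the descriptor matrix plus frame metadata to `path` (CSV) and
#' the generating configuration (weights, joints, `d_i`, `L`) to
#' `paste0(path, ".json")`.
#'
#' @param desc a `frame_descriptors` object from [build_descriptors()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(desc, path) {
  df <- cbind(desc$info, as.data.frame(desc$X))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(joints = desc$joints, d_i = as.list(desc$d_i), L = desc$L,
               lambda = desc$lambda, epsilon = desc$epsilon, eta = desc$eta)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    dput(side, file = paste0(path, ".json"))
  }
  invisible(path)
}
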