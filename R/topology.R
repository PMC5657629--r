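#' Skeleton topology
#'
#' A `skeleton_topology` describes the joint graph of a skeleton: named
#' joints, a parent link per joint (the root is its own parent), the
#' hip-centre joint used as coordinate origin, per-joint bone lengths
#' `d_i` (length of the bone connecting joint *i* to its parent, in the
#' same units as the coordinates), and the hip-segment length `L` used to
#' scale-normalize the pose block of the descriptor.
#'
#' @param joint_names character vector of joint identifiers (unique).
#' @param parents integer vector, 1-based index of each joint's parent;
#'   the root joint points at itself.
#' @param hip_center index (or name) of the hip-centre joint; must be the
#'   root of the parent tree.
#' @param bone_lengths numeric vector of per-joint parent-bone lengths
#'   `d_i`; the root entry may be `NA`. May be `NULL` when lengths are to
#'   be estimated from data (see [estimate_bone_lengths()]).
#' @param hip_segment_length positive scalar `L`, length of the hip
#'   segment (by default the bone from the hip centre to `hip_segment_joint`).
#' @param hip_segment_joint name of the hip-adjacent joint whose parent
#'   bone defines `L` (used by [estimate_bone_lengths()]).
#' @return An object of class `skeleton_topology`.
#' @seealso [default_topology()], [make_topology()]
#' @export
skeleton_topology <- function(joint_names, parents, hip_center,
                              bone_lengths = NULL,
                              hip_segment_length = NULL,
                              hip_segment_joint = NULL) {
  joint_names <- as.character(joint_names)
  n <- length(joint_names)
  if (anyDuplicated(joint_names))
    stop("joint names must be unique")
  parents <- as.integer(parents)
  if (length(parents) != n)
    stop("'parents' must have one entry per joint")
  if (is.character(hip_center)) hip_center <- match(hip_center, joint_names)
  hip_center <- as.integer(hip_center)
  if (is.na(hip_center) || hip_center < 1L || hip_center > n)
    stop("invalid hip_center joint")
  if (parents[hip_center] != hip_center)
    stop("the hip-centre joint must be the root (its own parent)")
  if (any(parents < 1L | parents > n))
    stop("parent indices out of range")
  if (sum(parents == seq_len(n)) != 1L)
    stop("exactly one root joint is allowed")
  # tree check: every joint must reach the root without revisiting a node
  for (j in seq_len(n)) {
    seen <- logical(n)
    k <- j
    while (k != hip_center) {
      if (seen[k]) stop("parent graph contains a cycle at joint ", joint_names[j])
      seen[k] <- TRUE
      k <- parents[k]
    }
  }
  if (!is.null(bone_lengths)) {
    bone_lengths <- as.numeric(bone_lengths)
    if (length(bone_lengths) == 1L) bone_lengths <- rep(bone_lengths, n)
    if (length(bone_lengths) != n)
      stop("'bone_lengths' must have one entry per joint")
    bl <- bone_lengths[-hip_center]
    if (any(!is.finite(bl)) || any(bl <= 0))
      stop("all bone lengths d_i must be positive")
    names(bone_lengths) <- joint_names
  }
  if (is.null(hip_segment_joint)) {
    kids <- which(parents == hip_center & seq_len(n) != hip_center)
    hip_segment_joint <- joint_names[kids[1L]]
  }
  if (!hip_segment_joint %in% joint_names)
    stop("unknown hip_segment_joint: ", hip_segment_joint)
  if (is.null(hip_segment_length) && !is.null(bone_lengths))
    hip_segment_length <- bone_lengths[[hip_segment_joint]]
  if (!is.null(hip_segment_length) &&
      (!is.finite(hip_segment_length) || hip_segment_length <= 0))
    stop("hip_segment_length L must be positive")
  structure(
    list(joint_names = joint_names,
         parents = parents,
         hip_center = hip_center,
         bone_lengths = bone_lengths,
         hip_segment_length = hip_segment_length,
         hip_segment_joint = hip_segment_joint),
    class = "skeleton_topology")
}

#' @export
print.skeleton_topology <- function(x, ...) {
  cat("Skeleton topology:", length(x$joint_names), "joints, root =",
      x$joint_names[x$hip_center], "\n")
  if (!is.null(x$hip_segment_length))
    cat("  hip segment L =", format(x$hip_segment_length),
        "(bone of", x$hip_segment_joint, ")\n")
  invisible(x)
}

n_joints <- function(topology) length(topology$joint_names)

joint_index <- function(topology, joints) {
  idx <- match(joints, topology$joint_names)
  if (anyNA(idx))
    stop("unknown joint name(s): ",
         paste(joints[is.na(idx)], collapse = ", "))
  idx
}

# Kinect-v1 style 20-joint layout: hip-centre root, spine/head chain,
# two 4-joint arms, two 3-joint legs.  Rest-pose bone offsets (unit
# direction per bone, metres-scale lengths) drive the synthetic generator.
.kinect20 <- local({
  # limbs hang slightly off-axis (arms a bit abducted and forward,
  # knees soft, feet turned out) so no lever arm is parallel to a
  # rotation axis at rest and every rotation moves all three dimensions
  def <- rbind(
    hip_center      = c(NA,          0,  0,  0, 0.00),
    spine           = c("hip_center", 0.10, 0.97, 0.20, 0.25),
    shoulder_center = c("spine",     -0.08, 0.97, 0.15, 0.25),
    head            = c("shoulder_center", 0.12, 0.95, 0.25, 0.20),
    shoulder_left   = c("shoulder_center", -0.94, 0.15, 0.30, 0.18),
    elbow_left      = c("shoulder_left", -0.28, -0.92, 0.28, 0.28),
    wrist_left      = c("elbow_left",    -0.15, -0.90, 0.41, 0.25),
    hand_left       = c("wrist_left",    -0.20, -0.85, 0.48, 0.08),
    shoulder_right  = c("shoulder_center", 0.94, 0.15, 0.30, 0.18),
    elbow_right     = c("shoulder_right", 0.28, -0.92, 0.28, 0.28),
    wrist_right     = c("elbow_right",    0.15, -0.90, 0.41, 0.25),
    hand_right      = c("wrist_right",    0.20, -0.85, 0.48, 0.08),
    hip_left        = c("hip_center",   -0.93, -0.25, 0.26, 0.10),
    knee_left       = c("hip_left",     -0.18, -0.94, 0.29, 0.40),
    ankle_left      = c("knee_left",     0.12, -0.93, -0.35, 0.38),
    foot_left       = c("ankle_left",    0.15, -0.30, 0.94, 0.15),
    hip_right       = c("hip_center",    0.93, -0.25, 0.26, 0.10),
    knee_right      = c("hip_right",     0.18, -0.94, 0.29, 0.40),
    ankle_right     = c("knee_right",   -0.12, -0.93, -0.35, 0.38),
    foot_right      = c("ankle_right",   0.15, -0.30, 0.94, 0.15))
  dirs <- matrix(as.numeric(def[, 2:4]), ncol = 3,
                 dimnames = list(rownames(def), c("x", "y", "z")))
  nrm <- sqrt(rowSums(dirs^2))
  dirs[nrm > 0, ] <- dirs[nrm > 0, ] / nrm[nrm > 0]
  list(names = rownames(def),
       parent_name = unname(def[, 1L]),
       directions = dirs,
       lengths = as.numeric(def[, 5L]))
})

#' Joints of the default descriptor subset (head and limbs)
#'
#' The descriptor deliberately drops torso joints such as the shoulders,
#' spine and neck, keeping the head and the distal limb joints whose
#' angular motion carries the action.
#'
#' @return Character vector of 13 joint names.
#' @export
default_selected_joints <- function() {
  c("head",
    "elbow_left", "elbow_right",
    "wrist_left", "wrist_right",
    "hand_left", "hand_right",
    "knee_left", "knee_right",
    "ankle_left", "ankle_right",
    "foot_left", "foot_right")
}

#' Build the default (or a rescaled) 20-joint skeleton topology
#'
#' `make_topology()` constructs the Kinect-v1 style 20-joint tree: a
#' hip-centre root, a spine/shoulder-centre/head chain, two
#' shoulder-elbow-wrist-hand arms and two hip-knee-ankle-foot legs.
#' `default_topology()` is `make_topology()` with the built-in bone
#' lengths (roughly metres for an adult).
#'
#' @param n_joints number of joints; only the 20-joint layout is defined.
#' @param base_bone_lengths optional replacement bone lengths: a single
#'   positive scalar (all bones equal) or a vector of length 20 in joint
#'   order (root entry ignored).
#' @return A [skeleton_topology()].
#' @export
make_topology <- function(n_joints = 20, base_bone_lengths = NULL) {
  if (n_joints != 20)
    stop("only the 20-joint default layout is defined")
  k <- .kinect20
  lengths <- k$lengths
  if (!is.null(base_bone_lengths)) {
    base_bone_lengths <- as.numeric(base_bone_lengths)
    if (length(base_bone_lengths) == 1L)
      base_bone_lengths <- rep(base_bone_lengths, 20L)
    if (length(base_bone_lengths) != 20L)
      stop("'base_bone_lengths' must be scalar or length 20")
    if (any(base_bone_lengths[-1L] <= 0) || any(!is.finite(base_bone_lengths[-1L])))
      stop("all bone lengths must be positive")
    lengths <- base_bone_lengths
  }
  parents <- ifelse(is.na(k$parent_name), seq_along(k$names),
                    match(k$parent_name, k$names))
  lengths[1L] <- NA_real_
  skeleton_topology(k$names, parents, hip_center = "hip_center",
                    bone_lengths = lengths,
                    hip_segment_joint = "spine")
}

#' @rdname make_topology
#' @export
default_topology <- function() make_topology()

#' Estimate bone lengths from a sequence
#'
#' Fills the topology's per-joint bone lengths `d_i` with the median over
#' frames of the observed distance between each joint and its parent, and
#' the hip-segment length `L` with the median hip-centre-to-hip-segment
#' distance.  Estimating lengths from the sequence itself is what makes
#' the angular descriptor independent of body size: each subject is
#' normalized by their own skeleton.
#'
#' @param seq a [skeleton_sequence()].
#' @param topology a [skeleton_topology()]; defaults to the sequence's own.
#' @return The topology with `bone_lengths` and `hip_segment_length`
#'   replaced by the estimates.
#' @export
estimate_bone_lengths <- function(seq, topology = seq$topology) {
  P <- seq$coords
  n <- n_joints(topology)
  if (dim(P)[2L] != n) stop("sequence joint count does not match topology")
  d <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    pa <- topology$parents[j]
    if (pa == j) next
    diff <- P[, j, , drop = FALSE] - P[, pa, , drop = FALSE]
    d[j] <- stats::median(sqrt(rowSums(matrix(diff, ncol = 3L)^2)))
  }
  if (any(d[-topology$hip_center] <= 0, na.rm = TRUE))
    stop("degenerate (zero-length) bone observed; cannot estimate d_i")
  names(d) <- topology$joint_names
  topology$bone_lengths <- d
  topology$hip_segment_length <- d[[topology$hip_segment_joint]]
  topology
}
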