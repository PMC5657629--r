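#' Skeleton sequence container
#'
#' A `skeleton_sequence` holds a frames x joints x 3 coordinate array plus
#' optional per-joint confidence, a frame rate (metadata only), subject /
#' action / sequence identifiers, and a reference to its
#' [skeleton_topology()].
#'
#' @param coords numeric array of dimension frames x n_joints x 3.
#' @param topology a [skeleton_topology()] with matching joint count.
#' @param confidence optional frames x n_joints matrix in \[0, 1\].
#' @param frame_rate frames per second (metadata only; derivatives are per
#'   frame, not per second).
#' @param subject_id,action_label,sequence_id optional identifiers.
#' @param meta free-form metadata list.
#' @return Object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(coords, topology, confidence = NULL,
                              frame_rate = NA_real_, subject_id = NA,
                              action_label = NA_character_,
                              sequence_id = NA_character_, meta = list()) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stop("'coords' must be a frames x joints x 3 array")
  if (dim(coords)[2L] != n_joints(topology))
    stop("coords joint count (", dim(coords)[2L],
         ") does not match topology (", n_joints(topology), ")")
  storage.mode(coords) <- "double"
  if (!is.null(confidence)) {
    confidence <- as.matrix(confidence)
    if (!all(dim(confidence) == dim(coords)[1:2]))
      stop("'confidence' must be frames x joints")
  }
  structure(
    list(coords = coords, confidence = confidence, frame_rate = frame_rate,
         subject_id = subject_id, action_label = action_label,
         sequence_id = sequence_id, topology = topology, meta = meta),
    class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat("Skeleton sequence", if (!is.na(x$sequence_id)) sQuote(x$sequence_id),
      ":", dim(x$coords)[1L], "frames x", dim(x$coords)[2L], "joints\n")
  if (!is.na(x$action_label)) cat("  action:", x$action_label, "\n")
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

n_frames <- function(seq) dim(seq$coords)[1L]

#' Validate a skeleton sequence against its invariants
#'
#' Checks the container invariants a sequence must satisfy before it can
#' enter descriptor computation: joint count matching the topology, no
#' missing coordinates, at least 5 frames (the sliding-window stencil must
#' fit), and confidence values in \[0, 1\] when present.
#'
#' @param seq a [skeleton_sequence()].
#' @param topology topology to validate against (default: the sequence's).
#' @return Character vector of violations (empty when valid); each entry
#'   names the offending frame/joint (0-based).
#' @export
validate_sequence <- function(seq, topology = seq$topology) {
  v <- character(0)
  d <- dim(seq$coords)
  if (d[2L] != n_joints(topology))
    v <- c(v, sprintf("joint count %d != topology %d", d[2L], n_joints(topology)))
  if (d[1L] < 5L)
    v <- c(v, sprintf("frames < 5 (got %d): descriptor window cannot fit", d[1L]))
  bad <- which(!is.finite(seq$coords), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- unique(bad[, 1:2, drop = FALSE])
    v <- c(v, sprintf("non-finite coordinate at frame %d, joint %d",
                      cells[, 1L] - 1L, cells[, 2L] - 1L))
  }
  if (!is.null(seq$confidence)) {
    cb <- seq$confidence < 0 | seq$confidence > 1
    if (any(cb, na.rm = TRUE) || anyNA(seq$confidence))
      v <- c(v, "confidence values outside [0, 1]")
  }
  v
}

#' Repair short gaps of missing joints by linear interpolation
#'
#' Sequences with missing (NaN) joints are rejected by default at load
#' time.  This optional repair linearly interpolates runs of at most
#' `max_gap` consecutive missing frames per joint/coordinate channel;
#' longer runs (or missing ends) remain missing and the sequence stays
#' invalid.
#'
#' @param seq a [skeleton_sequence()].
#' @param max_gap longest run of consecutive missing frames to repair.
#' @return The repaired sequence.
#' @export
interpolate_gaps <- function(seq, max_gap = 2L) {
  P <- seq$coords
  nf <- dim(P)[1L]
  for (j in seq_len(dim(P)[2L])) for (d in 1:3) {
    y <- P[, j, d]
    na <- which(!is.finite(y))
    if (!length(na)) next
    runs <- split(na, cumsum(c(1L, diff(na) != 1L)))
    for (r in runs) {
      lo <- min(r) - 1L; hi <- max(r) + 1L
      if (length(r) <= max_gap && lo >= 1L && hi <= nf &&
          is.finite(y[lo]) && is.finite(y[hi])) {
        y[r] <- y[lo] + (y[hi] - y[lo]) * (r - lo) / (hi - lo)
      }
    }
    P[, j, d] <- y
  }
  seq$coords <- P
  seq
}
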