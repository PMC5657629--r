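# squared-Euclidean cross-distance matrix, rows of A vs rows of B
dist2_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# deterministic K-nearest selection on a precomputed distance row:
# ties broken by source-sequence rank, then time label
.knn_rows <- function(d, src_rank, tlab, K) {
  order(d, src_rank, tlab)[seq_len(K)]
}

#' Exact K-nearest-neighbour query against a training index
#'
#' The shared KNN core of the method.  Returns the exact `K` nearest
#' training descriptors under the configured metric, with a
#' deterministic tie-break (smaller distance, then smaller sequence id,
#' then smaller time label).  When a time window `[t_lo, t_hi]` on the
#' regularized training labels is given and fewer than `K` descriptors
#' fall inside, the window is widened symmetrically until `K` are
#' available (recorded in the result).
#'
#' @param x a single descriptor vector.
#' @param index a `training_index` (see [action_knn()]).
#' @param K number of neighbours.
#' @param time_window optional `c(t_lo, t_hi)` restriction on time labels.
#' @param widen_step widening increment per side when the window is
#'   too narrow.
#' @return A list: `idx` (row indices into the index), `dist` (Euclidean
#'   distances), `info` (their metadata rows), `window` (the window
#'   actually used), `widened` (logical).
#' @export
knn_query <- function(x, index, K = index$K, time_window = NULL,
                      widen_step = 5L) {
  N <- nrow(index$X)
  if (is.null(N) || N == 0L) stop("empty training index")
  K <- min(as.integer(K), N)
  d2 <- dist2_matrix(matrix(x, nrow = 1L), index$X)[1L, ]
  tlab <- index$info$time_label
  widened <- FALSE
  if (!is.null(time_window)) {
    lo <- time_window[1L]; hi <- time_window[2L]
    repeat {
      inside <- tlab >= lo & tlab <= hi
      if (sum(inside) >= K) break
      lo <- lo - widen_step; hi <- hi + widen_step
      widened <- TRUE
    }
    d2[!inside] <- Inf
    time_window <- c(lo, hi)
  }
  o <- .knn_rows(d2, index$src_rank, tlab, K)
  list(idx = o, dist = sqrt(d2[o]), info = index$info[o, , drop = FALSE],
       window = time_window, widened = widened)
}

# mode of binned time labels; ties -> smaller bin; returns the centre label
.vote_time_label <- function(labels, b = 1L) {
  bins <- labels %/% b
  tab <- table(bins)
  best <- as.integer(names(tab)[tab == max(tab)])
  bin <- min(best)
  as.integer(bin * b + (b - 1L) %/% 2L)
}

#' Estimate the regularized time label of an input frame
#'
#' The second modified KNN: the `K` training frames nearest to the input
#' descriptor (no time restriction) vote for their own regularized time
#' labels, binned into width-`b` bins; the estimate `T_i` is the centre
#' label of the winning bin (ties toward the smaller label).  Because
#' subjects perform the same action at similar angular speeds, frames at
#' the same stage of an action land near each other in descriptor
#' space, making `T_i` a usable global-time coordinate even for a
#' single frame plucked from an unsegmented stream.
#'
#' @param x a descriptor vector.
#' @param index a `training_index`.
#' @param K number of voting neighbours.
#' @param b bin width in frames.
#' @return A list of class `time_estimate`: `T_i` (the estimate),
#'   `votes` (table of neighbour labels), `neighbours` (index rows).
#' @export
estimate_time_label <- function(x, index, K = index$K, b = 1L) {
  q <- knn_query(x, index, K)
  labs <- q$info$time_label
  structure(list(T_i = .vote_time_label(labs, b), votes = table(labs),
                 neighbours = q$idx),
            class = "time_estimate")
}

# per-frame confidence-weighted class votes for one query row of a
# precomputed distance matrix; returns named numeric vector over classes
.frame_votes <- function(d2row, index, K, w_t, t_i, classes, b = 1L,
                         frame_weight = 1) {
  tlab <- index$info$time_label
  lo <- t_i - w_t; hi <- t_i + w_t
  repeat {
    inside <- tlab >= lo & tlab <= hi
    if (sum(inside) >= K) break
    lo <- lo - max(1L, w_t); hi <- hi + max(1L, w_t)
  }
  d <- d2row
  d[!inside] <- Inf
  o <- .knn_rows(d, index$src_rank, tlab, K)
  v <- structure(numeric(length(classes)), names = classes)
  cls <- index$info$action_label[o]
  cw <- index$info$confidence[o] * frame_weight
  for (k in seq_along(o)) v[[cls[k]]] <- v[[cls[k]]] + cw[k]
  v
}

# shared per-sequence machinery: distance matrix + per-frame time
# estimates + per-frame vote vectors
.frame_vote_matrix <- function(Q, index, K, w_t, b = 1L,
                               time_labels = NULL, frame_weights = NULL) {
  D2 <- dist2_matrix(Q, index$X)
  nfr <- nrow(Q)
  classes <- names(index$class_weights)
  if (is.null(frame_weights)) frame_weights <- rep(1, nfr)
  t_est <- integer(nfr)
  V <- matrix(0, nfr, length(classes), dimnames = list(NULL, classes))
  tlab <- index$info$time_label
  for (i in seq_len(nfr)) {
    if (is.null(time_labels)) {
      o <- .knn_rows(D2[i, ], index$src_rank, tlab, min(K, nrow(index$X)))
      t_est[i] <- .vote_time_label(tlab[o], b)
    } else t_est[i] <- time_labels[i]
    V[i, ] <- .frame_votes(D2[i, ], index, min(K, nrow(index$X)), w_t,
                           t_est[i], classes, b, frame_weights[i])
  }
  list(votes = V, time_estimates = t_est)
}

#' Classify a segmented sequence of descriptors
#'
#' The third modified KNN: every input frame first gets its time label
#' `t_i` estimated (unless supplied), then its `K` nearest training
#' frames *within the voting window* `[t_i - w_t, t_i + w_t]` of
#' regularized training labels cast votes weighted by their training
#' confidence `c(X)`.  The sequence label is the class with the largest
#' accumulated confidence; scores are reported normalized to sum 1.
#' Because votes are summed, the decision is invariant to the order of
#' the input frames.
#'
#' @param frames descriptor matrix (rows = frames) or a
#'   `frame_descriptors` object.
#' @param index a `training_index`.
#' @param K neighbours per frame.
#' @param w_t voting-window half-width in frames.
#' @param b time-label bin width.
#' @param time_labels optional integer vector overriding the per-frame
#'   time-label estimates (used e.g. to study estimation errors).
#' @param frame_weights optional per-frame vote multipliers (e.g. sensor
#'   confidence).
#' @return A list of class `action_decision`: `label`, `scores`
#'   (normalized per-class), `votes` (raw per-class sums), `per_frame`
#'   (per-frame vote matrix), `time_estimates`.
#' @export
classify_segmented <- function(frames, index, K = index$K, w_t = 5L,
                               b = 1L, time_labels = NULL,
                               frame_weights = NULL) {
  Q <- if (inherits(frames, "frame_descriptors")) frames$X else as.matrix(frames)
  if (nrow(Q) == 0L) stop("no input frames to classify")
  fv <- .frame_vote_matrix(Q, index, K, w_t, b, time_labels, frame_weights)
  tot <- colSums(fv$votes)
  label <- names(tot)[which.max(tot)]
  s <- sum(tot)
  structure(list(label = label,
                 scores = if (s > 0) tot / s else tot,
                 votes = tot,
                 per_frame = fv$votes,
                 time_estimates = fv$time_estimates),
            class = "action_decision")
}

#' @export
print.action_decision <- function(x, ...) {
  cat("Action decision:", x$label,
      sprintf("(score %.3f over %d frames)\n",
              max(x$scores), nrow(x$per_frame)))
  invisible(x)
}

#' Classify an unsegmented stream of descriptors
#'
#' Processes frames one at a time, treating each as independent (no
#' assumption about its position in an action): each frame's time label
#' is estimated, its windowed neighbours vote with their confidence, and
#' the votes accumulate in a running tally.  Once more than `T_th`
#' frames have been seen and the leading class holds more than
#' `alpha_dec` of the accumulated confidence, that class is emitted and
#' the tally restarts (or decays, under the `"decay"` policy), so
#' consecutive different actions produce consecutive decisions.
#'
#' @param frames descriptor matrix in stream order (or
#'   `frame_descriptors`).
#' @param index a `training_index`.
#' @param K,w_t,b as in [classify_segmented()].
#' @param T_th minimum number of frames in the current tally before a
#'   decision may be emitted.
#' @param alpha_dec decision threshold on the leading class's vote
#'   fraction, in (0, 1].
#' @param reset_policy `"reset"` (tally cleared after a decision) or
#'   `"decay"`.
#' @param decay_factor tally multiplier used under `"decay"`.
#' @param frame_weights optional per-frame vote multipliers.
#' @return A list of class `stream_result`: `events` (data.frame with
#'   0-based `frame`, `label`, `fraction`, `support` — the winning
#'   class's accumulated confidence — and `tally_frames`), `per_frame`
#'   (data.frame with each frame's instantaneous top class and the
#'   pending tally leader), `final_tally`.
#' @export
classify_stream <- function(frames, index, K = index$K, w_t = 5L, b = 1L,
                            T_th = 15L, alpha_dec = 0.5,
                            reset_policy = c("reset", "decay"),
                            decay_factor = 0.5, frame_weights = NULL) {
  reset_policy <- match.arg(reset_policy)
  Q <- if (inherits(frames, "frame_descriptors")) frames$X else as.matrix(frames)
  fv <- .frame_vote_matrix(Q, index, K, w_t, b,
                           frame_weights = frame_weights)
  classes <- colnames(fv$votes)
  tally <- structure(numeric(length(classes)), names = classes)
  seen <- 0L
  events <- list()
  inst_top <- character(nrow(Q))
  pending <- character(nrow(Q))
  for (i in seq_len(nrow(Q))) {
    tally <- tally + fv$votes[i, ]
    seen <- seen + 1L
    inst_top[i] <- if (sum(fv$votes[i, ]) > 0)
      classes[which.max(fv$votes[i, ])] else NA_character_
    tot <- sum(tally)
    frac <- if (tot > 0) max(tally) / tot else 0
    pending[i] <- classes[which.max(tally)]
    if (seen > T_th && frac > alpha_dec) {
      events[[length(events) + 1L]] <- data.frame(
        frame = i - 1L, label = classes[which.max(tally)],
        fraction = frac, support = max(tally), tally_frames = seen,
        stringsAsFactors = FALSE)
      if (reset_policy == "reset") {
        tally[] <- 0
        seen <- 0L
      } else {
        tally <- tally * decay_factor
        seen <- 0L
      }
    }
  }
  structure(list(
    events = if (length(events)) do.call(rbind, events) else
      data.frame(frame = integer(0), label = character(0),
                 fraction = numeric(0), support = numeric(0),
                 tally_frames = integer(0)),
    per_frame = data.frame(frame = seq_len(nrow(Q)) - 1L,
                           instantaneous = inst_top, pending = pending,
                           time_estimate = fv$time_estimates,
                           stringsAsFactors = FALSE),
    final_tally = tally),
    class = "stream_result")
}

#' @export
print.stream_result <- function(x, ...) {
  cat("Stream result:", nrow(x$events), "decision(s) over",
      nrow(x$per_frame), "frames\n")
  if (nrow(x$events)) print(x$events)
  invisible(x)
}
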