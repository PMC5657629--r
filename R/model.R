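#' Fit a confidence-weighted KNN action recognizer
#'
#' `action_knn()` is the training entry point of the package.  Given
#' labelled skeleton sequences it (1) Gaussian-smooths each sequence,
#' (2) estimates per-sequence bone lengths for the angular
#' normalization, (3) computes per-frame angular spatio-temporal
#' descriptors, (4) locates each sequence's motion onset with the
#' sliding-window variance statistic and re-bases frame labels so time 0
#' is the first active frame (sequences with no detectable onset are
#' excluded with a warning), (5) balances classes with inverse-frequency
#' weights, and (6) scores every training frame's confidence with the
#' leave-source-out KNN.  The result is a `training_index` wrapped in an
#' object of class `action_knn`, ready for [predict.action_knn()].
#'
#' @param x a list of [skeleton_sequence()] objects with `action_label`
#'   set, or a `synthetic_dataset` (its training half is *not* selected
#'   automatically — pass the sequences you mean to train on, e.g. from
#'   [cross_subject_split()]).
#' @param control an [action_knn_control()].
#' @param topology optional fixed [skeleton_topology()] used when
#'   `control$bone_length_source = "topology"`.
#' @return An object of class `action_knn` with elements `index` (the
#'   training index: descriptor matrix `X`, per-frame `info` with
#'   regularized `time_label` and `confidence`, `class_weights`,
#'   `src_rank`, `K`), `control`, `excluded` (ids of sequences without a
#'   detectable onset), `n_sequences`, and `call`.
#' @examples
#' tpl <- default_templates()[1:2]
#' ds <- generate_dataset(tpl, n_subjects = 2, reps_per_subject = 1, seed = 1)
#' fit <- action_knn(ds$sequences)
#' fit
#' @export
action_knn <- function(x, control = action_knn_control(), topology = NULL) {
  seqs <- if (inherits(x, "synthetic_dataset")) x$sequences else x
  if (inherits(seqs, "skeleton_sequence")) seqs <- list(seqs)
  if (!length(seqs)) stop("no training sequences")
  labs <- vapply(seqs, function(s) as.character(s$action_label), character(1))
  if (anyNA(labs)) stop("every training sequence needs an action_label")
  X_list <- list(); info_list <- list(); excluded <- character(0)
  for (s in seqs) {
    sm <- gaussian_smooth(s, control$smooth_width, control$smooth_sigma)
    topo <- if (control$bone_length_source == "topology" && !is.null(topology))
      topology else estimate_bone_lengths(sm)
    prof <- motion_statistic(sm, control$monitored_joints,
                             control$stat_window, control$rms)
    t0 <- detect_onset(prof, control$Th)
    if (is.na(t0)) {
      warning("no motion onset in sequence ", s$sequence_id,
              "; excluded from training", call. = FALSE)
      excluded <- c(excluded, as.character(s$sequence_id))
      next
    }
    d <- build_descriptors(sm, topo, control)
    keep <- d$info$frame >= t0
    d$info$time_label <- d$info$frame - t0
    X_list[[length(X_list) + 1L]] <- d$X[keep, , drop = FALSE]
    info_list[[length(info_list) + 1L]] <- d$info[keep, , drop = FALSE]
  }
  if (!length(X_list))
    stop("no sequence had a detectable motion onset; nothing to train on")
  X <- do.call(rbind, X_list)
  info <- do.call(rbind, info_list)
  rownames(info) <- NULL
  index <- list(X = X, info = info,
                class_weights = class_weights(info$action_label),
                src_rank = match(info$source_id,
                                 sort(unique(info$source_id))),
                metric = control$metric)
  index <- compute_frame_confidence(index, control$K)
  class(index) <- "training_index"
  structure(list(index = index, control = control, excluded = excluded,
                 n_sequences = length(seqs) - length(excluded),
                 call = match.call()),
            class = "action_knn")
}

#' @export
print.action_knn <- function(x, ...) {
  idx <- x$index
  cat("Confidence-weighted KNN action recognizer\n")
  cat(sprintf("  %d training frames from %d sequences, %d classes\n",
              nrow(idx$X), x$n_sequences,
              length(idx$class_weights)))
  cat(sprintf("  descriptor dim %d; K = %d, w_t = %d, Th = %g\n",
              ncol(idx$X), x$control$K, x$control$w_t, x$control$Th))
  if (length(x$excluded))
    cat("  excluded (no onset):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.action_knn <- function(object, ...) {
  info <- object$index$info
  by_class <- split(info$confidence, info$action_label)
  s <- data.frame(
    class = names(by_class),
    frames = vapply(by_class, length, integer(1)),
    weight = object$index$class_weights[names(by_class)],
    mean_confidence = vapply(by_class, mean, numeric(1)),
    row.names = NULL)
  structure(list(model = object, class_table = s),
            class = "summary.action_knn")
}

#' @export
print.summary.action_knn <- function(x, ...) {
  print(x$model)
  cat("\nPer-class training summary:\n")
  print(x$class_table, digits = 3)
  invisible(x)
}

#' Plot training-frame confidence by class
#'
#' Boxplots of the per-frame confidence `c(X_t)` grouped by action
#' class; low-confidence tails correspond to idle or style-shared
#' frames that many classes share.
#'
#' @param x an `action_knn` model.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.action_knn <- function(x, ...) {
  info <- x$index$info
  graphics::boxplot(confidence ~ action_label, data = info,
                    xlab = "class", ylab = "frame confidence c(X_t)", ...)
  invisible(x)
}

# descriptor matrix for a raw test sequence, processed exactly as in
# training but without onset trimming (test time labels are estimated)
.test_descriptors <- function(s, model) {
  ctl <- model$control
  sm <- gaussian_smooth(s, ctl$smooth_width, ctl$smooth_sigma)
  topo <- estimate_bone_lengths(sm)
  build_descriptors(sm, topo, ctl)
}

#' Predict action labels for new skeleton sequences
#'
#' Runs the recognition pipeline on raw (unsmoothed) test sequences.
#' In `"segmented"` mode each sequence is classified as a whole: every
#' frame's time label is estimated, windowed neighbours vote with their
#' training confidence, and the top class wins.  In `"stream"` mode each
#' sequence is consumed frame by frame with the decision gate
#' (`alpha_dec`, `T_th`); the reported label is the emitted decision
#' with the largest accumulated support (falling back to the final
#' tally leader when the gate never fires), and the frame of that
#' decision is reported as the latency.
#'
#' @param object an `action_knn` model.
#' @param newdata a [skeleton_sequence()], a list of them, or a
#'   `synthetic_dataset`.
#' @param mode `"segmented"` or `"stream"`.
#' @param ... unused.
#' @return A data.frame with one row per sequence: `sequence_id`,
#'   `label`, `score`, and in stream mode `decision_frame` (0-based
#'   frame of the first decision, `NA` if the gate never fired).  The
#'   full per-sequence decision objects are attached as the
#'   `"decisions"` attribute.
#' @export
predict.action_knn <- function(object, newdata,
                               mode = c("segmented", "stream"), ...) {
  mode <- match.arg(mode)
  seqs <- if (inherits(newdata, "synthetic_dataset")) newdata$sequences
  else newdata
  if (inherits(seqs, "skeleton_sequence")) seqs <- list(seqs)
  ctl <- object$control
  idx <- object$index
  out <- vector("list", length(seqs))
  decisions <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    d <- .test_descriptors(seqs[[i]], object)
    fw <- if (ctl$use_confidence_weights) d$info$frame_confidence else NULL
    if (mode == "segmented") {
      dec <- classify_segmented(d$X, idx, ctl$K, ctl$w_t, ctl$bin_width,
                                frame_weights = fw)
      out[[i]] <- data.frame(sequence_id = as.character(seqs[[i]]$sequence_id),
                             label = dec$label,
                             score = unname(max(dec$scores)),
                             stringsAsFactors = FALSE)
    } else {
      dec <- classify_stream(d$X, idx, ctl$K, ctl$w_t, ctl$bin_width,
                             ctl$T_th, ctl$alpha_dec, ctl$reset_policy,
                             ctl$decay_factor, frame_weights = fw)
      if (nrow(dec$events)) {
        # several gate firings are expected on a stream with idle
        # padding (idle votes are weak but self-consistent); the
        # sequence label is the decision with the most accumulated
        # support, not merely the earliest
        best <- which.max(dec$events$support)
        lab <- dec$events$label[best]
        frac <- dec$events$fraction[best]
        dframe <- dec$events$frame[best]
      } else {
        tot <- sum(dec$final_tally)
        lab <- names(dec$final_tally)[which.max(dec$final_tally)]
        frac <- if (tot > 0) max(dec$final_tally) / tot else NA_real_
        dframe <- NA_integer_
      }
      out[[i]] <- data.frame(sequence_id = as.character(seqs[[i]]$sequence_id),
                             label = lab, score = frac,
                             decision_frame = dframe,
                             stringsAsFactors = FALSE)
    }
    decisions[[i]] <- dec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "decisions") <- decisions
  res
}
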