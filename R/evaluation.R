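#' Partition a dataset by subject identity
#'
#' Cross-subject evaluation trains and tests on disjoint performers, so
#' the classifier must generalize across body sizes and styles rather
#' than memorize a subject.  The default split follows the customary
#' odd/even protocol (odd-numbered subjects train); any explicit subject
#' sets may be given, e.g. the classic `{2, 3, 5, 7, 9}` training split.
#'
#' @param dataset a `synthetic_dataset` or a list of
#'   [skeleton_sequence()] with `subject_id` set.
#' @param train_subjects,test_subjects subject id vectors; when only one
#'   is given the other side is the complement; when neither, odd
#'   subjects train.
#' @return A list of class `subject_split`: `train`, `test` (sequence
#'   lists) and `spec` (the subject sets).
#' @export
cross_subject_split <- function(dataset, train_subjects = NULL,
                                test_subjects = NULL) {
  seqs <- if (inherits(dataset, "synthetic_dataset")) dataset$sequences
  else dataset
  subj <- vapply(seqs, function(s) as.numeric(s$subject_id), numeric(1))
  all_s <- sort(unique(subj))
  if (is.null(train_subjects) && is.null(test_subjects))
    train_subjects <- all_s[all_s %% 2 == 1]
  if (is.null(train_subjects)) train_subjects <- setdiff(all_s, test_subjects)
  if (is.null(test_subjects)) test_subjects <- setdiff(all_s, train_subjects)
  unknown <- setdiff(c(train_subjects, test_subjects), all_s)
  if (length(unknown))
    stop("unknown subject id(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(train_subjects, test_subjects)))
    stop("train and test subject sets must be disjoint")
  if (!length(train_subjects) || !length(test_subjects))
    stop("both sides of the split must be nonempty")
  structure(list(train = seqs[subj %in% train_subjects],
                 test = seqs[subj %in% test_subjects],
                 spec = list(train_subjects = train_subjects,
                             test_subjects = test_subjects)),
            class = "subject_split")
}

#' Confusion matrix with per-class and overall accuracy
#'
#' @param truth,predicted character vectors of equal length.
#' @param classes class ordering; default the sorted union.
#' @return Object of class `confusion_matrix`: `counts` (C x C, rows =
#'   truth), `per_class` accuracy, `accuracy` (trace/total).
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  counts <- table(factor(truth, classes), factor(predicted, classes))
  names(dimnames(counts)) <- c("truth", "predicted")
  per_class <- diag(counts) / pmax(rowSums(counts), 1L)
  structure(list(counts = unclass(counts), per_class = per_class,
                 accuracy = sum(diag(counts)) / sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  cat(sprintf("\nOverall accuracy: %.4f\n", x$accuracy))
  invisible(x)
}

#' Evaluate a fitted recognizer on held-out sequences
#'
#' Runs [predict.action_knn()] on the test side and tabulates the
#' confusion matrix.  `mode = "segmented"` classifies each sequence with
#' known boundaries; `mode = "unsegmented"` feeds each sequence as a
#' stream (frame positions unknown, decision gate active) and scores
#' the first emitted decision, also reporting the decision latency in
#' frames.
#'
#' @param model an `action_knn` fit.
#' @param test list of labelled [skeleton_sequence()].
#' @param mode `"segmented"` or `"unsegmented"`.
#' @return A list of class `action_eval`: `confusion`
#'   ([confusion_matrix()]), `accuracy`, `results` (per-sequence
#'   data.frame with truth), and for unsegmented mode `latency` summary.
#' @export
evaluate_model <- function(model, test,
                           mode = c("segmented", "unsegmented")) {
  mode <- match.arg(mode)
  if (inherits(test, "subject_split")) test <- test$test
  truth <- vapply(test, function(s) as.character(s$action_label),
                  character(1))
  pred <- predict(model, test,
                  mode = if (mode == "segmented") "segmented" else "stream")
  pred$truth <- truth
  cm <- confusion_matrix(truth, pred$label,
                         classes = sort(names(model$index$class_weights)))
  out <- list(confusion = cm, accuracy = cm$accuracy, results = pred,
              mode = mode)
  if (mode == "unsegmented")
    out$latency <- summary(pred$decision_frame)
  structure(out, class = "action_eval")
}

#' @export
print.action_eval <- function(x, ...) {
  cat("Evaluation (", x$mode, " mode):\n\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Sweep the onset threshold and report accuracy per value
#'
#' Retrains and re-evaluates the recognizer for each onset threshold,
#' reproducing the shape of the threshold-optimization experiment on
#' synthetic data.  A degenerate threshold that leaves no trainable
#' sequence yields `NA` accuracy with a warning.
#'
#' @param dataset a `synthetic_dataset`.
#' @param th_values numeric vector of thresholds (>= 2 values).
#' @param control base [action_knn_control()]; its `Th` is overridden.
#' @param split optional [cross_subject_split()]; default odd/even.
#' @return data.frame with columns `Th`, `accuracy`, `n_excluded`.
#' @export
threshold_sweep <- function(dataset, th_values,
                            control = action_knn_control(),
                            split = NULL) {
  if (length(th_values) < 2L) stop("need at least 2 threshold values")
  if (is.null(split)) split <- cross_subject_split(dataset)
  rows <- lapply(th_values, function(th) {
    ctl <- control
    ctl$Th <- th
    acc <- NA_real_; nexc <- NA_integer_
    fit <- tryCatch(suppressWarnings(action_knn(split$train, ctl)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("Th = ", th, ": no trainable sequences; accuracy is NA",
              call. = FALSE)
    } else {
      nexc <- length(fit$excluded)
      acc <- evaluate_model(fit, split$test, "segmented")$accuracy
    }
    data.frame(Th = th, accuracy = acc, n_excluded = nexc)
  })
  do.call(rbind, rows)
}
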