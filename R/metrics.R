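#' Classification metrics report
#'
#' Accuracy (in percent), Cohen's kappa (chance agreement from the
#' confusion-matrix marginals), macro F1 and per-class precision/recall,
#' all derived from one confusion matrix.
#'
#' @param y_true true labels.
#' @param y_pred predicted labels, same length.
#' @param classes label set (canonical order); defaults to the attention
#'   states present in either vector.
#' @return Object of class `metrics_report`: list with `accuracy` (%),
#'   `kappa`, `f1` (macro), `precision` and `recall` (named per-class
#'   vectors), `confusion` (true x predicted matrix) and `n_samples`.
#' @export
compute_metrics <- function(y_true, y_pred, classes = NULL) {
  if (!length(y_true)) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.null(classes)) {
    present <- unique(c(y_true, y_pred))
    classes <- attention_states()[attention_states() %in% present]
    if (!length(classes)) classes <- sort(present)
  }
  if (!all(y_true %in% classes) || !all(y_pred %in% classes)) {
    stop("labels outside the declared class set")
  }
  cm <- table(factor(y_true, classes), factor(y_pred, classes))
  cm <- matrix(as.numeric(cm), nrow = length(classes),
               dimnames = list(true = classes, predicted = classes))
  metrics_from_confusion(cm)
}

#' Metrics from a confusion matrix
#'
#' @param cm square numeric matrix, true classes in rows, predictions in
#'   columns (dimnames give the class labels).
#' @return A `metrics_report` (see [compute_metrics()]).
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  n <- sum(cm)
  classes <- rownames(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) 0 else (po - pe) / (1 - pe)
  prec <- diag(cm) / colSums(cm)
  rec <- diag(cm) / rowSums(cm)
  prec[!is.finite(prec)] <- 0
  rec[!is.finite(rec)] <- 0
  f1c <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(accuracy = 100 * po, kappa = kappa, f1 = mean(f1c),
                 f1_per_class = stats::setNames(f1c, classes),
                 precision = stats::setNames(prec, classes),
                 recall = stats::setNames(rec, classes),
                 confusion = cm, n_samples = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  Acc %.2f%%  kappa %.3f  macro-F1 %.3f\n",
              x$n_samples, x$accuracy, x$kappa, x$f1))
  tab <- rbind(precision = x$precision, recall = x$recall)
  print(round(tab, 3))
  invisible(x)
}

#' One-row model summaries
#' @param x object to summarise.
#' @param ... passed to methods.
#' @return One-row data.frame.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Tidy one-row summary of a metrics report
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return One-row data.frame (accuracy, kappa, f1, n).
#' @export
glance.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, kappa = x$kappa, f1 = x$f1,
             n = x$n_samples)
}

#' Average a list of metrics reports
#'
#' Element-wise mean of accuracy, kappa, F1 and per-class rows (fold
#' averaging); the confusion matrices are summed.
#'
#' @param reports list of `metrics_report`.
#' @return A `metrics_report` whose scalar fields are fold means.
#' @export
mean_metrics <- function(reports) {
  stopifnot(length(reports) >= 1)
  out <- reports[[1]]
  out$accuracy <- mean(vapply(reports, `[[`, numeric(1), "accuracy"))
  out$kappa <- mean(vapply(reports, `[[`, numeric(1), "kappa"))
  out$f1 <- mean(vapply(reports, `[[`, numeric(1), "f1"))
  out$precision <- rowMeans(vapply(reports, `[[`,
                                   numeric(length(out$precision)),
                                   "precision"))
  out$recall <- rowMeans(vapply(reports, `[[`,
                                numeric(length(out$recall)), "recall"))
  out$f1_per_class <- rowMeans(vapply(reports, `[[`,
                                      numeric(length(out$f1_per_class)),
                                      "f1_per_class"))
  out$confusion <- Reduce(`+`, lapply(reports, `[[`, "confusion"))
  out$n_samples <- sum(vapply(reports, `[[`, numeric(1), "n_samples"))
  out
}

#' Stratified fold assignment
#'
#' @param y labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`, class-stratified (fold
#'   test sizes differ by at most 1 per class).
#' @export
stratified_folds <- function(y, k = 5, seed = 1) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has fewer samples (", length(idx),
           ") than folds (", k, ")")
    }
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Stratified train/validation split
#'
#' @param y labels.
#' @param val_frac validation fraction per class.
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
stratified_split <- function(y, val_frac = 0.2, seed = 1) {
  set.seed(seed)
  val <- unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(val_frac * length(idx))))
  }))
  list(train = setdiff(seq_along(y), val), val = sort(val))
}

#' Stratified k-fold cross-validation
#'
#' Every sample is tested exactly once; folds are class-stratified. The
#' model builder receives the training subset and must return an object
#' whose `predict_fun(model, test_subset)` yields labels.
#'
#' @param builder function `(x_train, y_train)` returning a fitted model.
#' @param predict_fun function `(model, x_test)` returning labels.
#' @param x data: a list (subset by `[`) or a matrix (subset by rows).
#' @param y labels.
#' @param k folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param classes class set for the reports.
#' @return List with `fold_reports` (list of `metrics_report`), `mean`
#'   (their average), and `folds` (the assignment).
#' @export
kfold_cv <- function(builder, predict_fun, x, y, k = 5, seed = 1,
                     classes = NULL) {
  folds <- stratified_folds(y, k, seed)
  take <- function(data, idx) {
    if (is.matrix(data) || is.data.frame(data)) data[idx, , drop = FALSE]
    else data[idx]
  }
  reports <- lapply(seq_len(k), function(f) {
    tr <- folds != f; te <- !tr
    model <- builder(take(x, which(tr)), y[tr])
    pred <- predict_fun(model, take(x, which(te)))
    compute_metrics(y[te], pred, classes = classes)
  })
  list(fold_reports = reports, mean = mean_metrics(reports),
       folds = folds)
}

#' Online tally table
#'
#' Per-state counts of presented (`T`) and correctly predicted (`C`)
#' one-second windows, with overall accuracy `sum(C) / sum(T)`.
#'
#' @param y_true,y_pred per-window true and predicted labels.
#' @param classes class set.
#' @return Object of class `tally_table`: data.frame with columns
#'   `state`, `T`, `C`; overall accuracy attached as attribute
#'   `"overall_accuracy"`.
#' @export
tally_table <- function(y_true, y_pred, classes = NULL) {
  if (is.null(classes)) {
    classes <- attention_states()[attention_states() %in% unique(y_true)]
  }
  Tn <- vapply(classes, function(cl) sum(y_true == cl), numeric(1))
  Cn <- vapply(classes, function(cl)
    sum(y_true == cl & y_pred == y_true), numeric(1))
  out <- data.frame(state = classes, T = Tn, C = Cn,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "overall_accuracy") <- sum(Cn) / sum(Tn)
  class(out) <- c("tally_table", "data.frame")
  out
}

#' Overall accuracy from tally counts
#'
#' `sum(C) / sum(T)` in percent — the arithmetic used to summarise an
#' online session from its per-state tally.
#'
#' @param T_counts,C_counts per-state totals and correct counts.
#' @return Percentage in `[0, 100]`.
#' @export
tally_overall_accuracy <- function(T_counts, C_counts) {
  stopifnot(length(T_counts) == length(C_counts), all(C_counts <= T_counts),
            all(C_counts >= 0))
  100 * sum(C_counts) / sum(T_counts)
}

#' Simulated online detection loop
#'
#' Replays a labelled recording through the online preprocessing chain
#' (0.1-45 Hz, 100 Hz), slicing each valid event into consecutive 1-s
#' chunks aligned to event boundaries, predicting each chunk, and
#' tallying presented/correct counts per state.
#'
#' @param rec an [eeg_recording()] with ground-truth events, on the full
#'   montage.
#' @param model a trained [build_gru_eegnet()] model, or a function
#'   `(window_sample) -> label` (e.g. an oracle for testing).
#' @param chunk_s chunk length in seconds (fixed at 1 in the standard
#'   loop).
#' @return List with `predictions` (data.frame: window index, true,
#'   predicted) and `tally` (a [tally_table()]).
#' @export
replay_online <- function(rec, model, chunk_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (chunk_s != 1) {
    stop("the online loop operates on 1-s chunks; chunk_s must be 1")
  }
  windows <- preprocess_recording(rec, preset = "online",
                                  artifact_threshold_uv = Inf)
  y_true <- window_labels(windows)
  if (is.function(model)) {
    y_pred <- vapply(windows, model, character(1))
  } else if (inherits(model, "gru_eegnet")) {
    bands <- windows_to_band_features(windows)
    y_pred <- predict_state(model, bands)$label
  } else {
    stop("model must be a gru_eegnet or a prediction function")
  }
  tl <- tally_table(y_true, y_pred)
  list(predictions = data.frame(window = seq_along(windows),
                                true = y_true, predicted = y_pred,
                                stringsAsFactors = FALSE),
       tally = tl)
}
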