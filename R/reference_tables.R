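#' Published online-detection tally (reference table)
#'
#' Per-subject online sessions from the benchmark study of this decoder:
#' for each of five subjects and both models (EEGNet and GRU-EEGNet),
#' the number of 1-s windows presented (`*_T`) and correctly classified
#' (`*_C`) per attention state, together with the printed overall
#' accuracy. Shipped so the tally arithmetic
#' (`overall = sum(C) / sum(T)`) can be validated against published
#' numbers.
#'
#' @return data.frame, one row per model x subject.
#' @export
online_tally_reference <- function() {
  path <- system.file("extdata", "online_tally_reference.csv",
                      package = "eegdrive", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published per-subject offline metrics (reference table)
#'
#' Four-class cross-validated performance of the composite decoder for
#' ten subjects (accuracy %, Cohen's kappa, F1, per-class precision and
#' recall), plus the printed column of averages, as published in the
#' benchmark study. Used to validate metric-aggregation arithmetic.
#'
#' @return List with `subjects` (10-row data.frame) and `printed_avg`
#'   (one-row data.frame of the published averages).
#' @export
offline_metrics_reference <- function() {
  path <- system.file("extdata", "offline_subject_metrics_reference.csv",
                      package = "eegdrive", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  list(subjects = tab[tab$subject != "Avg", , drop = FALSE],
       printed_avg = tab[tab$subject == "Avg", , drop = FALSE])
}

#' Recompute overall online accuracies from the reference tally
#'
#' Applies [tally_overall_accuracy()] to each model x subject row of
#' [online_tally_reference()] and averages per model.
#'
#' @return data.frame with columns `model`, `subject`,
#'   `recomputed_accuracy_pct`, `printed_accuracy_pct`; per-model means
#'   attached as attribute `"model_means"` (named numeric vector).
#' @export
recompute_online_accuracies <- function() {
  tab <- online_tally_reference()
  Tm <- as.matrix(tab[, c("visual_T", "auditory_T", "cognitive_T",
                          "focused_T")])
  Cm <- as.matrix(tab[, c("visual_C", "auditory_C", "cognitive_C",
                          "focused_C")])
  rec <- vapply(seq_len(nrow(tab)), function(i)
    tally_overall_accuracy(Tm[i, ], Cm[i, ]), numeric(1))
  out <- data.frame(model = tab$model, subject = tab$subject,
                    recomputed_accuracy_pct = rec,
                    printed_accuracy_pct = tab$printed_accuracy_pct,
                    stringsAsFactors = FALSE)
  means <- tapply(round(rec, 2), tab$model, mean)
  attr(out, "model_means") <- means
  out
}
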