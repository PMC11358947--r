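#' Standard 64-channel actiCAP montage
#'
#' Ordered electrode labels of the extended 10-20 (10-10) system as laid out
#' on a 64-channel actiCAP-style cap, including the mastoid electrodes TP9
#' and TP10 and the frontal-polar pair Fp1/Fp2.
#'
#' @return Character vector of 64 unique channel labels.
#' @export
montage_64 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
    "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
    "FT9", "FT7", "FC3", "FC4", "FT8", "FT10",
    "C5", "C1", "C2", "C6", "TP7", "CP3", "CPz", "CP4", "TP8",
    "P5", "P1", "P2", "P6", "PO7", "PO3", "POz", "PO4", "PO8")
}

#' Scalp region of each electrode label
#'
#' Classifies electrode labels into coarse scalp regions by their 10-20
#' prefix. Used by the synthetic generator to apply topographically
#' structured band-power effects (e.g. parietal alpha suppression).
#'
#' @param channel_names character vector of electrode labels.
#' @return Character vector with values in
#'   `c("frontal", "central", "temporal", "parietal", "occipital")`.
#' @export
channel_region <- function(channel_names) {
  prefix <- sub("^([A-Za-z]+).*$", "\\1", channel_names)
  region <- rep("central", length(channel_names))
  region[prefix %in% c("Fp", "AF", "F", "FC", "FT")] <- "frontal"
  region[prefix %in% c("T", "TP")] <- "temporal"
  region[prefix %in% c("CP", "P")] <- "parietal"
  region[prefix %in% c("PO", "O")] <- "occipital"
  region
}

#' Hemisphere of each electrode label
#'
#' Odd digit suffixes are left-hemisphere, even are right, `z` is midline.
#'
#' @param channel_names character vector of electrode labels.
#' @return Character vector with values in `c("left", "right", "midline")`.
#' @export
channel_hemisphere <- function(channel_names) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", channel_names)))
  out <- ifelse(is.na(num), "midline", ifelse(num %% 2 == 1, "left", "right"))
  out
}

#' Driving attention state labels
#'
#' The four-class label set: focused driving plus the three distraction
#' types, in the fixed order used everywhere in the package (prediction
#' tie-breaks, confusion matrices, task codes).
#'
#' @return Character vector `c("focused", "visual", "auditory", "cognitive")`.
#' @export
attention_states <- function() {
  c("focused", "visual", "auditory", "cognitive")
}

#' Trial duration in seconds for each attention state
#'
#' Focused trials last 5 s, visual distractor subtasks 5 s, auditory
#' (2-back digit) subtasks 15 s and cognitive (mental rotation) subtasks
#' 10 s; one-second windowing therefore yields 5/5/15/10 windows per trial.
#'
#' @param state character vector of state labels.
#' @return Numeric vector of durations in seconds.
#' @export
state_duration_s <- function(state) {
  dur <- c(focused = 5, visual = 5, auditory = 15, cognitive = 10)
  unname(dur[match(state, names(dur))])
}

#' Expand a task code to its class subset
#'
#' Task codes follow the f/v/a/c shorthand: `"fv"` is focused vs visual,
#' `"fvac"` the full four-class problem, etc.
#'
#' @param task a task code such as `"fv"`, `"fca"` or `"fvac"`.
#' @return Character vector of state labels in canonical order.
#' @export
task_classes <- function(task) {
  stopifnot(is.character(task), length(task) == 1L, nchar(task) >= 2L)
  key <- c(f = "focused", v = "visual", a = "auditory", c = "cognitive")
  letters1 <- strsplit(task, "")[[1]]
  if (!all(letters1 %in% names(key)) || anyDuplicated(letters1)) {
    stop("invalid task code: ", task)
  }
  states <- unname(key[letters1])
  attention_states()[attention_states() %in% states]
}

#' All seven classification task codes
#' @return `c("fv","fa","fc","fva","fvc","fca","fvac")`
#' @export
all_tasks <- function() c("fv", "fa", "fc", "fva", "fvc", "fca", "fvac")
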