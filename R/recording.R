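#' Construct an EEG recording object
#'
#' The package's container for continuous multichannel EEG: a channels x
#' samples matrix in microvolts, its sampling rate, ordered channel labels
#' and a table of event markers (trial onsets with state labels).
#'
#' @param data numeric matrix, channels in rows, samples in columns, in uV.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector, one unique label per data row.
#' @param events data.frame with columns `sample_index` (0-based sample
#'   position of the trial onset), `state` (one of
#'   [attention_states()]), `duration_s` (trial length in seconds) and
#'   `valid` (logical; trials whose behavioural feedback was missed are
#'   flagged invalid and excluded at epoching). May be empty.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names, events = empty_events()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a positive scalar (Hz)")
  }
  channel_names <- as.character(channel_names)
  if (nrow(data) != length(channel_names)) {
    stop("channel count mismatch: ", nrow(data), " data rows vs ",
         length(channel_names), " channel names")
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  events <- validate_events(events, n_samples = ncol(data))
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         events = events),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Empty event table with the canonical columns
#' @return zero-row data.frame with columns sample_index, state,
#'   duration_s, valid.
#' @export
empty_events <- function() {
  data.frame(sample_index = integer(0), state = character(0),
             duration_s = numeric(0), valid = logical(0),
             stringsAsFactors = FALSE)
}

validate_events <- function(events, n_samples) {
  if (is.null(events)) return(empty_events())
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  required <- c("sample_index", "state", "duration_s", "valid")
  missing <- setdiff(required, names(events))
  if (length(missing)) stop("events missing columns: ",
                            paste(missing, collapse = ", "))
  events <- events[required]
  if (nrow(events)) {
    events$sample_index <- as.integer(events$sample_index)
    events$state <- as.character(events$state)
    events$duration_s <- as.numeric(events$duration_s)
    events$valid <- as.logical(events$valid)
    if (any(events$sample_index < 0L) ||
        any(events$sample_index >= n_samples)) {
      stop("event sample indices must lie in [0, n_samples)")
    }
    bad <- !events$state %in% attention_states()
    if (any(bad)) stop("unknown event states: ",
                       paste(unique(events$state[bad]), collapse = ", "))
  }
  rownames(events) <- NULL
  events
}

#' Number of samples in a recording
#' @param rec an `eeg_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Construct a single labelled trial epoch
#'
#' @param data channels x samples matrix (uV) for one trial.
#' @param state state label.
#' @param trial_id integer identifier.
#' @param fs sampling rate of `data`.
#' @return Object of class `trial_epoch`.
#' @export
trial_epoch <- function(data, state, trial_id, fs) {
  stopifnot(is.matrix(data), state %in% attention_states())
  structure(list(data = data, state = state,
                 trial_id = as.integer(trial_id), fs = fs),
            class = "trial_epoch")
}

#' Construct a one-second analysis window
#'
#' The classification atom: one second of EEG at the post-downsampling
#' rate, carrying its state label and provenance.
#'
#' @param data channels x T matrix, T = fs * 1 s.
#' @param state state label.
#' @param source_trial trial_id of the parent epoch.
#' @param window_index 0-based position within the parent trial.
#' @param fs sampling rate of `data`.
#' @return Object of class `window_sample`.
#' @export
window_sample <- function(data, state, source_trial, window_index, fs) {
  stopifnot(is.matrix(data), state %in% attention_states())
  if (ncol(data) != round(fs)) {
    stop("window must be exactly 1 s long: expected ", round(fs),
         " samples, got ", ncol(data))
  }
  structure(list(data = data, state = state,
                 source_trial = as.integer(source_trial),
                 window_index = as.integer(window_index), fs = fs),
            class = "window_sample")
}

#' State labels of a list of windows or epochs
#' @param x list of `window_sample` or `trial_epoch` objects.
#' @return character vector of labels.
#' @export
window_labels <- function(x) vapply(x, function(w) w$state, character(1))
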