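#' Select analysis channels
#'
#' The default policy reproduces the study montage reduction: from the
#' 64-channel cap, drop the reference `Fz`, the ocular-dominated pair
#' `Fp1`/`Fp2` and the mastoids `TP9`/`TP10` (already consumed by
#' re-referencing), leaving exactly 59 analysis channels in their original
#' order.
#'
#' @param rec an [eeg_recording()].
#' @param policy `"default59"` (drop Fz, Fp1, Fp2, TP9, TP10),
#'   `"identity"` (keep everything), or a character vector of channel
#'   names to keep, in recording order.
#' @return An [eeg_recording()] with the reduced montage.
#' @export
select_channels <- function(rec, policy = "default59") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (identical(policy, "identity")) return(rec)
  if (identical(policy, "default59")) {
    drop <- c("Fz", "Fp1", "Fp2", "TP9", "TP10")
    missing <- setdiff(drop, rec$channel_names)
    if (length(missing)) {
      stop("channel-selection policy requires channels absent from the ",
           "montage: ", paste(missing, collapse = ", "))
    }
    keep <- !(rec$channel_names %in% drop)
  } else {
    missing <- setdiff(policy, rec$channel_names)
    if (length(missing)) {
      stop("requested channels absent from the montage: ",
           paste(missing, collapse = ", "))
    }
    keep <- rec$channel_names %in% policy
  }
  eeg_recording(rec$data[keep, , drop = FALSE], rec$fs,
                rec$channel_names[keep], rec$events)
}

#' Re-reference to the mastoid average
#'
#' Subtracts 0.5 * (TP9 + TP10) from every channel, sample-wise. The
#' mastoid channels themselves are kept (afterwards holding their
#' deviation from the mastoid mean) so that [select_channels()] can drop
#' them in a separate, explicit step.
#'
#' @param rec an [eeg_recording()] containing TP9 and TP10.
#' @return The re-referenced [eeg_recording()].
#' @export
rereference_mastoid <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  idx <- match(c("TP9", "TP10"), rec$channel_names)
  if (anyNA(idx)) stop("mastoid channels TP9/TP10 absent; cannot re-reference")
  ref <- 0.5 * (rec$data[idx[1], ] + rec$data[idx[2], ])
  data <- sweep(rec$data, 2, ref, "-")
  eeg_recording(data, rec$fs, rec$channel_names, rec$events)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth high-pass and low-pass sections applied
#' forward-backward (zero phase) per channel. Each channel is demeaned
#' before filtering, so the DC component is fully removed whenever
#' `low_hz > 0`.
#'
#' @param rec an [eeg_recording()].
#' @param low_hz high-pass cutoff in Hz; 0 disables the high-pass.
#' @param high_hz low-pass cutoff in Hz, must be below Nyquist.
#' @param order Butterworth order of each section.
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low_hz = 0.5, high_hz = 50, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("need 0 <= low_hz < high_hz < fs/2 (Nyquist = ", nyq, " Hz)")
  }
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  hp <- if (low_hz > 0) signal::butter(order, low_hz / nyq, type = "high")
  data <- rec$data
  for (i in seq_len(nrow(data))) {
    x <- data[i, ]
    if (low_hz > 0) {
      x <- x - mean(x)
      x <- signal::filtfilt(hp, x)
    }
    data[i, ] <- signal::filtfilt(lp, x)
  }
  eeg_recording(data, rec$fs, rec$channel_names, rec$events)
}

#' Downsample a recording
#'
#' Anti-alias low-pass filtering (zero-phase Butterworth at 0.8 x the
#' target Nyquist) followed by decimation. Event sample indices are
#' rescaled to the new rate.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target sampling rate in Hz; must divide `fs`.
#' @return The resampled [eeg_recording()].
#' @export
downsample <- function(rec, target_fs = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs) stop("target_fs must not exceed fs")
  if (target_fs == rec$fs) return(rec)
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    stop("target_fs must divide fs (", rec$fs, " / ", target_fs,
         " is not an integer)")
  }
  factor <- as.integer(round(factor))
  cutoff <- 0.8 * (target_fs / 2)
  aa <- signal::butter(8, cutoff / (rec$fs / 2), type = "low")
  idx <- seq(1L, ncol(rec$data), by = factor)
  data <- matrix(0, nrow = nrow(rec$data), ncol = length(idx))
  for (i in seq_len(nrow(rec$data))) {
    data[i, ] <- signal::filtfilt(aa, rec$data[i, ])[idx]
  }
  events <- rec$events
  if (nrow(events)) {
    events$sample_index <- as.integer(events$sample_index %/% factor)
  }
  eeg_recording(data, target_fs, rec$channel_names, events)
}

#' Cut a recording into labelled trial epochs
#'
#' One epoch per valid event, spanning exactly the state-specific trial
#' duration (focused/visual 5 s, cognitive 10 s, auditory 15 s). Events
#' flagged invalid (missed behavioural feedback) are excluded here, before
#' any feature computation. Epochs that would run past the end of the
#' recording are skipped with a warning.
#'
#' @param rec an [eeg_recording()] with events.
#' @return List of [trial_epoch()] objects. The number of skipped
#'   (truncated) events is attached as attribute `"n_truncated"`.
#' @export
epoch_trials <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ev <- rec$events
  epochs <- list()
  n_trunc <- 0L
  if (nrow(ev)) {
    ev <- ev[ev$valid, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      len <- as.integer(round(ev$duration_s[i] * rec$fs))
      start <- ev$sample_index[i] + 1L           # matrix column (1-based)
      if (start + len - 1L > ncol(rec$data)) {
        n_trunc <- n_trunc + 1L
        next
      }
      epochs[[length(epochs) + 1L]] <- trial_epoch(
        rec$data[, start:(start + len - 1L), drop = FALSE],
        ev$state[i], trial_id = length(epochs) + 1L, fs = rec$fs)
    }
  }
  if (n_trunc > 0L) {
    warning(n_trunc, " event(s) extended past the end of the recording ",
            "and were skipped")
  }
  attr(epochs, "n_truncated") <- n_trunc
  epochs
}

#' Slice epochs into one-second windows
#'
#' Non-overlapping, consecutive 1-s windows; a D-second trial yields
#' exactly D windows, each inheriting the trial's label.
#'
#' @param epochs list of [trial_epoch()] objects (post-downsampling).
#' @return List of [window_sample()] objects.
#' @export
window_epochs <- function(epochs) {
  out <- list()
  for (ep in epochs) {
    w_len <- as.integer(round(ep$fs))
    n_win <- ncol(ep$data) %/% w_len
    for (k in seq_len(n_win)) {
      cols <- ((k - 1L) * w_len + 1L):(k * w_len)
      out[[length(out) + 1L]] <- window_sample(
        ep$data[, cols, drop = FALSE], ep$state,
        source_trial = ep$trial_id, window_index = k - 1L, fs = ep$fs)
    }
  }
  out
}

#' Amplitude-based artifact rejection
#'
#' Drops every window containing any sample whose absolute amplitude
#' exceeds the threshold on any channel (default 100 uV), the standard
#' gross-artifact rule for ocular and muscle activity.
#'
#' @param windows list of [window_sample()] objects (uV).
#' @param threshold_uv rejection threshold in microvolts.
#' @return The surviving windows; the number rejected is attached as
#'   attribute `"n_rejected"`.
#' @export
reject_artifacts <- function(windows, threshold_uv = 100) {
  keep <- vapply(windows, function(w) max(abs(w$data)) <= threshold_uv,
                 logical(1))
  out <- windows[keep]
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Preprocessing presets
#'
#' Two named filter/rate configurations: `"offline"` (0.5-50 Hz band,
#' 100 Hz) used for training-set preparation, and `"online"` (0.1-45 Hz,
#' 100 Hz) used by the streaming detection loop. The band mismatch between
#' the two settings is deliberate and preserved as-is.
#'
#' @param preset `"offline"` or `"online"`.
#' @return List with elements `low_hz`, `high_hz`, `target_fs`.
#' @export
preprocess_preset <- function(preset = c("offline", "online")) {
  preset <- match.arg(preset)
  switch(preset,
         offline = list(low_hz = 0.5, high_hz = 50, target_fs = 100),
         online  = list(low_hz = 0.1, high_hz = 45, target_fs = 100))
}

#' Full preprocessing chain: recording to windows
#'
#' Mastoid re-referencing, channel selection to the 59-channel analysis
#' montage, band-pass filtering, downsampling, epoching, one-second
#' windowing and artifact rejection, in that order.
#'
#' @param rec an [eeg_recording()] on the full 64-channel montage.
#' @param preset preprocessing preset name, see [preprocess_preset()].
#' @param artifact_threshold_uv rejection threshold; `Inf` disables.
#' @param channel_policy passed to [select_channels()].
#' @return List of [window_sample()] objects with attributes
#'   `"n_rejected"` and `"n_truncated"`.
#' @export
preprocess_recording <- function(rec, preset = "offline",
                                 artifact_threshold_uv = 100,
                                 channel_policy = "default59") {
  p <- preprocess_preset(preset)
  rec <- rereference_mastoid(rec)
  rec <- select_channels(rec, channel_policy)
  rec <- bandpass_filter(rec, p$low_hz, p$high_hz)
  rec <- downsample(rec, p$target_fs)
  epochs <- epoch_trials(rec)
  windows <- window_epochs(epochs)
  out <- reject_artifacts(windows, artifact_threshold_uv)
  attr(out, "n_truncated") <- attr(epochs, "n_truncated")
  out
}
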