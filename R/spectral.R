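#' Welch estimator configuration
#'
#' Parameters of the modified-periodogram average: segment length `M`,
#' fractional overlap, taper window, transform length `nfft` and
#' one-sided output. The default configuration for one-second windows at
#' 100 Hz (`M = nfft = 100`, no overlap, Hanning taper) produces a single
#' segment and 1-Hz bins over 0-50 Hz — the resolution at which the
#' theta/alpha/beta blocks are defined.
#'
#' @param M segment length in samples.
#' @param overlap fraction in `[0, 1)`; segment step is `M * (1 - overlap)`.
#' @param window `"rectangular"`, `"hanning"` or `"hamming"`.
#' @param nfft transform length, `>= M` (segments are zero-padded).
#' @param onesided return the one-sided spectrum (default TRUE).
#' @return List of class `welch_config`.
#' @export
welch_config <- function(M = 100, overlap = 0,
                         window = c("hanning", "rectangular", "hamming"),
                         nfft = M, onesided = TRUE) {
  window <- match.arg(window)
  stopifnot(M >= 1, overlap >= 0, overlap < 1, nfft >= M)
  structure(list(M = as.integer(M), overlap = overlap, window = window,
                 nfft = as.integer(nfft), onesided = isTRUE(onesided)),
            class = "welch_config")
}

#' Taper window samples
#'
#' @param window window name (`"rectangular"`, `"hanning"`, `"hamming"`).
#' @param M window length.
#' @return Numeric vector of length `M`.
#' @export
taper_window <- function(window, M) {
  n <- seq_len(M) - 1L
  switch(window,
         rectangular = rep(1, M),
         # periodic (DFT-even) forms, the convention under which the
         # estimator's normalisation is exact for segment averaging
         hanning = 0.5 - 0.5 * cos(2 * pi * n / M),
         hamming = 0.54 - 0.46 * cos(2 * pi * n / M),
         stop("unknown window: ", window))
}

#' Window normalization factor U
#'
#' `U = (1/M) * sum(w(n)^2)`, the mean squared taper amplitude that makes
#' the modified periodogram asymptotically unbiased as a density estimate.
#' For the rectangular window `U = 1`.
#'
#' @param window window name.
#' @param M window length.
#' @return Scalar `U > 0`.
#' @export
window_norm_factor <- function(window, M) {
  w <- taper_window(window, M)
  sum(w^2) / M
}

#' Split a signal into (possibly overlapping) segments
#'
#' Segment i starts at sample `1 + (i-1) * step` with
#' `step = M * (1 - overlap)`; the number of segments is
#' `L = floor((N - M) / step) + 1`. With zero overlap this is the plain
#' partition into consecutive blocks of length `M`.
#'
#' @param x numeric vector of length `N >= M`.
#' @param cfg a [welch_config()].
#' @return `M x L` matrix, one segment per column.
#' @export
segment_data <- function(x, cfg) {
  stopifnot(inherits(cfg, "welch_config"))
  N <- length(x)
  M <- cfg$M
  if (M > N) stop("segment length M = ", M, " exceeds data length N = ", N)
  step <- max(1L, as.integer(round(M * (1 - cfg$overlap))))
  L <- (N - M) %/% step + 1L
  starts <- (seq_len(L) - 1L) * step + 1L
  vapply(starts, function(s) x[s:(s + M - 1L)], numeric(M))
}

#' Welch power spectral density of a window sample
#'
#' The average of modified periodograms: each length-`M` segment is
#' tapered, Fourier transformed, and its squared magnitude normalised by
#' `M * U * fs` (density scaling, power per Hz); the per-segment
#' periodograms are then averaged. The one-sided spectrum doubles all
#' bins except DC and Nyquist.
#'
#' @param x a [window_sample()], an [eeg_recording()], or a channels x
#'   samples numeric matrix (a plain vector is treated as one channel).
#' @param cfg a [welch_config()]; defaults to the 1-Hz-bin configuration.
#' @param fs sampling rate in Hz; taken from `x` when it carries one.
#' @return Object of class `psd_matrix`: list with `values`
#'   (frequency-bin x channel matrix), `freqs` (bin centres in Hz),
#'   `in_db = FALSE`, `normalized = FALSE`, `channel_names`.
#' @export
welch_psd <- function(x, cfg = welch_config(), fs = NULL) {
  channel_names <- NULL
  if (inherits(x, "window_sample") || inherits(x, "eeg_recording")) {
    if (is.null(fs)) fs <- x$fs
    if (inherits(x, "eeg_recording")) channel_names <- x$channel_names
    x <- x$data
  }
  if (is.null(fs)) stop("fs is required for plain matrix/vector input")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  stopifnot(inherits(cfg, "welch_config"))
  if (cfg$M > ncol(x)) {
    stop("segment length M = ", cfg$M, " exceeds sample length ", ncol(x))
  }
  w <- taper_window(cfg$window, cfg$M)
  U <- window_norm_factor(cfg$window, cfg$M)
  nfft <- cfg$nfft
  n_bins <- if (cfg$onesided) nfft %/% 2 + 1L else nfft
  values <- matrix(0, nrow = n_bins, ncol = nrow(x))
  for (ch in seq_len(nrow(x))) {
    segs <- segment_data(x[ch, ], cfg)          # M x L
    tapered <- segs * w
    if (nfft > cfg$M) {
      tapered <- rbind(tapered,
                       matrix(0, nrow = nfft - cfg$M, ncol = ncol(tapered)))
    }
    spec <- Mod(stats::mvfft(tapered))^2 / (cfg$M * U * fs)
    pxx <- rowMeans(spec)                        # average over L segments
    if (cfg$onesided) {
      pxx <- pxx[seq_len(n_bins)]
      dbl <- 2:(n_bins - if (nfft %% 2 == 0) 1L else 0L)
      pxx[dbl] <- 2 * pxx[dbl]
    }
    values[, ch] <- pxx
  }
  freqs <- (seq_len(n_bins) - 1L) * fs / nfft
  structure(list(values = values, freqs = freqs, in_db = FALSE,
                 normalized = FALSE, channel_names = channel_names),
            class = "psd_matrix")
}

#' @export
print.psd_matrix <- function(x, ...) {
  cat(sprintf("<psd_matrix> %d bins (%.1f-%.1f Hz) x %d channels%s%s\n",
              nrow(x$values), min(x$freqs), max(x$freqs), ncol(x$values),
              if (x$in_db) ", dB" else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Convert a PSD to per-channel normalised decibels
#'
#' `10 * log10(max(p, eps))` followed by z-scoring each channel across its
#' own frequency bins (mean 0, sd 1 within the sample). The per-sample
#' normalisation keeps the transform stateless, so the online path can
#' apply it chunk by chunk. A channel with zero variance after the dB
#' transform is filled with zeros and flagged.
#'
#' @param psd a `psd_matrix` not yet in dB.
#' @param eps power floor before the log (default 1e-12).
#' @return A `psd_matrix` with `in_db = TRUE`, `normalized = TRUE`; the
#'   indices of any degenerate channels are attached as attribute
#'   `"flat_channels"`.
#' @export
psd_to_db_norm <- function(psd, eps = 1e-12) {
  stopifnot(inherits(psd, "psd_matrix"))
  if (psd$in_db) stop("PSD is already in dB")
  db <- 10 * log10(pmax(psd$values, eps))
  mu <- colMeans(db)
  sdv <- apply(db, 2, stats::sd)
  flat <- which(!is.finite(sdv) | sdv < 1e-14)
  sdv[flat] <- 1
  out <- sweep(sweep(db, 2, mu, "-"), 2, sdv, "/")
  out[, flat] <- 0
  res <- psd
  res$values <- out
  res$in_db <- TRUE
  res$normalized <- TRUE
  attr(res, "flat_channels") <- flat
  res
}

#' Frequency bands of the decoder
#'
#' Theta 4-8 Hz, alpha 8-13 Hz, beta 13-35 Hz, edges inclusive (adjacent
#' bands share their edge bin), giving 5/6/23 bins at 1-Hz resolution.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
band_definitions <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 35))
}

#' Extract theta/alpha/beta blocks from a PSD
#'
#' @param psd a `psd_matrix` with 1-Hz bin spacing covering at least
#'   0-35 Hz.
#' @param label optional state label carried along for training.
#' @return Object of class `band_features`: list with matrices `theta`
#'   (5 x channels), `alpha` (6 x channels), `beta` (23 x channels) and
#'   `label`.
#' @export
extract_bands <- function(psd, label = NA_character_) {
  stopifnot(inherits(psd, "psd_matrix"))
  bands <- band_definitions()
  pick <- function(rng) {
    idx <- which(psd$freqs >= rng[1] - 1e-9 & psd$freqs <= rng[2] + 1e-9)
    if (!length(idx)) stop("requested band ", rng[1], "-", rng[2],
                           " Hz exceeds available bins")
    if (max(psd$freqs[idx]) < rng[2] - 1e-9) {
      stop("PSD does not cover the ", rng[1], "-", rng[2], " Hz band")
    }
    psd$values[idx, , drop = FALSE]
  }
  structure(list(theta = pick(bands$theta), alpha = pick(bands$alpha),
                 beta = pick(bands$beta), label = label),
            class = "band_features")
}

#' @export
print.band_features <- function(x, ...) {
  cat(sprintf("<band_features> theta %dx%d, alpha %dx%d, beta %dx%d, label %s\n",
              nrow(x$theta), ncol(x$theta), nrow(x$alpha), ncol(x$alpha),
              nrow(x$beta), ncol(x$beta), x$label))
  invisible(x)
}

#' Combined three-band feature vector
#'
#' Reduces each band to one value per channel (default: the mean across
#' the band's frequency bins) and concatenates theta, alpha, beta. On the
#' 59-channel montage this yields the 177-dimensional vector used by the
#' band-power SVM.
#'
#' @param bands a `band_features` object.
#' @param reducer function applied over each channel's bins (default
#'   [colMeans] semantics via `mean`).
#' @return Numeric vector of length `3 * n_channels`.
#' @export
combined_band_vector <- function(bands, reducer = mean) {
  stopifnot(inherits(bands, "band_features"))
  reduce <- function(m) apply(m, 2, reducer)
  c(reduce(bands$theta), reduce(bands$alpha), reduce(bands$beta))
}

#' Windows to band features
#'
#' Runs [welch_psd()], [psd_to_db_norm()] and [extract_bands()] on every
#' window.
#'
#' @param windows list of [window_sample()] objects.
#' @param cfg a [welch_config()].
#' @return List of `band_features`, labels carried from the windows.
#' @export
windows_to_band_features <- function(windows, cfg = welch_config()) {
  lapply(windows, function(w) {
    extract_bands(psd_to_db_norm(welch_psd(w, cfg)), label = w$state)
  })
}

#' Feature matrix for classical classifiers
#'
#' @param windows list of [window_sample()] objects.
#' @param mode `"bands"` for the 3-per-channel combined band vector
#'   (177 features on the 59-channel montage) or `"full"` for every
#'   frequency bin of the 0-50 Hz PSD (51 x channels features), both on
#'   the dB-normalised scale.
#' @param cfg a [welch_config()].
#' @return List with `x` (numeric matrix, windows in rows) and `y`
#'   (character labels).
#' @export
feature_matrix <- function(windows, mode = c("bands", "full"),
                           cfg = welch_config()) {
  mode <- match.arg(mode)
  rows <- lapply(windows, function(w) {
    psd <- psd_to_db_norm(welch_psd(w, cfg))
    if (mode == "bands") {
      combined_band_vector(extract_bands(psd))
    } else {
      as.vector(psd$values)
    }
  })
  list(x = do.call(rbind, rows), y = window_labels(windows))
}

#' Export band features as a tidy table
#'
#' @param bands_list list of `band_features`.
#' @return data.frame with columns `window_id`, `channel`, `band`,
#'   `bin_hz`, `value`, `label`.
#' @export
band_features_table <- function(bands_list) {
  defs <- band_definitions()
  out <- lapply(seq_along(bands_list), function(i) {
    b <- bands_list[[i]]
    per_band <- lapply(names(defs), function(bn) {
      m <- b[[bn]]
      hz <- seq(defs[[bn]][1], defs[[bn]][2])
      data.frame(window_id = i,
                 channel = rep(seq_len(ncol(m)), each = nrow(m)),
                 band = bn,
                 bin_hz = rep(hz, times = ncol(m)),
                 value = as.vector(m),
                 label = b$label,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_band)
  })
  do.call(rbind, out)
}
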