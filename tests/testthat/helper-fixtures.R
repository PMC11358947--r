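# shared test helpers: small synthetic recordings and a fixture cache so
# the expensive generated datasets are built at most once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, seed = 42) {
  key <- paste0(name, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_fixture(name, seed = seed)
  }
  .fixture_cache[[key]]
}

# minimal labelled recording: white noise on the full montage
tiny_recording <- function(duration_s = 2, fs = 100, sd = 5, seed = 1,
                           events = empty_events(),
                           channel_names = montage_64()) {
  set.seed(seed)
  n <- duration_s * fs
  eeg_recording(matrix(rnorm(length(channel_names) * n, sd = sd),
                       length(channel_names)),
                fs, channel_names, events)
}

# windows of pure synthetic content for spectral tests (59 ch x 100 at
# 100 Hz unless overridden)
tiny_window <- function(fill = function(n) rnorm(n), n_ch = 59,
                        fs = 100, state = "focused", seed = 1) {
  set.seed(seed)
  data <- t(vapply(seq_len(n_ch), function(i) fill(fs),
                   numeric(fs)))
  window_sample(data, state, source_trial = 1L, window_index = 0L,
                fs = fs)
}

# small feature clouds for classifier tests: gaussian blobs per class
gaussian_features <- function(n_per_class = 30, n_features = 177,
                              classes = c("focused", "visual"),
                              sep = 1.5, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(classes), function(i) {
    mu <- numeric(n_features)
    k <- max(1L, n_features %/% (2 * length(classes)))
    idx <- ((seq_len(k) - 1L + (i - 1L) * k) %% n_features) + 1L
    mu[idx] <- sep
    matrix(rnorm(n_per_class * n_features), n_per_class) +
      matrix(mu, n_per_class, n_features, byrow = TRUE)
  }))
  list(x = x, y = rep(classes, each = n_per_class))
}
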