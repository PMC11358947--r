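# naive reference implementations used as oracles -----------------------

naive_periodogram <- function(x, window, fs) {
  # direct evaluation of the modified periodogram: |DFT(x*w)|^2 / (M U fs)
  M <- length(x)
  w <- taper_window(window, M)
  U <- sum(w^2) / M
  xw <- x * w
  n <- 0:(M - 1)
  bins <- 0:(M %/% 2)
  p <- vapply(bins, function(k) {
    s <- sum(xw * exp(-2i * pi * k * n / M))
    Mod(s)^2 / (M * U * fs)
  }, numeric(1))
  dbl <- 2:(length(bins) - if (M %% 2 == 0) 1 else 0)
  p[dbl] <- 2 * p[dbl]
  p
}

test_that("segmentation follows the overlap-aware count formula", {
  cfg <- welch_config(M = 3)
  segs <- segment_data(1:6, cfg)
  expect_equal(dim(segs), c(3, 2))
  expect_equal(segs[, 1], 1:3)
  expect_equal(segs[, 2], 4:6)
  # overlap 0.5: enumeration oracle
  cfg2 <- welch_config(M = 50, overlap = 0.5)
  x <- seq_len(100)
  segs2 <- segment_data(x, cfg2)
  starts <- seq(1, 100 - 50 + 1, by = 25)
  expect_equal(ncol(segs2), length(starts))
  for (i in seq_along(starts)) {
    expect_equal(segs2[, i], x[starts[i]:(starts[i] + 49)])
  }
  # N = M: one segment equal to x
  segs3 <- segment_data(1:10, welch_config(M = 10))
  expect_equal(segs3, matrix(1:10, ncol = 1))
  expect_error(segment_data(1:5, welch_config(M = 10)), "exceeds")
})

test_that("window normalization factor matches direct summation", {
  expect_equal(window_norm_factor("rectangular", 7), 1)
  expect_equal(window_norm_factor("rectangular", 100), 1)
  for (win in c("hanning", "hamming")) {
    for (M in c(64, 100)) {
      w <- taper_window(win, M)
      direct <- 0
      for (n in seq_len(M)) direct <- direct + w[n]^2
      expect_equal(window_norm_factor(win, M), direct / M,
                   tolerance = 1e-12)
    }
  }
  expect_error(taper_window("kaiser", 10), "unknown window")
})

test_that("Welch estimate equals averaged naive periodograms", {
  set.seed(1)
  x <- rnorm(120)
  for (win in c("rectangular", "hanning")) {
    cfg <- welch_config(M = 40, window = win)
    p <- welch_psd(x, cfg, fs = 40)
    segs <- segment_data(x, cfg)
    ref <- rowMeans(vapply(seq_len(ncol(segs)), function(i)
      naive_periodogram(segs[, i], win, fs = 40),
      numeric(21)))
    expect_lt(max(abs(p$values[, 1] - ref)), 1e-10)
  }
  # L = 1 with rectangular window is the plain periodogram
  cfgL1 <- welch_config(M = 120, window = "rectangular")
  p1 <- welch_psd(x, cfgL1, fs = 40)
  expect_lt(max(abs(p1$values[, 1] -
                      naive_periodogram(x, "rectangular", 40))), 1e-10)
})

test_that("default config gives 51 one-hertz bins and finds a 10 Hz peak", {
  w <- tiny_window(fill = function(n) sin(2 * pi * 10 * (0:(n - 1)) / n),
                   n_ch = 3)
  p <- welch_psd(w, welch_config(window = "rectangular"))
  expect_equal(nrow(p$values), 51)
  expect_equal(p$freqs, 0:50)
  expect_equal(p$freqs[apply(p$values, 2, which.max)], rep(10, 3))
})

test_that("PSD integrates to the signal variance (Parseval, mean over seeds)", {
  set.seed(2)
  ratios <- replicate(100, {
    x <- rnorm(100)
    p <- welch_psd(x, welch_config(), fs = 100)
    sum(p$values) / mean(x^2)      # delta_f = 1 Hz
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("PSD is non-negative and quadratic in amplitude", {
  set.seed(3)
  x <- rnorm(100)
  p1 <- welch_psd(x, fs = 100)
  p2 <- welch_psd(2 * x, fs = 100)
  expect_true(all(p1$values >= 0))
  expect_equal(p2$values, 4 * p1$values, tolerance = 1e-12)
})

test_that("dB conversion and per-channel normalisation behave as defined", {
  set.seed(4)
  w <- tiny_window(n_ch = 5)
  p <- welch_psd(w)
  nz <- psd_to_db_norm(p)
  expect_true(nz$in_db && nz$normalized)
  expect_true(all(abs(colMeans(nz$values)) < 1e-10))
  expect_true(all(abs(apply(nz$values, 2, sd) - 1) < 1e-10))
  # scale invariance: power x100 shifts dB, normalisation removes it
  p100 <- p; p100$values <- 100 * p$values
  expect_equal(psd_to_db_norm(p100)$values, nz$values, tolerance = 1e-10)
  # degenerate all-equal channel is zero-filled and flagged
  pf <- p; pf$values[, 2] <- 7
  nf <- psd_to_db_norm(pf)
  expect_equal(attr(nf, "flat_channels"), 2L)
  expect_true(all(nf$values[, 2] == 0))
  expect_error(psd_to_db_norm(nz), "already in dB")
  # hand-computed 3-bin x 2-channel toy case
  toy <- structure(list(values = matrix(c(1, 10, 100, 4, 4, 4), 3),
                        freqs = 0:2, in_db = FALSE, normalized = FALSE,
                        channel_names = NULL), class = "psd_matrix")
  tz <- psd_to_db_norm(toy)
  db1 <- c(0, 10, 20)                 # 10*log10 of column 1
  expect_equal(tz$values[, 1], (db1 - 10) / sd(db1))
  expect_true(all(tz$values[, 2] == 0))
})

test_that("band extraction produces the 5/6/23 x channel blocks", {
  set.seed(5)
  w <- tiny_window(n_ch = 59)
  p <- psd_to_db_norm(welch_psd(w))
  b <- extract_bands(p, label = "focused")
  expect_equal(dim(b$theta), c(5, 59))
  expect_equal(dim(b$alpha), c(6, 59))
  expect_equal(dim(b$beta), c(23, 59))
  expect_equal(b$label, "focused")
  # a PSD nonzero only at 10 Hz puts its sole nonzero entry in alpha
  spike <- p
  spike$values[] <- 0
  spike$values[11, ] <- 1              # 10 Hz bin
  bs <- extract_bands(spike)
  expect_true(all(bs$theta == 0) && all(bs$beta == 0))
  expect_equal(sum(bs$alpha != 0), 59)
  # band sums double-count the shared edge bins 8 and 13 Hz
  direct <- colSums(p$values[5:36, ]) + p$values[9, ] + p$values[14, ]
  expect_equal(colSums(b$theta) + colSums(b$alpha) + colSums(b$beta),
               direct, tolerance = 1e-12)
  short <- p; short$values <- p$values[1:20, ]; short$freqs <- 0:19
  expect_error(extract_bands(short), "band")
})

test_that("combined band vector has length 177 and reduces correctly", {
  set.seed(6)
  w <- tiny_window(n_ch = 59)
  b <- extract_bands(psd_to_db_norm(welch_psd(w)))
  v <- combined_band_vector(b)
  expect_length(v, 177)
  expect_equal(v[1:59], colMeans(b$theta))
  expect_equal(v[60:118], colMeans(b$alpha))
  expect_equal(v[119:177], colMeans(b$beta))
  # constant PSD gives a constant vector
  const <- b
  const$theta[] <- 3; const$alpha[] <- 3; const$beta[] <- 3
  expect_true(all(combined_band_vector(const) == 3))
  # toy reduced case against hand-computed means
  toy <- structure(list(theta = matrix(c(1, 3, 2, 6), 2),
                        alpha = matrix(c(5, 5, 1, 2), 2),
                        beta = matrix(c(0, 4, 8, 8), 2),
                        label = NA_character_), class = "band_features")
  expect_equal(combined_band_vector(toy), c(2, 4, 5, 1.5, 2, 8))
})

test_that("feature export table is tidy and complete", {
  set.seed(7)
  bands <- windows_to_band_features(list(
    tiny_window(n_ch = 59, state = "visual", seed = 8)))
  tab <- band_features_table(bands)
  expect_equal(nrow(tab), (5 + 6 + 23) * 59)
  expect_setequal(unique(tab$band), c("theta", "alpha", "beta"))
  expect_true(all(tab$label == "visual"))
  expect_equal(range(tab$bin_hz), c(4, 35))
})
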