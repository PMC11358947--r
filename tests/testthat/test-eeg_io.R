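ev3 <- function() {
  data.frame(sample_index = c(50L, 600L, 2500L),
             state = c("visual", "auditory", "cognitive"),
             duration_s = c(5, 15, 10), valid = TRUE)
}

test_that("recording constructor enforces its invariants", {
  expect_error(eeg_recording(matrix(0, 3, 10), 100, c("a", "b")),
               "channel count mismatch")
  expect_error(eeg_recording(matrix(0, 2, 10), 100, c("a", "a")),
               "unique")
  expect_error(eeg_recording(matrix(0, 2, 10), -1, c("a", "b")),
               "positive")
  bad_ev <- data.frame(sample_index = 50L, state = "visual",
                       duration_s = 5, valid = TRUE)
  expect_error(eeg_recording(matrix(0, 2, 10), 100, c("a", "b"), bad_ev),
               "sample indices")
})

test_that("internal container round-trips bit-exactly", {
  rec <- tiny_recording(duration_s = 4, fs = 1000, seed = 2,
                        events = ev3())
  path <- file.path(withr::local_tempdir(), "rec.eegr")
  write_recording_internal(rec, path)
  r2 <- read_recording(path)
  expect_identical(r2$data, rec$data)
  expect_identical(r2$fs, rec$fs)
  expect_identical(r2$channel_names, rec$channel_names)
  expect_equal(r2$events, rec$events)
})

test_that("BrainVision triplet round-trips within float32 precision", {
  rec <- tiny_recording(duration_s = 4, fs = 1000, seed = 3,
                        events = ev3())
  rec$events$valid[2] <- FALSE
  stem <- file.path(withr::local_tempdir(), "bv")
  write_brainvision(rec, stem)
  r2 <- read_recording(paste0(stem, ".vhdr"))
  expect_equal(r2$data, rec$data, tolerance = 1e-6)
  expect_identical(r2$channel_names, rec$channel_names)
  expect_equal(r2$fs, rec$fs)
  expect_equal(r2$events$state, rec$events$state)
  expect_equal(r2$events$sample_index, rec$events$sample_index)
  expect_equal(r2$events$valid, c(TRUE, FALSE, TRUE))
})

test_that("EDF round-trips within 16-bit quantisation, with events", {
  rec <- tiny_recording(duration_s = 6, fs = 500, seed = 4,
                        events = ev3())
  rec$events$valid[3] <- FALSE
  path <- file.path(withr::local_tempdir(), "rec.edf")
  write_edf(rec, path)
  r2 <- read_recording(path)
  span <- max(rec$data) - min(rec$data)
  expect_lt(max(abs(r2$data - rec$data)), span / 65536 * 2)
  expect_equal(r2$events$state, rec$events$state)
  expect_equal(r2$events$valid, rec$events$valid)
  expect_equal(r2$events$duration_s, rec$events$duration_s)
  expect_lt(max(abs(r2$events$sample_index - rec$events$sample_index)), 2)
})

test_that("header inconsistencies are reported", {
  rec <- tiny_recording(duration_s = 1, fs = 100, seed = 5)
  stem <- file.path(withr::local_tempdir(), "bad")
  write_brainvision(rec, stem)
  hdr <- readLines(paste0(stem, ".vhdr"))
  hdr <- hdr[!grepl("^Ch64=", hdr)]    # drop a channel entry
  writeLines(hdr, paste0(stem, ".vhdr"))
  expect_error(read_recording(paste0(stem, ".vhdr")),
               "header inconsistency")
  expect_error(read_recording(file.path(tempdir(), "absent.vhdr")),
               "not found")
  expect_error(read_recording(paste0(stem, ".vmrk"), format = "auto"),
               "infer format")
})

test_that("channel selection yields the 59-channel analysis montage", {
  rec <- tiny_recording()
  out <- select_channels(rec)
  expect_equal(nrow(out$data), 59)
  expect_false(any(c("Fz", "Fp1", "Fp2", "TP9", "TP10") %in%
                     out$channel_names))
  # order is preserved and deterministic
  expect_identical(out$channel_names,
                   setdiff(rec$channel_names,
                           c("Fz", "Fp1", "Fp2", "TP9", "TP10")))
  expect_identical(select_channels(out, "identity"), out)
  small <- tiny_recording(channel_names = montage_64()[33:64])
  expect_error(select_channels(small), "absent")
})

test_that("mastoid re-referencing subtracts the TP9/TP10 average", {
  rec <- tiny_recording(seed = 6)
  idx <- match(c("TP9", "TP10"), rec$channel_names)
  # zero mastoids leave everything unchanged
  rec0 <- rec; rec0$data[idx, ] <- 0
  expect_equal(rereference_mastoid(rec0)$data, rec0$data)
  # constant mastoids shift every channel by -c
  recc <- rec; recc$data[idx, ] <- 3
  shifted <- rereference_mastoid(recc)
  expect_equal(shifted$data, recc$data - 3)
  # random recording vs a direct per-sample loop
  out <- rereference_mastoid(rec)
  expected <- rec$data
  for (j in seq_len(ncol(rec$data))) {
    expected[, j] <- rec$data[, j] -
      mean(rec$data[idx, j])
  }
  expect_equal(out$data, expected)
  no_mast <- tiny_recording(channel_names = montage_64()[1:16])
  expect_error(rereference_mastoid(no_mast), "mastoid")
})

test_that("band-pass filter keeps the passband and kills DC and 80 Hz", {
  fs <- 1000
  t <- seq_len(5 * fs) / fs
  mk <- function(x) eeg_recording(matrix(x, 1), fs, "Cz")
  amp_at <- function(x, f) {
    X <- abs(stats::fft(x)); 2 * X[f * 5 + 1] / length(x)
  }
  sin10 <- sin(2 * pi * 10 * t)
  out <- bandpass_filter(mk(sin10), 0.5, 50)$data[1, ]
  expect_equal(amp_at(out, 10), 1, tolerance = 0.05)
  const <- rep(4, length(t))
  outc <- bandpass_filter(mk(const), 0.5, 50)$data[1, ]
  expect_lt(abs(mean(outc)), 0.01 * 4)
  sin80 <- sin(2 * pi * 80 * t)
  out80 <- bandpass_filter(mk(sin80), 0.5, 50)$data[1, ]
  expect_lt(sd(out80), 0.05 * sd(sin80))
  expect_error(bandpass_filter(mk(sin10), 0.5, 600), "Nyquist")
})

test_that("downsampling decimates exactly and preserves the passband", {
  fs <- 1000
  t <- seq_len(5 * fs) / fs
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs, "Cz")
  out <- downsample(rec, 100)
  expect_equal(ncol(out$data), 500)
  expect_equal(out$fs, 100)
  X <- abs(stats::fft(out$data[1, ]))
  expect_equal(2 * X[51] / 500, 1, tolerance = 0.05)
  expect_identical(downsample(rec, 1000), rec)
  expect_error(downsample(rec, 2000), "exceed")
  expect_error(downsample(rec, 300), "divide")
})

test_that("epoching honours state durations and drops invalid trials", {
  ev <- ev3()
  rec <- tiny_recording(duration_s = 40, fs = 100, seed = 7,
                        events = ev)
  eps <- epoch_trials(rec)
  expect_length(eps, 3)
  expect_equal(vapply(eps, function(e) ncol(e$data), numeric(1)),
               c(5, 15, 10) * 100)
  expect_equal(vapply(eps, function(e) e$state, character(1)),
               c("visual", "auditory", "cognitive"))
  rec$events$valid[2] <- FALSE
  expect_length(epoch_trials(rec), 2)
  rec$events <- empty_events()
  expect_length(epoch_trials(rec), 0)
  # epoch past the end of the recording is skipped with a warning
  short <- tiny_recording(duration_s = 6, fs = 100, seed = 8,
                          events = data.frame(sample_index = 300L,
                                              state = "auditory",
                                              duration_s = 15,
                                              valid = TRUE))
  expect_warning(eps2 <- epoch_trials(short), "skipped")
  expect_length(eps2, 0)
  expect_equal(attr(eps2, "n_truncated"), 1L)
})

test_that("a D-second trial yields exactly D one-second windows", {
  rec <- tiny_recording(duration_s = 40, fs = 100, seed = 9,
                        events = ev3())
  eps <- epoch_trials(rec)
  per_epoch <- lapply(eps, function(e) window_epochs(list(e)))
  expect_equal(lengths(per_epoch), c(5, 15, 10))
  wins <- window_epochs(eps)
  expect_length(wins, 30)
  expect_true(all(vapply(wins, function(w) ncol(w$data), numeric(1)) ==
                    100))
  # window conservation: total duration equals window count
  expect_equal(sum(rec$events$duration_s), length(wins))
  expect_length(window_epochs(list()), 0)
})

test_that("artifact rejection drops exactly the threshold violators", {
  rec <- tiny_recording(duration_s = 40, fs = 100, seed = 10,
                        events = ev3())
  wins <- window_epochs(epoch_trials(rec))
  w <- wins[[1]]; w$data[3, 50] <- 150; wins[[1]] <- w
  w <- wins[[7]]; w$data[1, 10] <- -120; wins[[7]] <- w
  kept <- reject_artifacts(wins, 100)
  expect_length(kept, length(wins) - 2)
  expect_equal(attr(kept, "n_rejected"), 2L)
  # a 99 uV sample survives
  w99 <- wins[[2]]; w99$data[] <- 0; w99$data[5, 5] <- 99
  expect_length(reject_artifacts(list(w99), 100), 1)
})

test_that("preprocessing is label-agnostic", {
  ev <- ev3()
  rec <- tiny_recording(duration_s = 40, fs = 200, seed = 11,
                        events = ev)
  wins1 <- preprocess_recording(rec, artifact_threshold_uv = Inf)
  perm <- rec
  perm$events$state <- c("cognitive", "auditory", "visual")
  perm$events$duration_s <- state_duration_s(perm$events$state)
  wins2 <- preprocess_recording(perm, artifact_threshold_uv = Inf)
  # first trial now cognitive: data of its windows unchanged
  expect_equal(wins2[[1]]$data, wins1[[1]]$data)
  expect_equal(wins1[[1]]$state, "visual")
  expect_equal(wins2[[1]]$state, "cognitive")
})
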