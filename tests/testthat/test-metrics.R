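test_that("perfect and constant predictors hit the analytic endpoints", {
  y <- rep(attention_states(), times = c(5, 5, 5, 5))
  perfect <- compute_metrics(y, y)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$kappa, 1)
  expect_true(all(perfect$precision == 1) && all(perfect$recall == 1))
  expect_equal(perfect$f1, 1)
  # constant predictor on balanced two-class data: kappa = 0
  y2 <- rep(c("focused", "visual"), each = 10)
  const <- compute_metrics(y2, rep("focused", 20))
  expect_equal(const$kappa, 0)
  expect_equal(const$accuracy, 50)
  expect_error(compute_metrics(character(0), character(0)), "empty")
  expect_error(compute_metrics(y2, rep("oops", 20)), "outside")
})

test_that("a hand-built confusion matrix reproduces frozen oracle values", {
  cm <- matrix(c(10, 2, 1, 1,
                 3, 20, 2, 0,
                 0, 4, 15, 1,
                 2, 0, 3, 25), 4, 4, byrow = TRUE,
               dimnames = list(true = c("V", "A", "C", "F"),
                               predicted = c("V", "A", "C", "F")))
  m <- metrics_from_confusion(cm)
  # spreadsheet-style independent calculation, frozen:
  expect_equal(m$n_samples, 89)
  expect_equal(m$accuracy, 78.6516853933, tolerance = 1e-9)
  expect_equal(m$kappa, 0.7099982850, tolerance = 1e-9)
  expect_equal(unname(m$precision),
               c(0.6666666667, 0.7692307692, 0.7142857143, 0.9259259259),
               tolerance = 1e-9)
  expect_equal(unname(m$recall),
               c(0.7142857143, 0.8, 0.75, 0.8333333333),
               tolerance = 1e-9)
  expect_equal(m$f1, 0.7707172994, tolerance = 1e-9)
  # macro F1 is the mean of the per-class F1s
  expect_equal(m$f1, mean(m$f1_per_class), tolerance = 1e-12)
})

test_that("metrics are permutation-consistent", {
  set.seed(1)
  y <- sample(attention_states(), 80, replace = TRUE)
  p <- sample(attention_states(), 80, replace = TRUE)
  m1 <- compute_metrics(y, p)
  swap <- c(focused = "visual", visual = "focused",
            auditory = "cognitive", cognitive = "auditory")
  m2 <- compute_metrics(unname(swap[y]), unname(swap[p]))
  expect_equal(m2$accuracy, m1$accuracy)
  expect_equal(m2$kappa, m1$kappa, tolerance = 1e-12)
  expect_equal(sort(unname(m2$precision)), sort(unname(m1$precision)))
  # confusion row sums equal per-class true counts
  expect_equal(rowSums(m1$confusion),
               vapply(attention_states(), function(cl) sum(y == cl),
                      numeric(1)))
})

test_that("k-fold evaluation tests every sample exactly once", {
  g <- gaussian_features(n_per_class = 15, n_features = 10,
                         classes = c("focused", "visual", "auditory"),
                         sep = 2, seed = 2)
  cv <- kfold_cv(function(x, y) MASS::lda(x, grouping = factor(y)),
                 function(m, x) as.character(predict(m, x)$class),
                 g$x, g$y, k = 5, seed = 3)
  expect_length(cv$fold_reports, 5)
  sizes <- vapply(cv$fold_reports, `[[`, numeric(1), "n_samples")
  expect_lte(diff(range(sizes)), 3)
  expect_equal(sum(sizes), length(g$y))
  expect_equal(cv$mean$n_samples, length(g$y))
  expect_gte(cv$mean$accuracy, 80)
})

test_that("the printed per-subject metrics table aggregates to its printed average", {
  ref <- offline_metrics_reference()
  expect_equal(nrow(ref$subjects), 10)
  expect_equal(round(mean(as.numeric(ref$subjects$accuracy_pct)), 2),
               ref$printed_avg$accuracy_pct)
  # kappa/F1 averages were printed from unrounded per-subject values, so
  # re-averaging the rounded entries can differ in the last digit
  expect_lt(abs(mean(ref$subjects$kappa) - ref$printed_avg$kappa), 2e-3)
  expect_lt(abs(mean(ref$subjects$f1) - ref$printed_avg$f1), 2e-3)
})

test_that("tally arithmetic reproduces the printed online accuracies", {
  tab <- online_tally_reference()
  for (i in seq_len(nrow(tab))) {
    rec <- tally_overall_accuracy(
      unlist(tab[i, c("visual_T", "auditory_T", "cognitive_T",
                      "focused_T")]),
      unlist(tab[i, c("visual_C", "auditory_C", "cognitive_C",
                      "focused_C")]))
    expect_equal(round(rec, 2), tab$printed_accuracy_pct[i])
  }
  res <- recompute_online_accuracies()
  means <- attr(res, "model_means")
  expect_equal(round(unname(means["gru_eegnet"]), 2), 71.71)
  expect_equal(round(unname(means["eegnet"]), 2), 66.25)
  expect_error(tally_overall_accuracy(c(5, 5), c(6, 1)), "C_counts")
})

test_that("the online replay loop tallies per-second windows correctly", {
  design <- data.frame(lap = 1L,
                       time_s = c(2, 10, 30, 48),
                       state = c("focused", "auditory", "cognitive",
                                 "visual"),
                       duration_s = c(5, 15, 10, 5), valid = TRUE)
  attr(design, "total_duration_s") <- 60
  rec <- simulate_eeg(design, effect_profile(1), fs = 200, seed = 4)
  res <- replay_online(rec, function(w) w$state)   # oracle model
  expect_equal(attr(res$tally, "overall_accuracy"), 1)
  tl <- res$tally
  expect_equal(tl$T[tl$state == "auditory"], 15)   # a 15-s event
  expect_equal(tl$T[tl$state == "cognitive"], 10)
  expect_equal(tl$T[tl$state == "visual"], 5)
  expect_equal(tl$T[tl$state == "focused"], 5)
  expect_equal(sum(tl$T), nrow(res$predictions))
  expect_true(all(tl$C <= tl$T))
})

test_that("offline and online presets share the chain but differ in band", {
  off <- preprocess_preset("offline")
  on <- preprocess_preset("online")
  expect_equal(off$low_hz, 0.5); expect_equal(off$high_hz, 50)
  expect_equal(on$low_hz, 0.1); expect_equal(on$high_hz, 45)
  expect_equal(off$target_fs, on$target_fs)
  # identical bands => identical features (path equivalence)
  ev <- data.frame(sample_index = 400L, state = "visual",
                   duration_s = 5, valid = TRUE)
  rec <- tiny_recording(duration_s = 10, fs = 200, seed = 5,
                        events = ev)
  rec2 <- rec
  w1 <- preprocess_recording(rec, "offline", artifact_threshold_uv = Inf)
  w2 <- preprocess_recording(rec2, "offline",
                             artifact_threshold_uv = Inf)
  expect_identical(lapply(w1, `[[`, "data"), lapply(w2, `[[`, "data"))
})
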