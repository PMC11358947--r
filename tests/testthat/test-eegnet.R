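small_cfg <- function(dropout_p = 0) {
  eegnet_config(C = 6, T = 16, F1 = 4, D = 2, F2 = 8, n_classes = 2,
                dropout_p = dropout_p, temporal_kernel = 5,
                separable_kernel = 4, pool1 = 2, pool2 = 2)
}

test_that("shape trace reproduces the architecture's output column", {
  cfg <- eegnet_config(C = 59, T = 100)   # raw-mode defaults
  tr <- eegnet_shape_trace(cfg)
  expect_equal(attr(tr, "t_final"), 3)    # 100 %/% 4 %/% 8
  expect_equal(attr(tr, "flatten_length"), 96)  # F2 * (T // 32)
  expect_equal(tr$shape[tr$layer == "Flatten"], "96")
  expect_equal(tr$shape[tr$layer == "DepthwiseConv2D"], "32, 1, 100")
  # no pooling: flatten = F2 * T
  cfg1 <- eegnet_config(C = 4, T = 10, F1 = 2, D = 1, F2 = 2,
                        temporal_kernel = 3, separable_kernel = 3,
                        pool1 = 1, pool2 = 1)
  expect_equal(attr(eegnet_shape_trace(cfg1), "flatten_length"), 2 * 10)
})

test_that("band-adapted configs keep a usable sequence length", {
  th <- adapt_config_for_band("theta")
  al <- adapt_config_for_band("alpha")
  be <- adapt_config_for_band("beta")
  expect_equal(th$T, 5)
  expect_equal(attr(eegnet_shape_trace(th), "t_final"), 2)
  expect_equal(attr(eegnet_shape_trace(al), "t_final"), 3)
  expect_equal(be$T, 23)
  expect_equal(attr(eegnet_shape_trace(be), "t_final"), 5)
  expect_equal(th$temporal_kernel, 5)     # min(50, T)
  # raw-mode pooling factors on a 6-bin input collapse the axis: 6//4//8 = 0
  bad <- eegnet_config(C = 59, T = 6, pool1 = 4, pool2 = 8)
  expect_error(eegnet_shape_trace(bad), "below 1")
})

test_that("parameter count matches an independent layer-by-layer sum", {
  for (cfg in list(eegnet_config(C = 59, T = 100),
                   adapt_config_for_band("beta"), small_cfg())) {
    F2p <- cfg$F1 * cfg$D
    T2 <- (cfg$T %/% cfg$pool1) %/% cfg$pool2
    manual <- cfg$F1 * cfg$temporal_kernel +          # temporal conv
      2 * cfg$F1 +                                    # BN 1
      cfg$C * F2p +                                   # depthwise
      2 * F2p +                                       # BN 2
      F2p * cfg$separable_kernel +                    # separable depthwise
      F2p * cfg$F2 +                                  # pointwise
      2 * cfg$F2 +                                    # BN 3
      cfg$n_classes * cfg$F2 * T2 + cfg$n_classes     # dense + bias
    expect_equal(eegnet_param_count(cfg), manual)
    model <- build_eegnet(cfg, seed = 1)
    actual <- length(unlist(model$params)) -
      2 * (cfg$F1 + F2p + cfg$F2)    # running BN stats are not trainable
    expect_equal(actual, eegnet_param_count(cfg))
  }
})

test_that("softmax output sums to 1 and runtime shapes match the trace", {
  cfg <- small_cfg()
  model <- build_eegnet(cfg, seed = 2)
  X <- array(rnorm(6 * 16 * 5), c(6, 16, 5))
  fw <- eegdrive:::eegnet_forward(model, X, keep_cache = TRUE)
  expect_equal(colSums(fw$prob), rep(1, 5), tolerance = 1e-6)
  tr <- eegnet_shape_trace(cfg)
  T1 <- cfg$T %/% cfg$pool1; T2 <- T1 %/% cfg$pool2
  ca <- fw$cache
  expect_equal(dim(ca$A1a), c(cfg$C, cfg$T, 5, cfg$F1))
  expect_equal(dim(ca$E2), c(cfg$T, 5, cfg$F1 * cfg$D))
  expect_equal(dim(ca$P1), c(T1, 5, cfg$F1 * cfg$D))
  expect_equal(dim(ca$E3), c(T1, 5, cfg$F2))
  expect_equal(dim(ca$P2), c(T2, 5, cfg$F2))
  expect_equal(nrow(fw$features), attr(tr, "flatten_length"))
  expect_equal(nrow(fw$prob), cfg$n_classes)
  expect_error(eegdrive:::eegnet_forward(model,
                                         array(0, c(5, 16, 2))),
               "does not match")
})

test_that("backpropagation matches finite differences on every layer", {
  set.seed(7)
  cfg <- eegnet_config(C = 5, T = 12, F1 = 3, D = 2, F2 = 6,
                       n_classes = 3, dropout_p = 0, temporal_kernel = 5,
                       separable_kernel = 4, pool1 = 2, pool2 = 2)
  model <- build_eegnet(cfg, seed = 3)
  X <- array(rnorm(5 * 12 * 4), c(5, 12, 4))
  Y <- eegdrive:::onehot(c("a", "b", "c", "a"), c("a", "b", "c"))
  loss_of <- function(m) {
    fw <- eegdrive:::eegnet_forward(m, X, training = TRUE)
    -mean(colSums(Y * log(pmax(fw$prob, 1e-12))))
  }
  fw <- eegdrive:::eegnet_forward(model, X, training = TRUE,
                                  keep_cache = TRUE)
  grads <- eegdrive:::eegnet_backward(model, fw, Y)
  check_leaf <- function(analytic, get, set, n_probe = 6) {
    p0 <- get(model)
    set.seed(length(p0))
    probe <- sample(seq_along(p0), min(n_probe, length(p0)))
    for (i in probe) {
      eps <- 1e-6
      m1 <- set(model, replace(p0, i, p0[i] + eps))
      m2 <- set(model, replace(p0, i, p0[i] - eps))
      num <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
      expect_equal(as.vector(analytic)[i], num, tolerance = 1e-4)
    }
  }
  check_leaf(grads$W1, function(m) m$params$W1,
             function(m, v) { m$params$W1[] <- v; m })
  check_leaf(grads$Wd, function(m) m$params$Wd,
             function(m, v) { m$params$Wd[] <- v; m })
  check_leaf(grads$Wsd, function(m) m$params$Wsd,
             function(m, v) { m$params$Wsd[] <- v; m })
  check_leaf(grads$Wpw, function(m) m$params$Wpw,
             function(m, v) { m$params$Wpw[] <- v; m })
  check_leaf(grads$Wout, function(m) m$params$Wout,
             function(m, v) { m$params$Wout[] <- v; m })
  check_leaf(grads$bn2$gamma, function(m) m$params$bn2$gamma,
             function(m, v) { m$params$bn2$gamma[] <- v; m })
})

test_that("training separates linearly separable two-class inputs", {
  set.seed(8)
  cfg <- small_cfg()
  n <- 30
  mk <- function(shift) {
    lapply(seq_len(n), function(i) {
      matrix(rnorm(6 * 16, sd = 0.5), 6, 16) + shift
    })
  }
  x <- c(mk(0.8), mk(-0.8))
  y <- rep(c("focused", "visual"), each = n)
  model <- build_eegnet(cfg, seed = 4)
  model <- train_eegnet(model, x, y, epochs = 50, batch_size = 16,
                        lr = 1e-3, seed = 5)
  expect_gte(utils::tail(model$history$accuracy, 1), 0.95)
  pred <- predict(model, x, type = "class")
  expect_gte(mean(pred == y), 0.95)
  prob <- predict(model, x, type = "prob")
  expect_equal(rowSums(prob), rep(1, 2 * n), tolerance = 1e-6)
})

test_that("shuffled labels stay at chance", {
  set.seed(9)
  cfg <- small_cfg()
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    x <- lapply(1:40, function(i) matrix(rnorm(6 * 16), 6, 16))
    y <- sample(rep(c("focused", "visual"), each = 20))
    tr <- c(1:15, 21:35); te <- setdiff(1:40, tr)
    m <- build_eegnet(cfg, seed = s)
    m <- train_eegnet(m, x[tr], y[tr], epochs = 10, batch_size = 16,
                      seed = s)
    mean(predict(m, x[te], type = "class") == y[te])
  }, numeric(1))
  # each run's accuracy has sd ~ sqrt(0.25/10); the mean of 10 runs has
  # se ~ 0.05, so 3 sd = 0.15
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("training is deterministic and inference is dropout-free", {
  set.seed(10)
  cfg <- small_cfg(dropout_p = 0.25)
  x <- lapply(1:20, function(i) matrix(rnorm(6 * 16), 6, 16))
  y <- rep(c("focused", "visual"), 10)
  m1 <- train_eegnet(build_eegnet(cfg, seed = 6), x, y, epochs = 5,
                     batch_size = 8, seed = 7)
  m2 <- train_eegnet(build_eegnet(cfg, seed = 6), x, y, epochs = 5,
                     batch_size = 8, seed = 7)
  expect_identical(m1$params, m2$params)
  p1 <- predict(m1, x, type = "prob")
  p2 <- predict(m1, x, type = "prob")
  expect_identical(p1, p2)
})

test_that("EEGNet checkpoints restore an identical model", {
  cfg <- small_cfg()
  x <- lapply(1:8, function(i) matrix(rnorm(6 * 16), 6, 16))
  y <- rep(c("focused", "visual"), 4)
  m <- train_eegnet(build_eegnet(cfg, seed = 8), x, y, epochs = 2,
                    batch_size = 4, seed = 9)
  path <- file.path(withr::local_tempdir(), "net.json")
  write_eegnet_checkpoint(m, path)
  m2 <- read_eegnet_checkpoint(path)
  expect_equal(m2$params, m$params)
  expect_equal(predict(m2, x, type = "prob"), predict(m, x, type = "prob"))
})
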