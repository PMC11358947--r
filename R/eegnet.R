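#' EEGNet configuration
#'
#' The compact convolutional architecture for EEG: a temporal convolution
#' (`F1` filters of length `temporal_kernel`), a full-channel depthwise
#' spatial convolution (depth multiplier `D`), and a separable convolution
#' block (`F2 = D * F1` pointwise filters), with batch normalisation, ELU
#' activations, average pooling and dropout between. `T` is the length of
#' the second input axis: time samples in raw mode, frequency bins in PSD
#' mode (where a theta/alpha/beta block of shape bins x channels plays the
#' role of the raw window).
#'
#' @param C input channel count (electrode axis).
#' @param T input temporal length (samples or frequency bins).
#' @param F1 number of temporal filters (default 16).
#' @param D depth multiplier of the spatial convolution (default 2).
#' @param F2 number of pointwise filters (default `D * F1`).
#' @param n_classes number of output classes.
#' @param dropout_p dropout probability (default 0.25).
#' @param temporal_kernel length of the temporal convolution (default 50).
#' @param separable_kernel length of the separable depthwise kernel
#'   (default 16).
#' @param pool1,pool2 average-pooling factors (defaults 4 and 8).
#' @param bn_momentum,bn_eps batch-normalisation running-average momentum
#'   and variance floor.
#' @return Object of class `eegnet_config`.
#' @export
eegnet_config <- function(C = 59, T = 100, F1 = 16, D = 2, F2 = D * F1,
                          n_classes = 4, dropout_p = 0.25,
                          temporal_kernel = 50, separable_kernel = 16,
                          pool1 = 4, pool2 = 8,
                          bn_momentum = 0.99, bn_eps = 1e-3) {
  stopifnot(C >= 1, T >= 1, F1 >= 1, D >= 1, F2 >= 1, n_classes >= 2,
            dropout_p >= 0, dropout_p < 1, temporal_kernel >= 1,
            separable_kernel >= 1, pool1 >= 1, pool2 >= 1)
  cfg <- structure(list(
    C = as.integer(C), T = as.integer(T), F1 = as.integer(F1),
    D = as.integer(D), F2 = as.integer(F2),
    n_classes = as.integer(n_classes), dropout_p = dropout_p,
    temporal_kernel = as.integer(min(temporal_kernel, T)),
    separable_kernel = as.integer(separable_kernel),
    pool1 = as.integer(pool1), pool2 = as.integer(pool2),
    bn_momentum = bn_momentum, bn_eps = bn_eps),
    class = "eegnet_config")
  cfg
}

#' Layer-by-layer output shapes
#'
#' Symbolic evaluation of every layer's output shape: the temporal
#' convolution preserves `(F1, C, T)` (same padding), the depthwise
#' spatial convolution collapses the channel axis to `(D*F1, 1, T)`, the
#' two average pools divide the temporal axis by `pool1` then `pool2`
#' (integer division), and the flatten length is
#' `F2 * floor(floor(T / pool1) / pool2)`.
#'
#' @param cfg an [eegnet_config()].
#' @return data.frame with columns `layer` and `shape` (shape as a
#'   comma-separated string); the flatten length is attached as attribute
#'   `"flatten_length"` and the post-pooling temporal length as
#'   `"t_final"`.
#' @export
eegnet_shape_trace <- function(cfg) {
  stopifnot(inherits(cfg, "eegnet_config"))
  F2p <- cfg$F1 * cfg$D
  T1 <- cfg$T %/% cfg$pool1
  T2 <- T1 %/% cfg$pool2
  if (T1 < 1 || T2 < 1) {
    stop("temporal length collapses below 1 (T=", cfg$T, ", pools ",
         cfg$pool1, ", ", cfg$pool2, ")")
  }
  sh <- function(...) paste(c(...), collapse = ", ")
  trace <- data.frame(
    layer = c("Input", "Reshape", "Conv2D", "BatchNorm",
              "DepthwiseConv2D", "BatchNorm", "ELU", "AveragePool2D",
              "Dropout", "SeparableConv2D", "BatchNorm", "ELU",
              "AveragePool2D", "Dropout", "Flatten", "Dense"),
    shape = c(sh(cfg$C, cfg$T), sh(1, cfg$C, cfg$T),
              sh(cfg$F1, cfg$C, cfg$T), sh(cfg$F1, cfg$C, cfg$T),
              sh(F2p, 1, cfg$T), sh(F2p, 1, cfg$T), sh(F2p, 1, cfg$T),
              sh(F2p, 1, T1), sh(F2p, 1, T1),
              sh(cfg$F2, 1, T1), sh(cfg$F2, 1, T1), sh(cfg$F2, 1, T1),
              sh(cfg$F2, 1, T2), sh(cfg$F2, 1, T2),
              sh(cfg$F2 * T2), sh(cfg$n_classes)),
    stringsAsFactors = FALSE)
  attr(trace, "flatten_length") <- cfg$F2 * T2
  attr(trace, "t_final") <- T2
  trace
}

#' Band-adapted EEGNet configuration
#'
#' PSD-mode inputs are only 5/6/23 frequency bins long, so the raw-mode
#' kernel and pooling defaults (50-sample kernel, 4x and 8x pools) would
#' collapse the temporal axis below one position. The adaptation keeps
#' `C = 59`, sets `T` to the band's bin count, shortens the temporal
#' kernel to `min(50, T)`, shrinks the separable kernel to the pooled
#' length, and chooses pooling factors that leave a nontrivial sequence
#' for the downstream recurrent layer: theta `(2, 1)` giving length 2,
#' alpha `(2, 1)` giving 3, beta `(2, 2)` giving 5.
#'
#' @param band `"theta"`, `"alpha"` or `"beta"`.
#' @param C channel count (default 59).
#' @param n_classes number of classes.
#' @param dropout_p dropout probability.
#' @return An [eegnet_config()].
#' @export
adapt_config_for_band <- function(band = c("theta", "alpha", "beta"),
                                  C = 59, n_classes = 4,
                                  dropout_p = 0.25) {
  band <- match.arg(band)
  T <- c(theta = 5L, alpha = 6L, beta = 23L)[[band]]
  pools <- switch(band, theta = c(2L, 1L), alpha = c(2L, 1L),
                  beta = c(2L, 2L))
  T1 <- T %/% pools[1]
  eegnet_config(C = C, T = T, n_classes = n_classes,
                dropout_p = dropout_p,
                temporal_kernel = min(50L, T),
                separable_kernel = min(16L, T1),
                pool1 = pools[1], pool2 = pools[2])
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained EEGNet
#'
#' Initialises all weights (Glorot uniform, seeded) and batch-norm
#' statistics for the architecture described by `cfg`. Convolutions carry
#' no biases; the dense softmax head does.
#'
#' @param cfg an [eegnet_config()].
#' @param seed RNG seed for the initialisation.
#' @return Object of class `eegnet`, holding `cfg` and the parameter
#'   list.
#' @export
build_eegnet <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "eegnet_config"))
  trace <- eegnet_shape_trace(cfg)     # validates shapes
  flat <- attr(trace, "flatten_length")
  set.seed(seed)
  F2p <- cfg$F1 * cfg$D
  k1 <- cfg$temporal_kernel; k2 <- cfg$separable_kernel
  params <- list(
    W1 = glorot(cfg$F1, k1, k1, k1 * cfg$F1),
    bn1 = bn_init(cfg$F1),
    Wd = array(stats::runif(cfg$C * cfg$F1 * cfg$D,
                            -sqrt(6 / (cfg$C + cfg$D)),
                            sqrt(6 / (cfg$C + cfg$D))),
               dim = c(cfg$C, cfg$F1, cfg$D)),
    bn2 = bn_init(F2p),
    Wsd = glorot(F2p, k2, k2, k2),
    Wpw = glorot(cfg$F2, F2p, F2p, cfg$F2),
    bn3 = bn_init(cfg$F2),
    Wout = glorot(cfg$n_classes, flat, flat, cfg$n_classes),
    bout = numeric(cfg$n_classes))
  structure(list(cfg = cfg, params = params, classes = NULL),
            class = "eegnet")
}

#' @export
print.eegnet <- function(x, ...) {
  tr <- eegnet_shape_trace(x$cfg)
  cat(sprintf("<eegnet> C=%d T=%d F1=%d D=%d F2=%d classes=%d, %d parameters\n",
              x$cfg$C, x$cfg$T, x$cfg$F1, x$cfg$D, x$cfg$F2,
              x$cfg$n_classes, eegnet_param_count(x$cfg)))
  invisible(x)
}

#' Trainable parameter count
#'
#' Sum over layers: temporal conv `F1 * k1`, depthwise `C * F1 * D`,
#' separable depthwise `D*F1 * k2`, pointwise `D*F1 * F2`, dense
#' `n_classes * flatten + n_classes`, plus two parameters (scale, shift)
#' per batch-normalised feature map.
#'
#' @param cfg an [eegnet_config()].
#' @return Integer parameter count.
#' @export
eegnet_param_count <- function(cfg) {
  stopifnot(inherits(cfg, "eegnet_config"))
  F2p <- cfg$F1 * cfg$D
  flat <- attr(eegnet_shape_trace(cfg), "flatten_length")
  cfg$F1 * cfg$temporal_kernel +
    2L * cfg$F1 +
    cfg$C * cfg$F1 * cfg$D +
    2L * F2p +
    F2p * cfg$separable_kernel +
    F2p * cfg$F2 +
    2L * cfg$F2 +
    cfg$n_classes * flat + cfg$n_classes
}

## ---- layer helpers ----------------------------------------------------

bn_init <- function(n) {
  list(gamma = rep(1, n), beta = numeric(n), rm = numeric(n),
       rv = rep(1, n))
}

# x: matrix with one column per feature map. Returns output + cache and,
# in training mode, updated running stats.
bn_forward <- function(x, bn, eps, momentum, training) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu, "-")
    v <- colMeans(xc^2)
    bn$rm <- momentum * bn$rm + (1 - momentum) * mu
    bn$rv <- momentum * bn$rv + (1 - momentum) * v
  } else {
    mu <- bn$rm
    v <- bn$rv
    xc <- sweep(x, 2, mu, "-")
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, ivar, "*")
  y <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(y = y, cache = list(xhat = xhat, ivar = ivar, gamma = bn$gamma),
       bn = bn)
}

bn_backward <- function(dy, cache) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, "*")
  term <- sweep(dxhat, 2, colSums(dxhat) / n, "-") -
    sweep(cache$xhat, 2, colSums(dxhat * cache$xhat) / n, "*")
  dx <- sweep(term, 2, cache$ivar, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_backward <- function(dy, y) dy * ifelse(y > 0, 1, y + 1)

pool_time <- function(a, p) {
  # a: array (T, B, F); average-pool first axis by factor p (floor)
  d <- dim(a)
  T2 <- d[1] %/% p
  if (p == 1L) return(a)
  trunc <- a[seq_len(T2 * p), , , drop = FALSE]
  array(colMeans(matrix(as.vector(trunc), nrow = p)), c(T2, d[2], d[3]))
}

pool_time_backward <- function(dy, p, T_orig) {
  d <- dim(dy)
  if (p == 1L) return(dy)
  expanded <- matrix(rep(as.vector(dy) / p, each = p), nrow = p)
  out <- array(0, c(T_orig, d[2], d[3]))
  out[seq_len(d[1] * p), , ] <- array(as.vector(expanded),
                                      c(d[1] * p, d[2], d[3]))
  out
}

time_im2col <- function(xp, T_out, k) {
  # xp: padded array with the convolved axis FIRST (T+k-1, ...): returns
  # matrix (prod(other dims)*T_out, k) -- used for the separable conv
  Z <- matrix(0, T_out * prod(dim(xp)[-1]), k)
  for (j in seq_len(k)) {
    Z[, j] <- as.vector(xp[j:(j + T_out - 1L), , , drop = FALSE])
  }
  Z
}

## ---- forward / backward ----------------------------------------------

canonical_input <- function(x, cfg) {
  if (is.list(x)) {
    x <- vapply(x, function(m) {
      if (inherits(m, "window_sample")) m <- m$data
      as.matrix(m)
    }, matrix(0, cfg$C, cfg$T))
  }
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (dim(x)[1] != cfg$C || dim(x)[2] != cfg$T) {
    stop("input shape (", dim(x)[1], ", ", dim(x)[2],
         ") does not match config (", cfg$C, ", ", cfg$T, ")")
  }
  x
}

eegnet_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg; p <- model$params
  X <- canonical_input(X, cfg)
  C <- cfg$C; T <- cfg$T; B <- dim(X)[3]
  F1 <- cfg$F1; D <- cfg$D; F2p <- F1 * D; F2 <- cfg$F2
  k1 <- cfg$temporal_kernel; k2 <- cfg$separable_kernel
  eps <- cfg$bn_eps; mom <- cfg$bn_momentum
  cache <- list()

  # temporal convolution (same padding) over the T axis
  pl1 <- (k1 - 1L) %/% 2L
  Xp <- array(0, c(C, T + k1 - 1L, B))
  Xp[, pl1 + seq_len(T), ] <- X
  Z1 <- matrix(0, C * T * B, k1)
  for (j in seq_len(k1)) {
    Z1[, j] <- as.vector(Xp[, j:(j + T - 1L), , drop = FALSE])
  }
  A1 <- Z1 %*% t(p$W1)                       # (C*T*B, F1) feature columns

  bn1 <- bn_forward(A1, p$bn1, eps, mom, training)
  if (training) model$params$bn1 <- bn1$bn

  # depthwise spatial convolution across the full channel axis
  A1a <- array(bn1$y, c(C, T, B, F1))
  A2 <- array(0, c(T, B, F2p))
  for (f in seq_len(F1)) {
    Mf <- matrix(A1a[, , , f], nrow = C)      # C x (T*B)
    Rf <- crossprod(p$Wd[, f, , drop = TRUE], Mf)  # D x (T*B) (D>1) ...
    if (D == 1L) Rf <- matrix(Rf, nrow = 1L)
    for (d in seq_len(D)) {
      A2[, , (f - 1L) * D + d] <- Rf[d, ]
    }
  }

  bn2 <- bn_forward(matrix(A2, ncol = F2p), p$bn2, eps, mom, training)
  if (training) model$params$bn2 <- bn2$bn
  E2 <- array(elu(bn2$y), c(T, B, F2p))

  P1 <- pool_time(E2, cfg$pool1)
  T1 <- dim(P1)[1]
  if (training && cfg$dropout_p > 0) {
    mask1 <- array(stats::rbinom(length(P1), 1, 1 - cfg$dropout_p) /
                     (1 - cfg$dropout_p), dim(P1))
    P1d <- P1 * mask1
  } else {
    mask1 <- NULL; P1d <- P1
  }

  # separable convolution: per-map temporal depthwise + pointwise mix
  pl2 <- (k2 - 1L) %/% 2L
  Xp2 <- array(0, c(T1 + k2 - 1L, B, F2p))
  Xp2[pl2 + seq_len(T1), , ] <- P1d
  Z2 <- time_im2col(Xp2, T1, k2)              # (T1*B*F2p, k2)
  midx <- rep(seq_len(F2p), each = T1 * B)
  A4v <- rowSums(Z2 * p$Wsd[midx, , drop = FALSE])
  A4 <- matrix(A4v, ncol = F2p)               # (T1*B, F2p)
  A5 <- A4 %*% t(p$Wpw)                       # (T1*B, F2)

  bn3 <- bn_forward(A5, p$bn3, eps, mom, training)
  if (training) model$params$bn3 <- bn3$bn
  E3 <- array(elu(bn3$y), c(T1, B, F2))

  P2 <- pool_time(E3, cfg$pool2)
  T2 <- dim(P2)[1]
  if (training && cfg$dropout_p > 0) {
    mask2 <- array(stats::rbinom(length(P2), 1, 1 - cfg$dropout_p) /
                     (1 - cfg$dropout_p), dim(P2))
    P2d <- P2 * mask2
  } else {
    mask2 <- NULL; P2d <- P2
  }

  # flatten as a T2-step sequence of F2-vectors (F2 fastest)
  Feat <- matrix(aperm(P2d, c(3, 1, 2)), nrow = F2 * T2)   # (F2*T2, B)
  logits <- p$Wout %*% Feat + p$bout
  prob <- softmax_cols(logits)

  out <- list(prob = prob, logits = logits, features = Feat,
              feature_map = aperm(P2d, c(3, 1, 2)), model = model)
  if (keep_cache) {
    out$cache <- list(X = X, Xp = Xp, Z1 = Z1, bn1 = bn1$cache, A1a = A1a,
                      bn2 = bn2$cache, E2 = E2, P1 = P1, mask1 = mask1,
                      Xp2 = Xp2, Z2 = Z2, A4 = A4, bn3 = bn3$cache,
                      E3 = E3, P2 = P2, mask2 = mask2, Feat = Feat,
                      T1 = T1, T2 = T2, B = B)
  }
  out
}

softmax_cols <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m, "-"))
  sweep(e, 2, colSums(e), "/")
}

eegnet_backward <- function(model, fw, y_onehot) {
  cfg <- model$cfg; p <- model$params; ca <- fw$cache
  C <- cfg$C; T <- cfg$T; B <- ca$B
  F1 <- cfg$F1; D <- cfg$D; F2p <- F1 * D; F2 <- cfg$F2
  k1 <- cfg$temporal_kernel; k2 <- cfg$separable_kernel
  T1 <- ca$T1; T2 <- ca$T2

  dlogits <- (fw$prob - y_onehot) / B          # (n_classes, B)
  gWout <- tcrossprod(dlogits, ca$Feat)
  gbout <- rowSums(dlogits)
  dFeat <- crossprod(p$Wout, dlogits)          # (F2*T2, B)

  dP2d <- aperm(array(dFeat, c(F2, T2, B)), c(2, 3, 1))  # (T2, B, F2)
  if (!is.null(ca$mask2)) dP2d <- dP2d * ca$mask2
  dE3 <- pool_time_backward(dP2d, cfg$pool2, T1)
  dBn3y <- matrix(elu_backward(as.vector(dE3), as.vector(ca$E3)),
                  ncol = F2)
  b3 <- bn_backward(dBn3y, ca$bn3)
  dA5 <- b3$dx                                  # (T1*B, F2)

  gWpw <- crossprod(dA5, ca$A4)                 # (F2, F2p)
  dA4 <- dA5 %*% p$Wpw                          # (T1*B, F2p)

  # separable depthwise backward
  midx <- rep(seq_len(F2p), each = T1 * B)
  dA4v <- as.vector(dA4)
  gWsd <- matrix(0, F2p, k2)
  for (j in seq_len(k2)) {
    gWsd[, j] <- rowsum(dA4v * ca$Z2[, j], midx)[, 1]
  }
  dXp2 <- array(0, dim(ca$Xp2))
  wexp <- p$Wsd[midx, , drop = FALSE]
  for (j in seq_len(k2)) {
    dXp2[j:(j + T1 - 1L), , ] <- dXp2[j:(j + T1 - 1L), , ] +
      array(dA4v * wexp[, j], c(T1, B, F2p))
  }
  pl2 <- (k2 - 1L) %/% 2L
  dP1d <- dXp2[pl2 + seq_len(T1), , , drop = FALSE]
  if (!is.null(ca$mask1)) dP1d <- dP1d * ca$mask1
  dE2 <- pool_time_backward(dP1d, cfg$pool1, T)
  dBn2y <- matrix(elu_backward(as.vector(dE2), as.vector(ca$E2)),
                  ncol = F2p)
  b2 <- bn_backward(dBn2y, ca$bn2)
  dA2 <- array(b2$dx, c(T, B, F2p))

  # depthwise spatial backward
  gWd <- array(0, dim(p$Wd))
  dA1a <- array(0, c(C, T, B, F1))
  for (f in seq_len(F1)) {
    Mf <- matrix(ca$A1a[, , , f], nrow = C)     # C x (T*B)
    dRf <- matrix(0, D, T * B)
    for (d in seq_len(D)) {
      dRf[d, ] <- as.vector(dA2[, , (f - 1L) * D + d])
    }
    gWd[, f, ] <- tcrossprod(Mf, dRf)           # C x D
    dMf <- matrix(p$Wd[, f, , drop = TRUE], nrow = C) %*% dRf
    dA1a[, , , f] <- array(dMf, c(C, T, B))
  }

  b1 <- bn_backward(matrix(dA1a, ncol = F1), ca$bn1)
  dA1 <- b1$dx                                  # (C*T*B, F1)
  gW1 <- crossprod(dA1, ca$Z1)                  # (F1, k1)

  list(W1 = gW1,
       bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
       Wd = gWd,
       bn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
       Wsd = gWsd, Wpw = gWpw,
       bn3 = list(gamma = b3$dgamma, beta = b3$dbeta),
       Wout = gWout, bout = gbout)
}

## ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) list(m = x * 0, v = x * 0),
         how = "replace", classes = c("numeric", "matrix", "array"))
}

# Applies one Adam update to a flat-named list of parameter leaves.
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, s = s)
  }
  walk <- function(pn, gn, sn) {
    for (nm in names(gn)) {
      if (is.null(gn[[nm]])) next
      if (is.list(gn[[nm]]) && !is.null(names(gn[[nm]]))) {
        res <- walk(pn[[nm]], gn[[nm]], sn[[nm]])
        pn[[nm]] <- res$p; sn[[nm]] <- res$s
      } else {
        r <- upd(pn[[nm]], gn[[nm]], sn[[nm]])
        pn[[nm]] <- r$p; sn[[nm]] <- r$s
      }
    }
    list(p = pn, s = sn)
  }
  walk(params, grads, state)
}

onehot <- function(y, classes) {
  m <- matrix(0, length(classes), length(y))
  m[cbind(match(y, classes), seq_along(y))] <- 1
  m
}

#' Train an EEGNet
#'
#' Minimises the cross-entropy loss with Adam (learning rate 0.001 by
#' default), mini-batches of 64, recording per-epoch training (and
#' optionally validation) loss and accuracy. Deterministic for a given
#' seed.
#'
#' @param model an [build_eegnet()] model.
#' @param x inputs: list of `C x T` matrices / window samples, or an
#'   array `(C, T, B)`.
#' @param y character labels aligned with `x`.
#' @param epochs training epochs (default 300).
#' @param batch_size mini-batch size (default 64).
#' @param lr Adam learning rate.
#' @param seed RNG seed controlling shuffling and dropout.
#' @param validation optional list `list(x = ..., y = ...)` evaluated
#'   after each epoch.
#' @param classes class labels in canonical order; defaults to the states
#'   present in `y`.
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return The trained model with a `history` data.frame attached
#'   (`epoch`, `loss`, `accuracy`, `val_loss`, `val_accuracy`).
#' @export
train_eegnet <- function(model, x, y, epochs = 300, batch_size = 64,
                         lr = 0.001, seed = 1, validation = NULL,
                         classes = NULL, verbose = 0) {
  stopifnot(inherits(model, "eegnet"))
  X <- canonical_input(x, model$cfg)
  B_all <- dim(X)[3]
  if (length(y) != B_all) stop("length(y) != number of input samples")
  if (is.null(classes)) {
    classes <- attention_states()[attention_states() %in% unique(y)]
    if (!length(classes)) classes <- sort(unique(y))
  }
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  if (model$cfg$n_classes != length(classes)) {
    stop("model has ", model$cfg$n_classes, " outputs but ",
         length(classes), " classes present")
  }
  model$classes <- classes
  Y <- onehot(y, classes)
  state <- adam_init(model$params)
  set.seed(seed)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0), val_loss = numeric(0),
                     val_accuracy = numeric(0))
  t_step <- 0L
  for (ep in seq_len(epochs)) {
    idx <- sample.int(B_all)
    batches <- split(idx, ceiling(seq_along(idx) / batch_size))
    ep_loss <- 0; ep_correct <- 0
    for (b in batches) {
      fw <- eegnet_forward(model, X[, , b, drop = FALSE], training = TRUE,
                           keep_cache = TRUE)
      model <- fw$model                       # running BN stats
      yb <- Y[, b, drop = FALSE]
      loss <- -mean(colSums(yb * log(pmax(fw$prob, 1e-12))))
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", ep, "; training diverged")
      }
      ep_loss <- ep_loss + loss * length(b)
      ep_correct <- ep_correct +
        sum(max.col(t(fw$prob)) == max.col(t(yb)))
      grads <- eegnet_backward(model, fw, yb)
      t_step <- t_step + 1L
      res <- adam_step(model$params, grads, state, lr, t_step)
      model$params <- res$p
      state <- res$s
    }
    row <- data.frame(epoch = ep, loss = ep_loss / B_all,
                      accuracy = ep_correct / B_all,
                      val_loss = NA_real_, val_accuracy = NA_real_)
    if (!is.null(validation)) {
      vx <- canonical_input(validation$x, model$cfg)
      vfw <- eegnet_forward(model, vx, training = FALSE)
      vY <- onehot(validation$y, classes)
      row$val_loss <- -mean(colSums(vY * log(pmax(vfw$prob, 1e-12))))
      row$val_accuracy <- mean(max.col(t(vfw$prob)) == max.col(t(vY)))
    }
    hist <- rbind(hist, row)
    if (verbose > 0 && ep %% verbose == 0) {
      message(sprintf("epoch %d/%d loss %.4f acc %.3f", ep, epochs,
                      row$loss, row$accuracy))
    }
  }
  model$history <- hist
  model
}

#' Predict with an EEGNet
#'
#' Inference-mode forward pass (dropout disabled, batch norm uses running
#' statistics).
#'
#' @param object a trained `eegnet`.
#' @param x inputs as in [train_eegnet()].
#' @param type `"prob"` for a samples x classes probability matrix,
#'   `"class"` for labels (ties broken by canonical class order).
#' @param ... unused.
#' @return Matrix of probabilities or character vector of labels.
#' @export
predict.eegnet <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  fw <- eegnet_forward(object, x, training = FALSE)
  prob <- t(fw$prob)
  classes <- object$classes
  if (is.null(classes)) classes <- seq_len(object$cfg$n_classes)
  colnames(prob) <- classes
  if (type == "prob") return(prob)
  classes[apply(prob, 1, which.max)]
}

#' Pre-flatten feature sequences
#'
#' Runs the convolutional trunk in inference mode and returns, for each
#' sample, the pre-flatten feature map as a `F2 x T_final` matrix — the
#' sequence of `F2`-dimensional feature vectors that the recurrent layer
#' of the composite model consumes.
#'
#' @param model a trained `eegnet`.
#' @param x inputs as in [train_eegnet()].
#' @return List of `F2 x T_final` matrices, one per sample.
#' @export
eegnet_features <- function(model, x) {
  fw <- eegnet_forward(model, x, training = FALSE)
  fm <- fw$feature_map                         # (F2, T2, B)
  lapply(seq_len(dim(fm)[3]), function(b) fm[, , b, drop = TRUE])
}

#' Serialise an EEGNet checkpoint (JSON, full config embedded)
#' @param model an `eegnet`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_eegnet_checkpoint <- function(model, path) {
  obj <- list(kind = "eegnet", cfg = unclass(model$cfg),
              classes = model$classes,
              params = rapply(model$params, identity, how = "list"),
              dims = rapply(model$params, function(x) dim(x) %||% length(x),
                            how = "list"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an EEGNet checkpoint
#' @param path checkpoint path.
#' @return An `eegnet` model.
#' @export
read_eegnet_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$kind, "eegnet")) stop("not an EEGNet checkpoint")
  cfg <- do.call(eegnet_config, obj$cfg[c("C", "T", "F1", "D", "F2",
                                          "n_classes", "dropout_p",
                                          "temporal_kernel",
                                          "separable_kernel", "pool1",
                                          "pool2", "bn_momentum",
                                          "bn_eps")])
  model <- build_eegnet(cfg, seed = 1)
  restore <- function(tmpl, flat, dims) {
    for (nm in names(tmpl)) {
      if (is.list(tmpl[[nm]]) && !is.null(names(tmpl[[nm]]))) {
        tmpl[[nm]] <- restore(tmpl[[nm]], flat[[nm]], dims[[nm]])
      } else {
        v <- as.numeric(unlist(flat[[nm]]))
        d <- unlist(dims[[nm]])
        tmpl[[nm]] <- if (length(d) > 1L) array(v, d) else v
      }
    }
    tmpl
  }
  model$params <- restore(model$params, obj$params, obj$dims)
  model$classes <- obj$classes
  model
}
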