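#' GRU-EEGNet configuration
#'
#' The composite decoder: three band-specific EEGNet trunks (theta,
#' alpha, beta), each feeding its pre-flatten feature sequence to a GRU,
#' with late fusion of the branch outputs. Fusion is either the average
#' of the three branch softmax outputs (default) or a joint dense layer
#' on the concatenated final GRU states.
#'
#' @param n_classes number of output classes.
#' @param gru_hidden GRU hidden size (default 32, matching `F2`).
#' @param fusion `"softmax_average"` or `"concat_dense"`.
#' @param dropout_stage2 dropout applied to the GRU state during stage-2
#'   training (default 0.5).
#' @param band_cfgs list of three [eegnet_config()]s named theta, alpha,
#'   beta; defaults to [adapt_config_for_band()] for each.
#' @return Object of class `gru_eegnet_config`.
#' @export
gru_eegnet_config <- function(n_classes = 4, gru_hidden = 32,
                              fusion = c("softmax_average", "concat_dense"),
                              dropout_stage2 = 0.5,
                              band_cfgs = NULL) {
  fusion <- match.arg(fusion)
  if (is.null(band_cfgs)) {
    band_cfgs <- lapply(stats::setNames(nm = c("theta", "alpha", "beta")),
                        adapt_config_for_band, n_classes = n_classes)
  }
  stopifnot(setequal(names(band_cfgs), c("theta", "alpha", "beta")))
  structure(list(n_classes = as.integer(n_classes),
                 gru_hidden = as.integer(gru_hidden), fusion = fusion,
                 dropout_stage2 = dropout_stage2,
                 band_cfgs = band_cfgs[c("theta", "alpha", "beta")]),
            class = "gru_eegnet_config")
}

#' Two-stage training schedule
#'
#' Stage 1 trains each band EEGNet (batch 64, 300 epochs, Adam lr 0.001,
#' dropout 0.25); stage 2 freezes the EEGNet weights and trains the GRUs,
#' branch heads and fusion (batch 16, 100 epochs, lr 0.001, dropout 0.5).
#'
#' @param stage1_epochs,stage1_batch,stage1_lr stage-1 settings.
#' @param stage2_epochs,stage2_batch,stage2_lr stage-2 settings.
#' @param folds reference fold count for cross-validated evaluation.
#' @param seed RNG seed.
#' @return List of class `train_stage_config`.
#' @export
train_stage_config <- function(stage1_epochs = 300, stage1_batch = 64,
                               stage1_lr = 0.001,
                               stage2_epochs = 100, stage2_batch = 16,
                               stage2_lr = 0.001,
                               folds = 5, seed = 1) {
  stopifnot(stage1_epochs >= 1, stage2_epochs >= 1, stage1_batch >= 1,
            stage2_batch >= 1, stage1_lr > 0, stage2_lr > 0)
  structure(list(stage1_epochs = stage1_epochs,
                 stage1_batch = stage1_batch, stage1_lr = stage1_lr,
                 stage2_epochs = stage2_epochs,
                 stage2_batch = stage2_batch, stage2_lr = stage2_lr,
                 folds = folds, seed = seed),
            class = "train_stage_config")
}

#' Build an untrained GRU-EEGNet
#'
#' @param cfg a [gru_eegnet_config()].
#' @param seed RNG seed for all weight initialisation.
#' @return Object of class `gru_eegnet` with per-band EEGNets, GRUs,
#'   branch heads and (for concat fusion) the joint dense layer.
#' @export
build_gru_eegnet <- function(cfg = gru_eegnet_config(), seed = 1) {
  stopifnot(inherits(cfg, "gru_eegnet_config"))
  bands <- c("theta", "alpha", "beta")
  eegnets <- list(); grus <- list(); heads <- list()
  for (i in seq_along(bands)) {
    b <- bands[i]
    bc <- cfg$band_cfgs[[b]]
    eegnets[[b]] <- build_eegnet(bc, seed = seed + i)
    grus[[b]] <- gru_params(input_size = bc$F2,
                            hidden_size = cfg$gru_hidden,
                            seed = seed + 10 + i)
    set.seed(seed + 20 + i)
    heads[[b]] <- list(W = glorot(cfg$n_classes, cfg$gru_hidden,
                                  cfg$gru_hidden, cfg$n_classes),
                       b = numeric(cfg$n_classes))
  }
  fusion_dense <- NULL
  if (cfg$fusion == "concat_dense") {
    set.seed(seed + 30)
    fusion_dense <- list(W = glorot(cfg$n_classes, 3 * cfg$gru_hidden,
                                    3 * cfg$gru_hidden, cfg$n_classes),
                         b = numeric(cfg$n_classes))
  }
  structure(list(cfg = cfg, eegnets = eegnets, grus = grus,
                 heads = heads, fusion_dense = fusion_dense,
                 classes = NULL, trained = FALSE),
            class = "gru_eegnet")
}

#' @export
print.gru_eegnet <- function(x, ...) {
  lens <- vapply(x$cfg$band_cfgs, function(bc)
    attr(eegnet_shape_trace(bc), "t_final"), integer(1))
  cat(sprintf(paste0("<gru_eegnet> %d classes, fusion=%s, GRU hidden %d, ",
                     "branch sequence lengths theta=%d alpha=%d beta=%d%s\n"),
              x$cfg$n_classes, x$cfg$fusion, x$cfg$gru_hidden,
              lens[1], lens[2], lens[3],
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

# bands_list (list of band_features) -> per-band input arrays (C, T, B)
bands_to_arrays <- function(bands_list) {
  stopifnot(length(bands_list) >= 1,
            inherits(bands_list[[1]], "band_features"))
  out <- list()
  for (b in c("theta", "alpha", "beta")) {
    mats <- lapply(bands_list, function(bf) t(bf[[b]]))  # C x bins
    out[[b]] <- array(unlist(mats),
                      c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
  }
  out
}

## ---- batched GRU used by stage-2 training -----------------------------

# X: array (input_size, T, B). Returns caches with H x B matrices per step.
gru_batch_forward <- function(params, X, training = FALSE, dropout_p = 0,
                              mask = NULL) {
  H <- params$hidden_size
  Tn <- dim(X)[2]; B <- dim(X)[3]
  h <- matrix(0, H, B)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x_t <- matrix(X[, t, ], ncol = B)
    hx <- rbind(h, x_t)
    z <- sigmoid(params$W_z %*% hx)
    r <- sigmoid(params$W_r %*% hx)
    rhx <- rbind(r * h, x_t)
    h_tilde <- tanh(params$W %*% rhx)
    h_new <- (1 - z) * h + z * h_tilde
    steps[[t]] <- list(h_prev = h, x = x_t, z = z, r = r,
                       h_tilde = h_tilde, h = h_new)
    h <- h_new
  }
  list(steps = steps, h_final = h)
}

gru_batch_backward <- function(params, fw, dh_final) {
  H <- params$hidden_size
  gW_z <- params$W_z * 0; gW_r <- params$W_r * 0; gW <- params$W * 0
  Wh <- params$W[, seq_len(H), drop = FALSE]
  Wzh <- params$W_z[, seq_len(H), drop = FALSE]
  Wrh <- params$W_r[, seq_len(H), drop = FALSE]
  dh <- dh_final
  for (t in rev(seq_along(fw$steps))) {
    st <- fw$steps[[t]]
    dz <- dh * (st$h_tilde - st$h_prev)
    dh_tilde <- dh * st$z
    dh_prev <- dh * (1 - st$z)
    da_c <- dh_tilde * (1 - st$h_tilde^2)
    gW <- gW + tcrossprod(da_c, rbind(st$r * st$h_prev, st$x))
    d_rh <- crossprod(Wh, da_c)
    dr <- d_rh * st$h_prev
    dh_prev <- dh_prev + d_rh * st$r
    da_z <- dz * st$z * (1 - st$z)
    da_r <- dr * st$r * (1 - st$r)
    hx <- rbind(st$h_prev, st$x)
    gW_z <- gW_z + tcrossprod(da_z, hx)
    gW_r <- gW_r + tcrossprod(da_r, hx)
    dh_prev <- dh_prev + crossprod(Wzh, da_z) + crossprod(Wrh, da_r)
    dh <- dh_prev
  }
  list(W_z = gW_z, W_r = gW_r, W = gW)
}

## ---- two-stage training ----------------------------------------------

eegnet_weight_fingerprint <- function(model) {
  # trainable convolutional-trunk weights only
  p <- model$params
  digest_vec <- c(as.vector(p$W1), p$bn1$gamma, p$bn1$beta,
                  as.vector(p$Wd), p$bn2$gamma, p$bn2$beta,
                  as.vector(p$Wsd), as.vector(p$Wpw),
                  p$bn3$gamma, p$bn3$beta)
  digest_vec
}

#' Two-stage training of a GRU-EEGNet
#'
#' Stage 1 trains the three band EEGNets independently, each with its own
#' (temporary) softmax head. Stage 2 freezes every EEGNet weight — the
#' pre-flatten feature sequences are computed once with the frozen trunks
#' and verified bit-identical before and after — and trains the GRUs,
#' branch heads and fusion on those sequences.
#'
#' @param model a [build_gru_eegnet()] model.
#' @param bands_list list of `band_features`, one per window.
#' @param labels character labels aligned with `bands_list`.
#' @param stage_cfg a [train_stage_config()].
#' @param classes class labels in canonical order (defaults to those
#'   present).
#' @param validation optional list `list(bands = ..., labels = ...)` used
#'   for per-epoch stage-2 validation metrics.
#' @param verbose print progress (0 = silent).
#' @return The trained `gru_eegnet` with `history` (stage-2 epochs)
#'   attached.
#' @export
train_two_stage <- function(model, bands_list, labels,
                            stage_cfg = train_stage_config(),
                            classes = NULL, validation = NULL,
                            verbose = 0) {
  stopifnot(inherits(model, "gru_eegnet"),
            inherits(stage_cfg, "train_stage_config"))
  if (length(bands_list) != length(labels)) {
    stop("bands_list and labels must be aligned")
  }
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  if (is.null(classes)) {
    classes <- attention_states()[attention_states() %in% unique(labels)]
  }
  if (length(classes) != model$cfg$n_classes) {
    stop("model configured for ", model$cfg$n_classes, " classes but ",
         length(classes), " present")
  }
  model$classes <- classes
  arrays <- bands_to_arrays(bands_list)

  # ---- stage 1: band EEGNets with temporary heads
  for (b in c("theta", "alpha", "beta")) {
    if (verbose) message("stage 1: training ", b, " EEGNet")
    model$eegnets[[b]] <- train_eegnet(
      model$eegnets[[b]], arrays[[b]], labels,
      epochs = stage_cfg$stage1_epochs,
      batch_size = stage_cfg$stage1_batch,
      lr = stage_cfg$stage1_lr,
      seed = stage_cfg$seed + match(b, c("theta", "alpha", "beta")),
      classes = classes)
  }
  fingerprints <- lapply(model$eegnets, eegnet_weight_fingerprint)

  # ---- stage 2: frozen trunks, train GRU + heads (+ fusion)
  feats <- lapply(c("theta", "alpha", "beta"), function(b) {
    fm <- eegnet_features(model$eegnets[[b]], arrays[[b]])
    array(unlist(fm), c(nrow(fm[[1]]), ncol(fm[[1]]), length(fm)))
  })
  names(feats) <- c("theta", "alpha", "beta")

  model <- train_stage2(model, feats, labels, stage_cfg, classes,
                        validation = validation, verbose = verbose)

  after <- lapply(model$eegnets, eegnet_weight_fingerprint)
  if (!identical(fingerprints, after)) {
    stop("internal error: EEGNet weights changed during stage 2")
  }
  model$trained <- TRUE
  model
}

train_stage2 <- function(model, feats, labels, stage_cfg, classes,
                         validation = NULL, verbose = 0) {
  cfg <- model$cfg
  bands <- c("theta", "alpha", "beta")
  B_all <- length(labels)
  Y <- onehot(labels, classes)
  p_drop <- cfg$dropout_stage2

  params <- list(grus = model$grus, heads = model$heads,
                 fusion = model$fusion_dense)
  state <- adam_init(list(
    grus = lapply(model$grus, function(g) g[c("W_z", "W_r", "W")]),
    heads = model$heads,
    fusion = model$fusion_dense))

  val_feats <- NULL
  if (!is.null(validation)) {
    varr <- bands_to_arrays(validation$bands)
    val_feats <- lapply(bands, function(b) {
      fm <- eegnet_features(model$eegnets[[b]], varr[[b]])
      array(unlist(fm), c(nrow(fm[[1]]), ncol(fm[[1]]), length(fm)))
    })
    names(val_feats) <- bands
  }

  set.seed(stage_cfg$seed + 100)
  t_step <- 0L
  hist <- NULL
  for (ep in seq_len(stage_cfg$stage2_epochs)) {
    idx <- sample.int(B_all)
    batches <- split(idx, ceiling(seq_along(idx) / stage_cfg$stage2_batch))
    ep_loss <- 0; ep_correct <- 0
    for (bt in batches) {
      nb <- length(bt)
      yb <- Y[, bt, drop = FALSE]
      fwd <- list(); hdrop <- list(); masks <- list(); probs <- list()
      for (b in bands) {
        fwd[[b]] <- gru_batch_forward(params$grus[[b]],
                                      feats[[b]][, , bt, drop = FALSE])
        h <- fwd[[b]]$h_final
        if (p_drop > 0) {
          masks[[b]] <- matrix(stats::rbinom(length(h), 1, 1 - p_drop) /
                                 (1 - p_drop), nrow(h), ncol(h))
          h <- h * masks[[b]]
        }
        hdrop[[b]] <- h
      }
      grads <- list(grus = list(), heads = list(), fusion = NULL)
      if (cfg$fusion == "concat_dense") {
        hcat <- do.call(rbind, hdrop)
        logits <- params$fusion$W %*% hcat + params$fusion$b
        prob <- softmax_cols(logits)
        loss <- -mean(colSums(yb * log(pmax(prob, 1e-12))))
        dlogits <- (prob - yb) / nb
        grads$fusion <- list(W = tcrossprod(dlogits, hcat),
                             b = rowSums(dlogits))
        dhcat <- crossprod(params$fusion$W, dlogits)
        H <- cfg$gru_hidden
        for (i in seq_along(bands)) {
          b <- bands[i]
          dh <- dhcat[((i - 1) * H + 1):(i * H), , drop = FALSE]
          if (p_drop > 0) dh <- dh * masks[[b]]
          grads$grus[[b]] <- gru_batch_backward(params$grus[[b]],
                                                fwd[[b]], dh)
        }
        fused <- prob
      } else {
        branch_probs <- list()
        for (b in bands) {
          logits <- params$heads[[b]]$W %*% hdrop[[b]] +
            params$heads[[b]]$b
          prob <- softmax_cols(logits)
          branch_probs[[b]] <- prob
          dlogits <- (prob - yb) / nb
          grads$heads[[b]] <- list(W = tcrossprod(dlogits, hdrop[[b]]),
                                   b = rowSums(dlogits))
          dh <- crossprod(params$heads[[b]]$W, dlogits)
          if (p_drop > 0) dh <- dh * masks[[b]]
          grads$grus[[b]] <- gru_batch_backward(params$grus[[b]],
                                                fwd[[b]], dh)
        }
        fused <- Reduce(`+`, branch_probs) / 3
        loss <- -mean(colSums(yb * log(pmax(fused, 1e-12)))) # monitoring
        # optimised objective: mean of per-branch cross-entropies
      }
      if (!is.finite(loss)) stop("non-finite stage-2 loss at epoch ", ep)
      ep_loss <- ep_loss + loss * nb
      ep_correct <- ep_correct + sum(max.col(t(fused)) == max.col(t(yb)))

      t_step <- t_step + 1L
      upd_params <- list(
        grus = lapply(params$grus, function(g) g[c("W_z", "W_r", "W")]),
        heads = params$heads, fusion = params$fusion)
      upd_grads <- list(grus = grads$grus, heads = grads$heads,
                        fusion = grads$fusion)
      if (cfg$fusion == "concat_dense") upd_grads$heads <- NULL
      res <- adam_step(upd_params, upd_grads, state,
                       stage_cfg$stage2_lr, t_step)
      state <- res$s
      for (b in bands) {
        params$grus[[b]][c("W_z", "W_r", "W")] <-
          res$p$grus[[b]][c("W_z", "W_r", "W")]
      }
      if (cfg$fusion == "concat_dense") {
        params$fusion <- res$p$fusion
      } else {
        params$heads <- res$p$heads
      }
    }
    row <- data.frame(epoch = ep, loss = ep_loss / B_all,
                      accuracy = ep_correct / B_all,
                      val_accuracy = NA_real_)
    if (!is.null(val_feats)) {
      tmp_model <- model
      tmp_model$grus <- params$grus
      tmp_model$heads <- params$heads
      tmp_model$fusion_dense <- params$fusion
      vp <- predict_from_features(tmp_model, val_feats)
      row$val_accuracy <- mean(classes[max.col(vp, ties.method = "first")] ==
                                 validation$labels)
    }
    hist <- rbind(hist, row)
    if (verbose > 0 && ep %% verbose == 0) {
      message(sprintf("stage 2 epoch %d/%d loss %.4f acc %.3f", ep,
                      stage_cfg$stage2_epochs, row$loss, row$accuracy))
    }
  }
  model$grus <- params$grus
  model$heads <- params$heads
  model$fusion_dense <- params$fusion
  model$history <- hist
  model
}

# feats: named list of arrays (F2, T', B); returns B x n_classes matrix
predict_from_features <- function(model, feats, drop_branch = NULL) {
  cfg <- model$cfg
  bands <- setdiff(c("theta", "alpha", "beta"), drop_branch)
  hs <- list()
  for (b in bands) {
    fwd <- gru_batch_forward(model$grus[[b]], feats[[b]])
    hs[[b]] <- fwd$h_final
  }
  if (cfg$fusion == "concat_dense") {
    if (!is.null(drop_branch)) {
      # zero out the dropped branch's block
      H <- cfg$gru_hidden
      full <- lapply(c("theta", "alpha", "beta"), function(b) {
        if (b %in% bands) hs[[b]] else matrix(0, H, ncol(hs[[bands[1]]]))
      })
      hcat <- do.call(rbind, full)
    } else {
      hcat <- do.call(rbind, hs)
    }
    prob <- softmax_cols(model$fusion_dense$W %*% hcat +
                           model$fusion_dense$b)
  } else {
    probs <- lapply(bands, function(b) {
      softmax_cols(model$heads[[b]]$W %*% hs[[b]] + model$heads[[b]]$b)
    })
    prob <- Reduce(`+`, probs) / length(probs)
  }
  t(prob)
}

#' Predict attention states with a trained GRU-EEGNet
#'
#' Deterministic inference: class probabilities over the configured
#' label set and the argmax label (ties broken by canonical class
#' order).
#'
#' @param model a trained `gru_eegnet`.
#' @param bands a `band_features` object or a list of them.
#' @param drop_branch optional band name to exclude at prediction time
#'   (diagnostic; shows each branch contributes).
#' @return List with `prob` (samples x classes matrix) and `label`
#'   (character vector).
#' @export
predict_state <- function(model, bands, drop_branch = NULL) {
  stopifnot(inherits(model, "gru_eegnet"))
  if (!model$trained) stop("model is untrained; run train_two_stage() first")
  if (inherits(bands, "band_features")) bands <- list(bands)
  arrays <- bands_to_arrays(bands)
  feats <- lapply(c("theta", "alpha", "beta"), function(b) {
    fm <- eegnet_features(model$eegnets[[b]], arrays[[b]])
    array(unlist(fm), c(nrow(fm[[1]]), ncol(fm[[1]]), length(fm)))
  })
  names(feats) <- c("theta", "alpha", "beta")
  prob <- predict_from_features(model, feats, drop_branch = drop_branch)
  colnames(prob) <- model$classes
  list(prob = prob,
       label = model$classes[max.col(prob, ties.method = "first")])
}

#' @export
predict.gru_eegnet <- function(object, bands, ...) {
  predict_state(object, bands)$label
}
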