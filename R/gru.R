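#' Initialise GRU parameters
#'
#' Three weight matrices — update gate `W_z`, reset gate `W_r` and
#' candidate `W` — each acting on the spliced vector `[h_{t-1}, x_t]`
#' (state first, then input, following the gate equations verbatim).
#' There are no bias terms by default; a flag adds them for parity with
#' common GRU variants. Weights are drawn uniform(-k, k) with
#' `k = 1/sqrt(hidden_size)`.
#'
#' @param input_size length of each input vector `x_t`.
#' @param hidden_size length of the hidden state `h_t`.
#' @param bias include bias vectors (default FALSE).
#' @param seed optional seed for reproducible initialisation.
#' @return Object of class `gru_params`.
#' @export
gru_params <- function(input_size, hidden_size, bias = FALSE, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  k <- 1 / sqrt(hidden_size)
  d <- hidden_size + input_size
  rand <- function() matrix(stats::runif(hidden_size * d, -k, k),
                            nrow = hidden_size, ncol = d)
  structure(list(
    W_z = rand(), W_r = rand(), W = rand(),
    b_z = if (bias) numeric(hidden_size),
    b_r = if (bias) numeric(hidden_size),
    b = if (bias) numeric(hidden_size),
    input_size = as.integer(input_size),
    hidden_size = as.integer(hidden_size),
    bias = isTRUE(bias)),
    class = "gru_params")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One GRU step
#'
#' The gate recurrence: `z_t = sigma(W_z [h_{t-1}, x_t])`,
#' `r_t = sigma(W_r [h_{t-1}, x_t])`,
#' `htilde_t = tanh(W [r_t * h_{t-1}, x_t])`,
#' `h_t = (1 - z_t) * h_{t-1} + z_t * htilde_t` — so a gate value near 0
#' preserves the previous state and a value near 1 overwrites it with the
#' candidate.
#'
#' @param params a [gru_params()].
#' @param h_prev hidden state vector (length `hidden_size`).
#' @param x_t input vector (length `input_size`).
#' @return Object of class `gru_state`: list with `h` and the retained
#'   intermediates `z`, `r`, `h_tilde`.
#' @export
gru_step <- function(params, h_prev, x_t) {
  stopifnot(inherits(params, "gru_params"))
  if (length(h_prev) != params$hidden_size) {
    stop("h_prev has length ", length(h_prev), ", expected ",
         params$hidden_size)
  }
  if (length(x_t) != params$input_size) {
    stop("x_t has length ", length(x_t), ", expected ", params$input_size)
  }
  hx <- c(h_prev, x_t)
  z <- sigmoid(drop(params$W_z %*% hx) + if (params$bias) params$b_z else 0)
  r <- sigmoid(drop(params$W_r %*% hx) + if (params$bias) params$b_r else 0)
  rhx <- c(r * h_prev, x_t)
  h_tilde <- tanh(drop(params$W %*% rhx) + if (params$bias) params$b else 0)
  h <- (1 - z) * h_prev + z * h_tilde
  structure(list(h = h, z = z, r = r, h_tilde = h_tilde),
            class = "gru_state")
}

#' Run a GRU over a sequence
#'
#' Left-to-right recurrence from `h0` (zeros by default); the final
#' hidden state summarises the sequence for downstream layers.
#'
#' @param params a [gru_params()].
#' @param xs input sequence: a list of vectors, or a matrix with one
#'   time step per column.
#' @param h0 initial state (default zeros).
#' @return List with `states` (list of `gru_state`, one per step) and
#'   `h_final`. An empty sequence returns `h0` and no states.
#' @export
gru_sequence <- function(params, xs, h0 = NULL) {
  stopifnot(inherits(params, "gru_params"))
  if (is.matrix(xs)) xs <- lapply(seq_len(ncol(xs)), function(j) xs[, j])
  if (is.null(h0)) h0 <- numeric(params$hidden_size)
  states <- vector("list", length(xs))
  h <- h0
  for (t in seq_along(xs)) {
    states[[t]] <- gru_step(params, h, xs[[t]])
    h <- states[[t]]$h
  }
  list(states = states, h_final = h)
}

#' Naive scalar-loop GRU step (reference implementation)
#'
#' Element-by-element evaluation of the gate equations with explicit
#' loops and no matrix algebra. Deliberately slow; it exists as the
#' correctness oracle for [gru_step()] and any accelerated variant.
#'
#' @inheritParams gru_step
#' @return Same structure as [gru_step()].
#' @export
gru_step_reference <- function(params, h_prev, x_t) {
  H <- params$hidden_size
  hx <- c(h_prev, x_t)
  z <- numeric(H); r <- numeric(H); h_tilde <- numeric(H); h <- numeric(H)
  for (i in seq_len(H)) {
    az <- if (params$bias) params$b_z[i] else 0
    ar <- if (params$bias) params$b_r[i] else 0
    for (j in seq_along(hx)) {
      az <- az + params$W_z[i, j] * hx[j]
      ar <- ar + params$W_r[i, j] * hx[j]
    }
    z[i] <- 1 / (1 + exp(-az))
    r[i] <- 1 / (1 + exp(-ar))
  }
  rhx <- c(r * h_prev, x_t)
  for (i in seq_len(H)) {
    ac <- if (params$bias) params$b[i] else 0
    for (j in seq_along(rhx)) ac <- ac + params$W[i, j] * rhx[j]
    h_tilde[i] <- tanh(ac)
    h[i] <- (1 - z[i]) * h_prev[i] + z[i] * h_tilde[i]
  }
  structure(list(h = h, z = z, r = r, h_tilde = h_tilde),
            class = "gru_state")
}

## ---- backpropagation through time (used by stage-2 training) ---------

# Forward pass retaining everything needed for gradients.
gru_forward_cache <- function(params, xs, h0 = NULL) {
  if (is.matrix(xs)) xs <- lapply(seq_len(ncol(xs)), function(j) xs[, j])
  if (is.null(h0)) h0 <- numeric(params$hidden_size)
  run <- gru_sequence(params, xs, h0)
  list(xs = xs, h0 = h0, states = run$states, h_final = run$h_final)
}

# Backward pass: dh_final is the gradient of the loss w.r.t. the final
# hidden state. Returns gradients for W_z, W_r, W (and biases when used).
gru_backward <- function(params, cache, dh_final) {
  H <- params$hidden_size
  gW_z <- matrix(0, nrow(params$W_z), ncol(params$W_z))
  gW_r <- gW_z; gW <- gW_z
  gb_z <- numeric(H); gb_r <- numeric(H); gb <- numeric(H)
  dh <- dh_final
  Wh <- params$W[, seq_len(H), drop = FALSE]       # candidate weights on r*h
  Wzh <- params$W_z[, seq_len(H), drop = FALSE]
  Wrh <- params$W_r[, seq_len(H), drop = FALSE]
  for (t in rev(seq_along(cache$states))) {
    st <- cache$states[[t]]
    h_prev <- if (t == 1L) cache$h0 else cache$states[[t - 1L]]$h
    x_t <- cache$xs[[t]]
    # h = (1-z) h_prev + z h_tilde
    dz <- dh * (st$h_tilde - h_prev)
    dh_tilde <- dh * st$z
    dh_prev <- dh * (1 - st$z)
    # candidate: h_tilde = tanh(W [r*h_prev, x])
    da_c <- dh_tilde * (1 - st$h_tilde^2)
    rhx <- c(st$r * h_prev, x_t)
    gW <- gW + tcrossprod(da_c, rhx)
    if (params$bias) gb <- gb + da_c
    d_rh <- drop(crossprod(Wh, da_c))              # grad w.r.t. r*h_prev
    dr <- d_rh * h_prev
    dh_prev <- dh_prev + d_rh * st$r
    # gates: a_z = W_z [h_prev, x], a_r = W_r [h_prev, x]
    da_z <- dz * st$z * (1 - st$z)
    da_r <- dr * st$r * (1 - st$r)
    hx <- c(h_prev, x_t)
    gW_z <- gW_z + tcrossprod(da_z, hx)
    gW_r <- gW_r + tcrossprod(da_r, hx)
    if (params$bias) { gb_z <- gb_z + da_z; gb_r <- gb_r + da_r }
    dh_prev <- dh_prev + drop(crossprod(Wzh, da_z)) +
      drop(crossprod(Wrh, da_r))
    dh <- dh_prev
  }
  out <- list(W_z = gW_z, W_r = gW_r, W = gW)
  if (params$bias) out <- c(out, list(b_z = gb_z, b_r = gb_r, b = gb))
  out
}

#' Serialise GRU parameters to a JSON checkpoint
#'
#' @param params a [gru_params()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_gru_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "gru_params"))
  obj <- list(kind = "gru_params",
              input_size = params$input_size,
              hidden_size = params$hidden_size,
              bias = params$bias,
              W_z = params$W_z, W_r = params$W_r, W = params$W,
              b_z = params$b_z, b_r = params$b_r, b = params$b)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a GRU checkpoint written by [write_gru_checkpoint()]
#'
#' @param path checkpoint path.
#' @return A [gru_params()].
#' @export
read_gru_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$kind, "gru_params")) stop("not a GRU checkpoint")
  p <- gru_params(obj$input_size, obj$hidden_size, bias = isTRUE(obj$bias))
  p$W_z <- matrix(obj$W_z, nrow = obj$hidden_size, byrow = FALSE)
  p$W_r <- matrix(obj$W_r, nrow = obj$hidden_size, byrow = FALSE)
  p$W <- matrix(obj$W, nrow = obj$hidden_size, byrow = FALSE)
  if (isTRUE(obj$bias)) {
    p$b_z <- as.numeric(obj$b_z); p$b_r <- as.numeric(obj$b_r)
    p$b <- as.numeric(obj$b)
  }
  p
}
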