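## Fully convolutional shock-advisory network ----------------------------
##
## Architecture: three blocks of Conv1D -> ReLU -> MaxPool(2) ->
## Dropout(0.3), kernel sizes {10, 20, 20}, filter counts {5, 25, 50}
## (input channel count 1), then GlobalAveragePooling1D (one feature per
## filter, 50 features) and a dense unit with sigmoid output pSh in
## [0, 1]. Because convolution weights are shared along time and the
## pooled features are averaged, one parameter set (27,681 weights)
## serves any input length >= the receptive field: the same network
## evaluates 5, 10 and 15 s windows (625/1250/1875 samples at 125 Hz).
##
## Convolutions use "same"-style zero padding (stride 1), so each pool
## halves the length (floor). The batched convolution itself lives in
## compiled code (src/conv1d.cpp): an im2col reshape feeding one BLAS
## matrix product per layer. Activations are stored as
## (channels*length) x batch matrices with the channel index fastest.

#' Build the shock-advisory CNN
#'
#' @param D Nominal analysis duration (s), one of 5, 10, 15. The
#'   parameter count does not depend on `D`; the duration is recorded so
#'   that training and prediction agree on the window length.
#' @param kernels Kernel sizes of the three convolution blocks.
#' @param filters Filter counts of the three convolution blocks.
#' @param dropout Dropout rate applied after each pooling layer during
#'   training.
#' @param fs Sampling rate (Hz) of the expected input.
#' @param input_scale Multiplier applied to the raw input before the
#'   first convolution. Signals in this package are in microvolt; the
#'   default `5e-3` expresses them in units of 200 uV (the coarse-VF
#'   amplitude criterion), so typical defi-lead amplitudes reach the
#'   randomly initialised network as O(1)-O(10) values. This keeps
#'   early gradients well conditioned, which matters at desk-scale
#'   epoch budgets.
#' @param seed Optional integer seed for the random-uniform weight
#'   initialisation (range +/- 0.05, biases zero).
#' @return An object of class `cnn_cpr`.
#' @examples
#' m <- build_cnn(10, seed = 1)
#' m$n_params
#' @export
build_cnn <- function(D = 10, kernels = c(10, 20, 20),
                      filters = c(5, 25, 50), dropout = 0.3, fs = 125,
                      input_scale = 5e-3, seed = NULL) {
  check_duration(D)
  stopifnot(length(kernels) == length(filters), length(kernels) >= 1)
  local_seed_if(seed)
  n_l <- length(kernels)
  chans <- c(1L, filters)
  W <- vector("list", n_l)
  b <- vector("list", n_l)
  for (i in seq_len(n_l)) {
    W[[i]] <- matrix(runif(filters[i] * kernels[i] * chans[i], -0.05, 0.05),
                     nrow = filters[i])
    b[[i]] <- numeric(filters[i])
  }
  wd <- matrix(runif(filters[n_l], -0.05, 0.05), ncol = 1)
  bd <- 0
  model <- structure(
    list(D = D, fs = fs, kernels = as.integer(kernels),
         filters = as.integer(filters), dropout = dropout,
         input_scale = input_scale,
         weights = list(W = W, b = b, wd = wd, bd = bd)),
    class = "cnn_cpr"
  )
  model$n_params <- n_cnn_params(model)
  model
}

#' Number of trainable parameters
#'
#' For the default architecture this is
#' (10*1*5 + 5) + (20*5*25 + 25) + (20*25*50 + 50) + (50 + 1) = 27,681,
#' independent of the analysis duration.
#'
#' @param model A `cnn_cpr`.
#' @return Integer parameter count.
#' @export
n_cnn_params <- function(model) {
  w <- model$weights
  sum(vapply(w$W, length, numeric(1))) +
    sum(vapply(w$b, length, numeric(1))) +
    length(w$wd) + 1L
}

#' @export
print.cnn_cpr <- function(x, ...) {
  cat(sprintf("<cnn_cpr> D = %g s (N = %d @ %g Hz), %d conv blocks, %d parameters\n",
              x$D, round(x$D * x$fs), x$fs, length(x$kernels), x$n_params))
  cat(sprintf("  kernels %s | filters %s | pool 2 | dropout %.2f\n",
              paste(x$kernels, collapse = "/"),
              paste(x$filters, collapse = "/"), x$dropout))
  invisible(x)
}

#' Sigmoid output unit
#'
#' `pSh(x) = 1 / (1 + exp(-x))`, the probability of a shockable rhythm
#' produced by the dense output unit.
#'
#' @param x Numeric vector of pre-activations.
#' @return Values in (0, 1).
#' @examples
#' sigmoid_psh(0)
#' @export
sigmoid_psh <- function(x) 1 / (1 + exp(-x))

## receptive field of the conv stack (samples); inputs shorter than this
## see only zero padding at some output positions and are rejected
cnn_receptive_field <- function(model) {
  rf <- 1
  j <- 1
  for (i in seq_along(model$kernels)) {
    rf <- rf + (model$kernels[i] - 1) * j   # conv
    rf <- rf + 1 * j                        # pool window
    j <- j * 2
  }
  rf
}

## forward / backward ----------------------------------------------------
##
## Convolution is evaluated as a sum over kernel offsets k of small
## matrix products: with activations stored as (C*Npad) x B (channel
## fastest) and zero padding baked into the matrix, the input block
## feeding offset k is the contiguous row range C*(k-1) + 1 ... + C*N,
## which reshapes to a (C) x (N*B) operand without any scattered
## gather. This keeps all multiply-accumulate work in BLAS and avoids
## materialising the full im2col matrix.

# X: N x B matrix of raw ECG (uV). Returns list(p, z, cache) where cache
# holds everything backprop needs (NULL unless training = TRUE).
cnn_forward <- function(model, X, training = FALSE) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  N <- nrow(X)
  B <- ncol(X)
  if (N < cnn_receptive_field(model)) {
    abort(sprintf("input length %d is shorter than the receptive field (%d samples)",
                  N, cnn_receptive_field(model)),
          class = "cprshock_error_bad_input")
  }
  w <- model$weights
  A <- X * model$input_scale            # (1*N) x B, channel-fastest
  C <- 1L
  caches <- if (training) vector("list", length(model$kernels)) else NULL
  for (i in seq_along(model$kernels)) {
    K <- model$kernels[i]
    F_i <- model$filters[i]
    blk <- conv_block_fwd(A, w$W[[i]], w$b[[i]], N, K, C)
    P <- blk$P                           # (F_i*No) x B, pooled ReLU output
    dm <- NULL
    if (training && model$dropout > 0) {
      dm <- (runif(length(P)) >= model$dropout) / (1 - model$dropout)
      dim(dm) <- dim(P)
      P <- P * dm
    }
    if (training) {
      caches[[i]] <- list(N = N, C = C, K = K, F = F_i, Ap = blk$Ap,
                          Y = blk$Y, dm = dm)
    }
    A <- P
    C <- F_i
    N <- N %/% 2L
  }
  # global average pooling over time: (F*N) x B -> F x B
  a3 <- A
  dim(a3) <- c(C, N, B)
  gap <- colSums(aperm(a3, c(2, 1, 3))) / N
  dim(gap) <- c(C, B)
  z <- drop(crossprod(gap, w$wd)) + w$bd
  p <- sigmoid_psh(z)
  list(p = p, z = z,
       cache = if (training) list(conv = caches, gap = gap, N_gap = N,
                                  B = B) else NULL)
}

# dz: dLoss/dz, length B. Returns gradients shaped like model$weights.
cnn_backward <- function(model, fwd, dz) {
  w <- model$weights
  ca <- fwd$cache
  B <- ca$B
  n_l <- length(model$kernels)
  dwd <- ca$gap %*% dz
  dbd <- sum(dz)
  F_last <- nrow(w$wd)
  dA <- (w$wd %*% matrix(dz, nrow = 1))[rep(seq_len(F_last), ca$N_gap), ,
                                        drop = FALSE] / ca$N_gap
  gW <- vector("list", n_l)
  gb <- vector("list", n_l)
  for (i in rev(seq_len(n_l))) {
    cc0 <- ca$conv[[i]]
    if (!is.null(cc0$dm)) dA <- dA * cc0$dm   # dA: (F_i*No) x B
    bw <- conv_block_bwd(cc0$Ap, w$W[[i]], cc0$Y, dA,
                         cc0$N, cc0$K, cc0$C, i > 1L)
    gW[[i]] <- bw$dW
    gb[[i]] <- as.numeric(bw$db)
    if (i > 1L) dA <- bw$dA
  }
  list(W = gW, b = gb, wd = dwd, bd = dbd)
}

#' Predict shock probabilities for a batch of analysis windows
#'
#' Runs the network in inference mode (no dropout). Windows of any
#' length at or above the receptive field are accepted; all windows in
#' one call must share a length.
#'
#' @param model A `cnn_cpr` (or a `cnn_cpr_fit`, whose selected model is
#'   used).
#' @param X Numeric matrix, one window per column (uV), or a single
#'   window as a vector.
#' @param chunk Maximum batch size per forward pass.
#' @return Numeric vector of `pSh` probabilities, one per window.
#' @export
cnn_predict <- function(model, X, chunk = 256L) {
  if (inherits(model, "cnn_cpr_fit")) model <- model$model
  stopifnot(inherits(model, "cnn_cpr"))
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  B <- ncol(X)
  out <- numeric(B)
  for (s in seq(1L, B, by = chunk)) {
    e <- min(B, s + chunk - 1L)
    out[s:e] <- cnn_forward(model, X[, s:e, drop = FALSE])$p
  }
  out
}
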