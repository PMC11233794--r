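# Primitive operations of the binary convolutional neural network.
# Weights entering the convolution are 1-bit ({-1, +1}); activations and
# fully-connected weights stay real.

#' Deterministic sign binarization
#'
#' Elementwise `+1` if `x >= 0`, `-1` otherwise (zero maps to `+1`).
#'
#' @param x Numeric vector/matrix/array, finite.
#' @return Object of the same shape with values in `{-1, +1}`.
#' @export
sign_binarize <- function(x) {
  if (!all(is.finite(x))) stop("input must be finite", call. = FALSE)
  out <- x
  out[] <- ifelse(x >= 0, 1, -1)
  out
}

#' Hard sigmoid
#'
#' `clip((x + 1) / 2, 0, 1)`: the piecewise-linear squashing used as the
#' probability of drawing `+1` in stochastic binarization.
#'
#' @param x Numeric, finite.
#' @return Values in `[0, 1]`, same shape.
#' @export
hard_sigmoid <- function(x) {
  if (!all(is.finite(x))) stop("input must be finite", call. = FALSE)
  pmin(pmax((x + 1) / 2, 0), 1)
}

#' Stochastic binarization
#'
#' Independent draws of `+1` with probability `hard_sigmoid(x)` and `-1`
#' otherwise; reproducible under the seed.
#'
#' @param x Numeric, finite.
#' @param seed Integer seed.
#' @return Same shape, values in `{-1, +1}`.
#' @export
stochastic_binarize <- function(x, seed = 1L) {
  p <- hard_sigmoid(x)
  set.seed(as.integer(seed))
  out <- x
  out[] <- ifelse(runif(length(x)) < p, 1, -1)
  out
}

#' Convolution layer
#'
#' Holds latent real kernels of shape `kh x kw x d_in x d_out`; the forward
#' pass uses their sign ([sign_binarize()]), so every weight entering the
#' convolution product is in `{-1, +1}`.
#'
#' @param kernels 4-D array `kh x kw x d_in x d_out` of latent real weights.
#' @param stride Positive integer stride.
#' @param pad Non-negative integer zero padding on each side.
#' @return A `conv_layer` object.
#' @export
conv_layer <- function(kernels, stride = 1L, pad = 0L) {
  stopifnot(is.array(kernels), length(dim(kernels)) == 4L,
            stride >= 1L, pad >= 0L)
  structure(list(kernels = kernels, stride = as.integer(stride),
                 pad = as.integer(pad)),
            class = "conv_layer")
}

# 3-D input -> patch matrix (rows: output positions column-major, cols:
# kernel offsets dy-fastest then dx then input channel).
im2col3 <- function(x, kh, kw, stride, pad) {
  h <- dim(x)[1L]; w <- dim(x)[2L]; d <- dim(x)[3L]
  hp <- h + 2L * pad; wp <- w + 2L * pad
  if (kh > hp || kw > wp) stop("kernel larger than padded input", call. = FALSE)
  xp <- array(0, c(hp, wp, d))
  xp[pad + seq_len(h), pad + seq_len(w), ] <- x
  ho <- (hp - kh) %/% stride + 1L
  wo <- (wp - kw) %/% stride + 1L
  ri <- (seq_len(ho) - 1L) * stride
  ci <- (seq_len(wo) - 1L) * stride
  P <- matrix(0, ho * wo, kh * kw * d)
  col <- 0L
  for (dd in seq_len(d)) {
    for (dx in seq_len(kw)) {
      for (dy in seq_len(kh)) {
        col <- col + 1L
        P[, col] <- xp[ri + dy, ci + dx, dd]
      }
    }
  }
  attr(P, "out_dim") <- c(ho, wo)
  P
}

#' Convolution forward pass (binarized kernels)
#'
#' Valid cross-correlation of the input with the sign-binarized kernels.
#' Output height is `floor((h + 2 pad - kh) / stride) + 1` (same for
#' width); depth equals the number of kernels.
#'
#' @param input 3-D array `h x w x d_in` (a 2-D matrix is treated as depth 1).
#' @param layer A [conv_layer()].
#' @return 3-D array `h_out x w_out x d_out`.
#' @export
conv_forward <- function(input, layer) {
  stopifnot(inherits(layer, "conv_layer"))
  if (is.matrix(input)) input <- array(input, c(dim(input), 1L))
  kd <- dim(layer$kernels)
  if (dim(input)[3L] != kd[3L]) {
    stop("input depth does not match the layer's kernels", call. = FALSE)
  }
  P <- im2col3(input, kd[1L], kd[2L], layer$stride, layer$pad)
  Wb <- matrix(sign_binarize(layer$kernels), nrow = kd[1L] * kd[2L] * kd[3L])
  Z <- P %*% Wb
  od <- attr(P, "out_dim")
  array(Z, c(od[1L], od[2L], kd[4L]))
}

#' Max pooling
#'
#' Per-channel maximum over non-overlapping (stride = window) or strided
#' square windows; depth is unchanged.
#'
#' @param input 3-D array `h x w x d` (a 2-D matrix is treated as depth 1).
#' @param window Pooling window side, default 2.
#' @param stride Stride, default equal to `window`.
#' @return 3-D array of pooled values.
#' @export
maxpool <- function(input, window = 2L, stride = window) {
  if (is.matrix(input)) input <- array(input, c(dim(input), 1L))
  h <- dim(input)[1L]; w <- dim(input)[2L]; d <- dim(input)[3L]
  if (window > h || window > w) stop("window larger than input", call. = FALSE)
  if ((h - window) %% stride != 0L || (w - window) %% stride != 0L) {
    stop("input dimensions are not compatible with window/stride", call. = FALSE)
  }
  ho <- (h - window) %/% stride + 1L
  wo <- (w - window) %/% stride + 1L
  out <- array(-Inf, c(ho, wo, d))
  ri <- (seq_len(ho) - 1L) * stride
  ci <- (seq_len(wo) - 1L) * stride
  for (dy in seq_len(window)) {
    for (dx in seq_len(window)) {
      out <- pmax(out, input[ri + dy, ci + dx, , drop = FALSE])
    }
  }
  out
}

#' Min-max range normalization
#'
#' Elementwise `(x - m) / (x_max - x_min)` per channel, with `m` the channel
#' mean -- a range-scaled centering whose output is always within
#' `[-1, 1]`.  A constant channel (zero range) maps to zeros.  In
#' `"batch"` mode the statistics are computed from `x` itself and blended
#' into the running state with momentum 0.9; in `"running"` mode the stored
#' running statistics are used (inference).  The `"minmax01"` variant
#' rescales to `[0, 1]` via `(x - x_min) / (x_max - x_min)`.
#'
#' @param x 3-D array `h x w x d` (or matrix, depth 1).
#' @param state Optional `norm_state` from a previous call; `NULL` starts a
#'   fresh state.
#' @param mode `"batch"` (training) or `"running"` (inference).
#' @param variant `"centered"` (default) or `"minmax01"`.
#' @return List with `values` (normalized array) and `state` (updated
#'   `norm_state` with per-channel `m`, `x_max`, `x_min`).
#' @export
minmax_normalize <- function(x, state = NULL,
                             mode = c("batch", "running"),
                             variant = c("centered", "minmax01")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)[3L]
  if (mode == "batch") {
    m <- apply(x, 3L, mean)
    xmx <- apply(x, 3L, max)
    xmn <- apply(x, 3L, min)
    if (is.null(state)) {
      state <- list(m = m, x_max = xmx, x_min = xmn)
    } else {
      state$m <- 0.9 * state$m + 0.1 * m
      state$x_max <- 0.9 * state$x_max + 0.1 * xmx
      state$x_min <- 0.9 * state$x_min + 0.1 * xmn
    }
  } else {
    if (is.null(state)) stop("running mode requires a state", call. = FALSE)
    m <- state$m; xmx <- state$x_max; xmn <- state$x_min
  }
  out <- x
  for (k in seq_len(d)) {
    rng <- xmx[k] - xmn[k]
    ctr <- if (variant == "centered") m[k] else xmn[k]
    out[, , k] <- if (rng > 0) (x[, , k] - ctr) / rng else 0
  }
  list(values = out, state = structure(state, class = "norm_state"))
}

#' Fully connected layer
#'
#' @param w Weight matrix, `n_out x n_in`.
#' @param b Bias vector, length `n_out`.
#' @param activation Activation function `g`; default identity.  Use
#'   [relu()] for hidden layers.
#' @return An `fc_layer` object.
#' @export
fc_layer <- function(w, b = rep(0, nrow(w)), activation = identity) {
  stopifnot(is.matrix(w), length(b) == nrow(w), is.function(activation))
  structure(list(w = w, b = b, activation = activation), class = "fc_layer")
}

#' Rectified linear unit
#' @param x Numeric.
#' @return `max(x, 0)` elementwise.
#' @export
relu <- function(x) pmax(x, 0)

#' Fully connected forward pass
#'
#' `g(w x + b)`: affine map followed by the layer's activation.  The final
#' classifier layer uses the identity activation and hands its logits to
#' [softmax_predict()].
#'
#' @param x Numeric vector of length `n_in`.
#' @param layer An [fc_layer()].
#' @return Numeric vector of length `n_out`.
#' @export
fc_forward <- function(x, layer) {
  stopifnot(inherits(layer, "fc_layer"))
  if (length(x) != ncol(layer$w)) stop("shape mismatch", call. = FALSE)
  layer$activation(drop(layer$w %*% x) + layer$b)
}

#' Softmax probabilities and predicted class
#'
#' Numerically stabilized by subtracting the maximum logit.  Probabilities
#' sum to 1; the label is the argmax, ties broken toward the lowest class
#' index.
#'
#' @param logits Finite numeric vector.
#' @return List with `probabilities` and `class` (integer index).
#' @export
softmax_predict <- function(logits) {
  if (!all(is.finite(logits))) stop("logits must be finite", call. = FALSE)
  z <- exp(logits - max(logits))
  p <- z / sum(z)
  list(probabilities = p, class = which.max(p))
}
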