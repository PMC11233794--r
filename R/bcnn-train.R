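# Training and evaluation of the binary CNN.
#
# Architecture preset: input mask resized to a square side (default 64) and
# mapped to {-1, +1}; three blocks of [3x3 binarized convolution (pad 1) ->
# 2x2 max pool -> per-channel min-max normalization]; flatten; one fully
# connected layer to 5 logits; softmax.  Only the convolution kernels are
# 1-bit; gradients reach their latent real weights through a clipped
# straight-through estimator.

#' BCNN configuration
#'
#' @param input_size Side length the input mask is nearest-neighbor-resized
#'   to (default 64; must be divisible by 8 so three 2x2 pools fit).
#' @param n_kernels Kernels per convolution block (default 8 each; exactly
#'   three blocks).
#' @param kernel_size Convolution kernel side (default 3, zero padding 1).
#' @param binarization `"deterministic"` (sign) or `"stochastic"` (used for
#'   the kernels during training only; inference always uses sign).
#' @param norm_variant Normalization variant, see [minmax_normalize()].
#' @param learning_rate,momentum,epochs,batch_size Plain SGD-with-momentum
#'   hyperparameters (defaults 0.1, 0.9, 50, 8; cross-entropy loss).
#' @param lr_decay,lr_decay_at Step learning-rate schedule: the rate is
#'   multiplied by `lr_decay` once `lr_decay_at` (fraction) of the epochs
#'   have passed, settling the end of the run.
#' @param seed Integer seed controlling initialization, shuffling and any
#'   stochastic binarization.
#' @return A `bcnn_config` object.
#' @export
bcnn_config <- function(input_size = 64L, n_kernels = c(16L, 16L, 16L),
                        kernel_size = 3L,
                        binarization = c("deterministic", "stochastic"),
                        norm_variant = c("centered", "minmax01"),
                        learning_rate = 0.1, momentum = 0.9,
                        epochs = 50L, batch_size = 8L,
                        lr_decay = 0.2, lr_decay_at = 0.7, seed = 1L) {
  binarization <- match.arg(binarization)
  norm_variant <- match.arg(norm_variant)
  if (length(n_kernels) != 3L) {
    stop("the preset has exactly three convolution blocks", call. = FALSE)
  }
  if (input_size %% 8L != 0L || input_size < 8L) {
    stop("input_size must be a positive multiple of 8", call. = FALSE)
  }
  structure(
    list(input_size = as.integer(input_size),
         n_kernels = as.integer(n_kernels),
         kernel_size = as.integer(kernel_size),
         binarization = binarization, norm_variant = norm_variant,
         learning_rate = learning_rate, momentum = momentum,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr_decay = lr_decay, lr_decay_at = lr_decay_at,
         seed = as.integer(seed)),
    class = "bcnn_config"
  )
}

# ---- batched array helpers -------------------------------------------------

# x: (H, W, D, B); returns patch matrix (H*W*B) x (k*k*D) for stride-1
# convolution with zero padding keeping the spatial size.
im2col_batch <- function(x, k, pad) {
  dm <- dim(x)
  h <- dm[1L]; w <- dm[2L]; d <- dm[3L]; b <- dm[4L]
  xp <- array(0, c(h + 2L * pad, w + 2L * pad, d, b))
  xp[pad + seq_len(h), pad + seq_len(w), , ] <- x
  P <- matrix(0, h * w * b, k * k * d)
  col <- 0L
  for (dd in seq_len(d)) {
    for (dx in seq_len(k)) {
      for (dy in seq_len(k)) {
        col <- col + 1L
        P[, col] <- xp[dy + seq_len(h) - 1L, dx + seq_len(w) - 1L, dd, ]
      }
    }
  }
  P
}

col2im_batch <- function(dP, h, w, d, b, k, pad) {
  dxp <- array(0, c(h + 2L * pad, w + 2L * pad, d, b))
  col <- 0L
  for (dd in seq_len(d)) {
    for (dx in seq_len(k)) {
      for (dy in seq_len(k)) {
        col <- col + 1L
        ri <- dy + seq_len(h) - 1L
        ci <- dx + seq_len(w) - 1L
        dxp[ri, ci, dd, ] <- dxp[ri, ci, dd, , drop = FALSE] +
          array(dP[, col], c(h, w, 1L, b))
      }
    }
  }
  dxp[pad + seq_len(h), pad + seq_len(w), , , drop = FALSE]
}

conv_batch_forward <- function(x, Wb) {
  dm <- dim(x)
  k <- round(sqrt(nrow(Wb) / dm[3L]))
  P <- im2col_batch(x, k, (k - 1L) %/% 2L)
  Z <- P %*% Wb
  z <- array(Z, c(dm[1L], dm[2L], dm[4L], ncol(Wb)))
  list(out = aperm(z, c(1L, 2L, 4L, 3L)), P = P)
}

conv_batch_backward <- function(dZ, P, Wb, in_dim) {
  dm <- dim(dZ)                            # (H, W, D2, B)
  dZm <- matrix(aperm(dZ, c(1L, 2L, 4L, 3L)), ncol = dm[3L])
  dW <- crossprod(P, dZm)
  dP <- dZm %*% t(Wb)
  k <- round(sqrt(nrow(Wb) / in_dim[3L]))
  dX <- col2im_batch(dP, in_dim[1L], in_dim[2L], in_dim[3L], in_dim[4L],
                     k, (k - 1L) %/% 2L)
  list(dW = dW, dX = dX)
}

pool2_forward <- function(x) {
  dm <- dim(x)
  ro <- seq(1L, dm[1L], by = 2L)
  co <- seq(1L, dm[2L], by = 2L)
  a11 <- x[ro, co, , , drop = FALSE]
  a21 <- x[ro + 1L, co, , , drop = FALSE]
  a12 <- x[ro, co + 1L, , , drop = FALSE]
  a22 <- x[ro + 1L, co + 1L, , , drop = FALSE]
  m <- pmax(a11, a21, a12, a22)
  idx <- ifelse(a11 == m, 1L, ifelse(a21 == m, 2L, ifelse(a12 == m, 3L, 4L)))
  list(out = m, idx = idx)
}

pool2_backward <- function(dM, idx, in_dim) {
  dX <- array(0, in_dim)
  ro <- seq(1L, in_dim[1L], by = 2L)
  co <- seq(1L, in_dim[2L], by = 2L)
  put <- function(sel, r, c) {
    s <- dX[r, c, , , drop = FALSE]
    s[sel] <- dM[sel]
    dX[r, c, , ] <<- s
  }
  put(idx == 1L, ro, co)
  put(idx == 2L, ro + 1L, co)
  put(idx == 3L, ro, co + 1L)
  put(idx == 4L, ro + 1L, co + 1L)
  dX
}

norm_batch_forward <- function(x, state, variant, mode) {
  d <- dim(x)[3L]
  if (mode == "batch") {
    m <- vapply(seq_len(d), function(k) mean(x[, , k, ]), numeric(1L))
    xmx <- vapply(seq_len(d), function(k) max(x[, , k, ]), numeric(1L))
    xmn <- vapply(seq_len(d), function(k) min(x[, , k, ]), numeric(1L))
    state <- if (is.null(state)) {
      list(m = m, x_max = xmx, x_min = xmn)
    } else {
      list(m = 0.9 * state$m + 0.1 * m,
           x_max = 0.9 * state$x_max + 0.1 * xmx,
           x_min = 0.9 * state$x_min + 0.1 * xmn)
    }
  } else {
    m <- state$m; xmx <- state$x_max; xmn <- state$x_min
  }
  rng <- xmx - xmn
  out <- x
  for (k in seq_len(d)) {
    ctr <- if (variant == "centered") m[k] else xmn[k]
    out[, , k, ] <- if (rng[k] > 0) (x[, , k, ] - ctr) / rng[k] else 0
  }
  list(out = out, state = state, rng = rng)
}

norm_batch_backward <- function(dY, rng) {
  d <- dim(dY)[3L]
  dX <- dY
  for (k in seq_len(d)) {
    dX[, , k, ] <- if (rng[k] > 0) dY[, , k, ] / rng[k] else 0
  }
  dX
}

# Binarize the kernels for the forward pass.
forward_kernels <- function(Wlat, config, training, seed) {
  if (training && config$binarization == "stochastic") {
    stochastic_binarize(Wlat, seed = seed)
  } else {
    sign_binarize(Wlat)
  }
}

# Full batched forward pass.  x: (S, S, 1, B).  mode "batch" uses batch
# normalization statistics (training); "running" the stored ones.
bcnn_forward_batch <- function(model, x, mode = "running",
                               kernels = NULL) {
  cfg <- model$config
  kb <- kernels %||% lapply(model$conv, sign_binarize)
  cache <- list(x = list(), P = list(), pool = list(), rng = list())
  cur <- x
  for (i in 1:3) {
    kd <- dim(kb[[i]])
    Wb <- matrix(kb[[i]], nrow = kd[1L] * kd[2L] * kd[3L])
    cache$x[[i]] <- cur
    cf <- conv_batch_forward(cur, Wb)
    cache$P[[i]] <- cf$P
    cache$conv_dim <- c(cache$conv_dim, list(dim(cf$out)))
    pf <- pool2_forward(cf$out)
    cache$pool[[i]] <- pf$idx
    nf <- norm_batch_forward(pf$out, model$norm[[i]], cfg$norm_variant, mode)
    if (mode == "batch") model$norm[[i]] <- nf$state
    cache$rng[[i]] <- nf$rng
    cache$pool_in_dim <- c(cache$pool_in_dim, list(dim(cf$out)))
    cur <- nf$out
  }
  b <- dim(cur)[4L]
  feat <- t(matrix(cur, ncol = b))              # B x n_feat
  logits <- feat %*% t(model$fc$w) +
    matrix(model$fc$b, nrow(feat), length(model$fc$b), byrow = TRUE)
  z <- exp(logits - apply(logits, 1L, max))
  probs <- z / rowSums(z)
  list(model = model, probs = probs, logits = logits, feat = feat,
       feat_dim = dim(cur), cache = cache, kernels = kb)
}

init_model <- function(config, levels) {
  set.seed(config$seed)
  k <- config$kernel_size
  depths_in <- c(1L, config$n_kernels[1:2])
  conv <- vector("list", 3L)
  for (i in 1:3) {
    n <- k * k * depths_in[i] * config$n_kernels[i]
    conv[[i]] <- array(runif(n, -0.5, 0.5),
                       c(k, k, depths_in[i], config$n_kernels[i]))
  }
  n_feat <- (config$input_size %/% 8L)^2 * config$n_kernels[3L]
  fc <- list(
    w = matrix(rnorm(length(levels) * n_feat, 0, sqrt(2 / n_feat)),
               length(levels), n_feat),
    b = rep(0, length(levels))
  )
  structure(
    list(config = config, conv = conv, fc = fc,
         norm = vector("list", 3L), levels = levels),
    class = "bcnn_model"
  )
}

# Resize masks to the network input side and map {0,1} -> {-1,+1}.
masks_to_input <- function(masks, size) {
  b <- length(masks)
  x <- array(0, c(size, size, 1L, b))
  for (i in seq_len(b)) {
    x[, , 1L, i] <- resize_nearest(masks[[i]], size, size) * 2 - 1
  }
  x
}

#' Train the binary CNN on labeled masks
#'
#' Stochastic-gradient training with momentum and cross-entropy loss.  The
#' forward pass always multiplies by 1-bit kernels; gradients flow to the
#' latent real kernels through the straight-through estimator (passed where
#' `|latent| <= 1`, zero outside), and latent kernels are clipped to
#' `[-1, 1]` after every update.  Fixed seed gives a bit-reproducible run.
#'
#' @param masks List of binary matrices (tumor masks).
#' @param labels Character or factor of class labels, one per mask; at least
#'   two distinct classes.
#' @param config A [bcnn_config()].
#' @param validation Optional list with `masks` and `labels` evaluated after
#'   training.
#' @return List with `model` (a `bcnn_model`) and `report` (per-epoch
#'   training accuracy/loss data.frame plus final validation metrics, the
#'   seed and a config snapshot).
#' @export
bcnn_train <- function(masks, labels, config = bcnn_config(),
                       validation = NULL) {
  stopifnot(inherits(config, "bcnn_config"))
  if (length(masks) == 0L) stop("empty dataset", call. = FALSE)
  if (length(masks) != length(labels)) stop("masks/labels length mismatch", call. = FALSE)
  labels <- as.character(labels)
  levels <- grade_levels()
  if (!all(labels %in% levels)) stop("unknown class label", call. = FALSE)
  if (length(unique(labels)) < 2L) stop("need at least two classes", call. = FALSE)

  model <- init_model(config, levels)
  x_all <- masks_to_input(masks, config$input_size)
  y_all <- match(labels, levels)
  n <- length(masks)
  vel <- list(conv = lapply(model$conv, function(w) array(0, dim(w))),
              fcw = matrix(0, nrow(model$fc$w), ncol(model$fc$w)),
              fcb = rep(0, length(model$fc$b)))
  report <- data.frame(epoch = integer(), accuracy = numeric(),
                       loss = numeric())
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$epochs)) {
    lr_now <- config$learning_rate *
      if (epoch > config$lr_decay_at * config$epochs) config$lr_decay else 1
    ord <- sample.int(n)
    correct <- 0L
    loss_sum <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x_all[, , , idx, drop = FALSE]
      yb <- y_all[idx]
      bsz <- length(idx)
      kb <- lapply(seq_along(model$conv), function(i) {
        forward_kernels(model$conv[[i]], config, TRUE,
                        derive_seed(config$seed, epoch * 1000L + start + i))
      })
      fw <- bcnn_forward_batch(model, xb, mode = "batch", kernels = kb)
      model <- fw$model                      # running norm state updated
      p_true <- fw$probs[cbind(seq_len(bsz), yb)]
      loss_sum <- loss_sum + sum(-log(pmax(p_true, 1e-12)))
      correct <- correct + sum(max.col(fw$probs, ties.method = "first") == yb)

      # backward
      dlogits <- fw$probs
      dlogits[cbind(seq_len(bsz), yb)] <- dlogits[cbind(seq_len(bsz), yb)] - 1
      dlogits <- dlogits / bsz
      gfcw <- t(dlogits) %*% fw$feat
      gfcb <- colSums(dlogits)
      dfeat <- dlogits %*% model$fc$w
      dcur <- array(t(dfeat), fw$feat_dim)
      gconv <- vector("list", 3L)
      for (i in 3:1) {
        dnorm <- norm_batch_backward(dcur, fw$cache$rng[[i]])
        dpool <- pool2_backward(dnorm, fw$cache$pool[[i]],
                                fw$cache$pool_in_dim[[i]])
        kd <- dim(fw$kernels[[i]])
        Wb <- matrix(fw$kernels[[i]], nrow = kd[1L] * kd[2L] * kd[3L])
        cb <- conv_batch_backward(dpool, fw$cache$P[[i]], Wb,
                                  dim(fw$cache$x[[i]]))
        gconv[[i]] <- array(cb$dW, kd) * (abs(model$conv[[i]]) <= 1)  # STE
        dcur <- cb$dX
      }
      # SGD with momentum; clip latent kernels to [-1, 1]
      for (i in 1:3) {
        vel$conv[[i]] <- config$momentum * vel$conv[[i]] -
          lr_now * gconv[[i]]
        model$conv[[i]] <- clip(model$conv[[i]] + vel$conv[[i]], -1, 1)
      }
      vel$fcw <- config$momentum * vel$fcw - lr_now * gfcw
      model$fc$w <- model$fc$w + vel$fcw
      vel$fcb <- config$momentum * vel$fcb - lr_now * gfcb
      model$fc$b <- model$fc$b + vel$fcb
    }
    report <- rbind(report, data.frame(
      epoch = epoch, accuracy = 100 * correct / n, loss = loss_sum / n))
  }
  # Recalibrate the inference normalization statistics on the full training
  # set (one deterministic batch-mode pass), so evaluation does not depend
  # on the happenstance of the last mini-batches.
  model$norm <- vector("list", 3L)
  recal <- bcnn_forward_batch(model, x_all, mode = "batch")
  model <- recal$model
  out_report <- list(epochs = report, seed = config$seed, config = config,
                     validation_accuracy = NA_real_,
                     validation_loss = NA_real_)
  if (!is.null(validation)) {
    vm <- bcnn_evaluate(model, validation$masks, validation$labels)
    out_report$validation_accuracy <- vm$accuracy
    out_report$validation_loss <- vm$loss
  }
  list(model = model, report = out_report)
}

# Batched inference probabilities (deterministic sign kernels, running
# normalization statistics).
bcnn_probs <- function(model, masks) {
  x <- masks_to_input(masks, model$config$input_size)
  fw <- bcnn_forward_batch(model, x, mode = "running")
  fw$probs
}

#' Predict the grade of one mask
#'
#' @param model A trained `bcnn_model`.
#' @param mask Binary matrix.
#' @return List with `label`, `class` (index) and `probabilities` (named).
#' @export
bcnn_predict <- function(model, mask) {
  p <- drop(bcnn_probs(model, list(mask)))
  names(p) <- model$levels
  cls <- which.max(p)
  list(label = model$levels[cls], class = cls, probabilities = p)
}

#' Evaluate a trained model on a labeled test set
#'
#' Computes overall accuracy, macro-averaged precision, recall and
#' F-measure (all in percent), cross-entropy loss, and the confusion
#' matrix (rows = truth, columns = prediction) over the five classes.
#'
#' @param model A trained `bcnn_model`.
#' @param masks List of binary matrices.
#' @param labels True class labels.
#' @return List of metrics; see [classification_metrics()].
#' @export
bcnn_evaluate <- function(model, masks, labels) {
  if (length(masks) == 0L) stop("empty test set", call. = FALSE)
  probs <- bcnn_probs(model, masks)
  pred <- model$levels[max.col(probs, ties.method = "first")]
  truth <- as.character(labels)
  y <- match(truth, model$levels)
  loss <- mean(-log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
  m <- classification_metrics(truth, pred, model$levels)
  m$loss <- loss
  m
}

#' Multiclass classification metrics
#'
#' Accuracy plus macro-averaged precision, recall and F-measure in percent,
#' and the confusion matrix (rows = truth, columns = prediction).  A class
#' absent from both truth and prediction contributes 0 to the macro averages
#' and triggers a warning.
#'
#' @param truth,pred Character vectors of true and predicted labels.
#' @param levels Class labels defining the confusion-matrix order.
#' @return List with `accuracy`, `precision`, `recall`, `f_measure`
#'   (percent), `confusion` and a `per_class` data.frame.
#' @export
classification_metrics <- function(truth, pred, levels = grade_levels()) {
  truth <- factor(truth, levels = levels)
  pred <- factor(pred, levels = levels)
  cm <- table(truth = truth, pred = pred)
  absent <- rowSums(cm) == 0 & colSums(cm) == 0
  if (any(absent)) {
    warning("class absent from both truth and prediction: ",
            paste(levels[absent], collapse = ", "), call. = FALSE)
  }
  di <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, di / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, di / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(
    accuracy = 100 * sum(di) / sum(cm),
    precision = 100 * mean(prec),
    recall = 100 * mean(rec),
    f_measure = 100 * mean(f1),
    confusion = cm,
    per_class = data.frame(class = levels, precision = 100 * prec,
                           recall = 100 * rec, f_measure = 100 * f1,
                           row.names = NULL)
  )
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the latent kernels, the
#' running normalization state, the fully connected weights and the config.
#'
#' @param model A `bcnn_model`.
#' @param path File path.
#' @return `path` (save) or the restored `bcnn_model` (load).
#' @export
bcnn_save <- function(model, path) {
  stopifnot(inherits(model, "bcnn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname bcnn_save
#' @export
bcnn_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "bcnn_model"))
  model
}
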