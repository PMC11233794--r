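# Independent brute-force oracles: plain per-pixel loops written directly
# from the operation definitions, kept free of the vectorized/summed-area
# machinery they are used to check.

oracle_local_stats <- function(img, N, M) {
  h <- nrow(img); w <- ncol(img)
  hh <- (N - 1) / 2; hw <- (M - 1) / 2
  mu <- matrix(0, h, w); s2 <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0; sq <- 0
    for (di in -hh:hh) for (dj in -hw:hw) {
      r <- i + di; c <- j + dj
      v <- if (r >= 1 && r <= h && c >= 1 && c <= w) img[r, c] else 0
      s <- s + v; sq <- sq + v * v
    }
    mu[i, j] <- s / (N * M)
    s2[i, j] <- max(sq / (N * M) - mu[i, j]^2, 0)
  }
  list(mu = mu, sigma2 = s2)
}

oracle_wiener <- function(img, N, M, nv = NULL) {
  st <- oracle_local_stats(img, N, M)
  if (is.null(nv)) nv <- mean(st$sigma2)
  out <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    s2 <- st$sigma2[i, j]
    gain <- if (s2 > 0) max(s2 - nv, 0) / s2 else 0
    out[i, j] <- st$mu[i, j] + gain * (img[i, j] - st$mu[i, j])
  }
  out
}

oracle_adaptive_threshold <- function(img, window, C, mode = "mean_minus_c") {
  h <- nrow(img); w <- ncol(img)
  half <- (window - 1) / 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0; n <- 0
    for (di in -half:half) for (dj in -half:half) {
      r <- i + di; c <- j + dj
      if (r >= 1 && r <= h && c >= 1 && c <= w) { s <- s + img[r, c]; n <- n + 1 }
    }
    thr <- if (mode == "mean_minus_c") s / n - C else s / n + C
    out[i, j] <- as.numeric(img[i, j] > thr)
  }
  out
}

oracle_fits <- function(f, s, pos) {
  idx <- which(s$mask == 1, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- pos[1] + idx[k, 1] - s$origin[1]
    c <- pos[2] + idx[k, 2] - s$origin[2]
    v <- if (r >= 1 && r <= nrow(f) && c >= 1 && c <= ncol(f)) f[r, c] else 0
    if (v != 1) return(FALSE)
  }
  TRUE
}

oracle_hits <- function(f, s, pos) {
  idx <- which(s$mask == 1, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    r <- pos[1] + idx[k, 1] - s$origin[1]
    c <- pos[2] + idx[k, 2] - s$origin[2]
    v <- if (r >= 1 && r <= nrow(f) && c >= 1 && c <= ncol(f)) f[r, c] else 0
    if (v == 1) return(TRUE)
  }
  FALSE
}

oracle_erode <- function(f, s) {
  out <- matrix(0, nrow(f), ncol(f))
  for (i in seq_len(nrow(f))) for (j in seq_len(ncol(f))) {
    out[i, j] <- as.numeric(oracle_fits(f, s, c(i, j)))
  }
  out
}

oracle_dilate <- function(f, s) {
  out <- matrix(0, nrow(f), ncol(f))
  for (i in seq_len(nrow(f))) for (j in seq_len(ncol(f))) {
    out[i, j] <- as.numeric(oracle_hits(f, s, c(i, j)))
  }
  out
}

oracle_conv <- function(input, kernels, stride = 1, pad = 0) {
  if (is.matrix(input)) input <- array(input, c(dim(input), 1))
  kb <- sign_binarize(kernels)
  kd <- dim(kb)
  h <- dim(input)[1]; w <- dim(input)[2]; d <- dim(input)[3]
  hp <- h + 2 * pad; wp <- w + 2 * pad
  xp <- array(0, c(hp, wp, d))
  xp[pad + seq_len(h), pad + seq_len(w), ] <- input
  ho <- floor((hp - kd[1]) / stride) + 1
  wo <- floor((wp - kd[2]) / stride) + 1
  out <- array(0, c(ho, wo, kd[4]))
  for (o in seq_len(kd[4])) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    acc <- 0
    for (di in seq_len(kd[1])) for (dj in seq_len(kd[2])) for (dd in seq_len(d)) {
      acc <- acc + xp[(i - 1) * stride + di, (j - 1) * stride + dj, dd] *
        kb[di, dj, dd, o]
    }
    out[i, j, o] <- acc
  }
  out
}

oracle_maxpool <- function(input, window = 2, stride = window) {
  if (is.matrix(input)) input <- array(input, c(dim(input), 1))
  h <- dim(input)[1]; w <- dim(input)[2]; d <- dim(input)[3]
  ho <- (h - window) / stride + 1
  wo <- (w - window) / stride + 1
  out <- array(0, c(ho, wo, d))
  for (k in seq_len(d)) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    out[i, j, k] <- max(input[(i - 1) * stride + seq_len(window),
                              (j - 1) * stride + seq_len(window), k])
  }
  out
}

random_binary <- function(h, w, p = 0.5) {
  matrix(as.numeric(runif(h * w) < p), h, w)
}

random_se <- function(h, w) {
  m <- random_binary(h, w)
  if (sum(m) == 0) m[sample(h, 1), sample(w, 1)] <- 1
  struct_el(m, c(sample(h, 1), sample(w, 1)))
}

# Small in-memory separable mask set for classifier tests: one circular
# blob per class-specific radius at a random position, on an s x s grid.
tiny_mask_set <- function(n_per_class = 8, s = 64, radii = c(3, 5, 8, 12),
                          seed = 1) {
  set.seed(seed)
  masks <- list(); labels <- character(0)
  lv <- grade_levels()
  for (ci in seq_along(lv)) {
    for (i in seq_len(n_per_class)) {
      m <- matrix(0, s, s)
      if (lv[ci] != "Healthy") {
        r <- radii[ci]
        cy <- sample((r + 2):(s - r - 1), 1)
        cx <- sample((r + 2):(s - r - 1), 1)
        for (y in seq_len(s)) for (x in seq_len(s)) {
          if ((y - cy)^2 + (x - cx)^2 <= r^2) m[y, x] <- 1
        }
      }
      masks[[length(masks) + 1]] <- m
      labels <- c(labels, lv[ci])
    }
  }
  list(masks = masks, labels = labels)
}
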