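# Internal numeric helpers shared by the preprocessing and morphology code.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop(sprintf("`%s` must have positive dimensions", name), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

stop_if_not_binary <- function(x, name = deparse(substitute(x))) {
  stop_if_not_matrix(x, name)
  if (!all(x == 0 | x == 1)) {
    stop(sprintf("`%s` must contain only 0 and 1", name), call. = FALSE)
  }
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Quantize a real-valued image to 8-bit: round half away from zero, clip.
quantize_8bit <- function(x) {
  clip(floor(x + 0.5), 0, 255)
}

# Sliding-window sums over an axis-aligned rectangular window via a
# summed-area table.  The window at pixel (i, j) spans rows
# [i - top, i + bottom] and columns [j - left, j + right]; parts of the
# window falling outside the image contribute 0 (equivalently: truncated
# window).  O(h * w) regardless of window size.
box_sum <- function(x, top, bottom, left, right) {
  h <- nrow(x)
  w <- ncol(x)
  # sat[i + 1, j + 1] = sum(x[1:i, 1:j]); first row/col are zeros
  sat <- matrix(0, h + 1L, w + 1L)
  cs <- apply(x, 2L, cumsum)
  if (h == 1L) cs <- matrix(cs, nrow = 1L)
  sat[-1L, -1L] <- t(apply(cs, 1L, cumsum))
  r1 <- pmax(seq_len(h) - top, 1L)          # first row inside the image
  r2 <- pmin(seq_len(h) + bottom, h)        # last row inside the image
  c1 <- pmax(seq_len(w) - left, 1L)
  c2 <- pmin(seq_len(w) + right, w)
  sat[r2 + 1L, c2 + 1L] - sat[r1, c2 + 1L] - sat[r2 + 1L, c1] + sat[r1, c1]
}

# Number of in-image pixels in the same sliding window.
box_count <- function(h, w, top, bottom, left, right) {
  nr <- pmin(seq_len(h) + bottom, h) - pmax(seq_len(h) - top, 1L) + 1L
  nc <- pmin(seq_len(w) + right, w) - pmax(seq_len(w) - left, 1L) + 1L
  outer(nr, nc)
}

# Derive a per-item 32-bit seed from a master seed and a counter.
derive_seed <- function(master, counter) {
  (as.numeric(master) * 7919 + as.numeric(counter)) %% 2147483647
}
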