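# Phase-1 step 1: size standardization and adaptive Wiener denoising.

#' Resize an image by nearest-neighbor interpolation
#'
#' Maps output pixel `i` (0-based) to source row `floor((i + 0.5) * h_in /
#' h_out)`, i.e. each output pixel copies the value of its nearest source
#' pixel, ties broken toward the smaller index.  For an integer upscale
#' factor `k` this replicates every source pixel into a `k x k` block; no new
#' intensity values are ever created.
#'
#' @param img Numeric matrix (grayscale image).
#' @param out_height,out_width Target dimensions in pixels (positive).
#' @return Numeric matrix of size `out_height x out_width`.
#' @export
#' @examples
#' resize_nearest(matrix(1:4, 2, 2, byrow = TRUE), 4, 4)
resize_nearest <- function(img, out_height, out_width) {
  stop_if_not_matrix(img)
  if (out_height < 1 || out_width < 1) {
    stop("target dimensions must be positive", call. = FALSE)
  }
  h <- nrow(img)
  w <- ncol(img)
  ri <- pmin(floor((seq_len(out_height) - 0.5) * h / out_height), h - 1L) + 1L
  ci <- pmin(floor((seq_len(out_width) - 0.5) * w / out_width), w - 1L) + 1L
  img[ri, ci, drop = FALSE]
}

#' Halve an image by removing every second row and column
#'
#' Keeps the rows and columns with odd 1-based index, so a `2h x 2w` image
#' becomes `h x w`.  The inverse of an integer-factor-2 nearest-neighbor
#' upscale.
#'
#' @param img Numeric matrix with even height and width.
#' @return Numeric matrix of half the size.
#' @export
decimate_halve <- function(img) {
  stop_if_not_matrix(img)
  if (nrow(img) %% 2L != 0L || ncol(img) %% 2L != 0L) {
    stop("decimate_halve requires even dimensions", call. = FALSE)
  }
  img[seq(1L, nrow(img), by = 2L), seq(1L, ncol(img), by = 2L), drop = FALSE]
}

#' Wiener filter parameters
#'
#' @param window_h,window_w Odd neighborhood height and width `N`, `M`
#'   (pixels).  Default 3.
#' @param noise_var Optional non-negative noise variance.  When `NULL`
#'   (default), the filter uses the average of all local estimated variances.
#' @return A `wiener_params` list.
#' @export
wiener_params <- function(window_h = 3L, window_w = 3L, noise_var = NULL) {
  if (window_h < 1 || window_w < 1 || window_h %% 2L != 1L || window_w %% 2L != 1L) {
    stop("window dimensions must be odd positive integers", call. = FALSE)
  }
  if (!is.null(noise_var)) {
    if (!is.numeric(noise_var) || length(noise_var) != 1L || noise_var < 0) {
      stop("noise_var must be a single non-negative number", call. = FALSE)
    }
  }
  structure(
    list(window_h = as.integer(window_h), window_w = as.integer(window_w),
         noise_var = noise_var),
    class = "wiener_params"
  )
}

#' Local mean and variance maps
#'
#' Computes, for every pixel, the mean and variance of the `N x M`
#' neighborhood centered there: `mu = sum(a) / (N*M)` and
#' `sigma2 = sum(a^2) / (N*M) - mu^2`, clamped at 0.  Pixels outside the
#' image contribute zero and the normalizer stays `N*M` (zero padding),
#' matching the pixel-wise adaptive filter convention.
#'
#' @param img Numeric matrix.
#' @param p A [wiener_params()] object.
#' @return List with matrices `mu` and `sigma2`, same size as `img`.
#' @export
local_stats <- function(img, p = wiener_params()) {
  stop_if_not_matrix(img)
  stopifnot(inherits(p, "wiener_params"))
  if (p$window_h > 2L * nrow(img) || p$window_w > 2L * ncol(img)) {
    stop("window larger than twice the image", call. = FALSE)
  }
  hh <- (p$window_h - 1L) %/% 2L
  hw <- (p$window_w - 1L) %/% 2L
  nm <- p$window_h * p$window_w
  mu <- box_sum(img, hh, hh, hw, hw) / nm
  sigma2 <- pmax(box_sum(img * img, hh, hh, hw, hw) / nm - mu^2, 0)
  list(mu = mu, sigma2 = sigma2)
}

#' Pixel-wise adaptive Wiener filter
#'
#' Denoises an image by shrinking each pixel toward its local mean in
#' proportion to the locally estimated signal variance:
#' `b = mu + (max(sigma2 - nv, 0) / sigma2) * (a - mu)`, where `mu` and
#' `sigma2` come from [local_stats()] and `nv` is the noise variance.  If the
#' noise variance is not supplied it is taken as the average of all local
#' estimated variances.  Two degeneracies are guarded: the numerator is
#' clamped at 0 (strong noise) and a zero local variance returns `mu`.
#'
#' @inheritParams local_stats
#' @return Filtered image, same size as `img`, with attribute
#'   `"noise_variance"` recording the noise variance actually used.
#' @export
wiener_filter <- function(img, p = wiener_params()) {
  ls <- local_stats(img, p)
  nv <- p$noise_var %||% mean(ls$sigma2)
  gain <- pmax(ls$sigma2 - nv, 0) / pmax(ls$sigma2, .Machine$double.eps)
  out <- ls$mu + gain * (img - ls$mu)
  attr(out, "noise_variance") <- nv
  out
}

#' Standard phase-1 preprocessing of one image
#'
#' Resizes to the standard square size by nearest-neighbor interpolation and
#' applies the adaptive Wiener filter.
#'
#' @param img Numeric matrix, intensities on the 0--255 scale.
#' @param size Target side length in pixels (default 600).
#' @param p [wiener_params()] for the denoising step.
#' @return Preprocessed image, `size x size`.
#' @export
preprocess_image <- function(img, size = 600L, p = wiener_params()) {
  wiener_filter(resize_nearest(img, size, size), p)
}
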