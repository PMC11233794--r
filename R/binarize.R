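# Phase-1 step 2: adaptive thresholding and binary morphology.

#' Adaptive local-mean thresholding
#'
#' Binarizes a grayscale image against a per-pixel threshold derived from the
#' mean `M` of the square neighborhood centered at the pixel (mean over the
#' pixels that fall inside the image).  In the literal `"mean_minus_c"` mode
#' the threshold is `T = M - C` and a pixel is foreground iff it is strictly
#' above `T`; note that with `C > 0` this marks essentially every pixel of a
#' near-constant region as foreground, and the subsequent morphological
#' opening is responsible for cleanup.  The `"mean_plus_c"` mode
#' (`T = M + C`) keeps only pixels clearly brighter than their surroundings
#' and is the practical choice for tumor masks.
#'
#' @param img Numeric matrix.
#' @param window Odd neighborhood side length in pixels (>= 3).
#' @param C Constant offset, intensity units.
#' @param mode `"mean_minus_c"` (default, literal definition) or
#'   `"mean_plus_c"`.
#' @return Binary matrix over `{0, 1}` (1 = foreground).
#' @export
adaptive_threshold <- function(img, window = 35L, C = 10,
                               mode = c("mean_minus_c", "mean_plus_c")) {
  stop_if_not_matrix(img)
  mode <- match.arg(mode)
  if (window < 3L || window %% 2L != 1L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  half <- (window - 1L) %/% 2L
  m <- box_sum(img, half, half, half, half) /
    box_count(nrow(img), ncol(img), half, half, half, half)
  thr <- if (mode == "mean_minus_c") m - C else m + C
  (img > thr) * 1
}

#' Structuring element
#'
#' A small binary matrix with an origin, used to probe a binary image in the
#' morphological operations.
#'
#' @param mask Binary matrix with at least one 1.
#' @param origin Integer `(row, col)` of the origin within `mask`, 1-based.
#'   Defaults to the center, `ceiling((dim + 1) / 2)`; for the even-sized
#'   default 22x22 element this is row 12, column 12.
#' @return A `struct_el` object.
#' @export
struct_el <- function(mask, origin = NULL) {
  stop_if_not_binary(mask)
  if (sum(mask) < 1) stop("structuring element needs at least one 1", call. = FALSE)
  origin <- as.integer(origin %||% ceiling((dim(mask) + 1L) / 2L))
  if (length(origin) != 2L || any(origin < 1L) ||
      origin[1L] > nrow(mask) || origin[2L] > ncol(mask)) {
    stop("origin must lie inside the structuring element", call. = FALSE)
  }
  structure(list(mask = mask, origin = origin), class = "struct_el")
}

#' All-ones square structuring element
#'
#' @param size Side length in pixels; the default 22 is the element used for
#'   skull-boundary removal.
#' @return A [struct_el()].
#' @export
se_square <- function(size = 22L) {
  struct_el(matrix(1, size, size))
}

#' Reflect a structuring element about its origin
#'
#' Rotates the mask by 180 degrees and mirrors the origin, so that the
#' offset set is negated.
#'
#' @param s A [struct_el()].
#' @return The reflected [struct_el()].
#' @export
reflect_se <- function(s) {
  stopifnot(inherits(s, "struct_el"))
  m <- s$mask[nrow(s$mask):1L, ncol(s$mask):1L, drop = FALSE]
  struct_el(m, c(nrow(s$mask) + 1L - s$origin[1L],
                 ncol(s$mask) + 1L - s$origin[2L]))
}

# Row/column offsets of the 1-pixels of s relative to its origin.
se_offsets <- function(s) {
  idx <- which(s$mask == 1, arr.ind = TRUE)
  cbind(idx[, 1L] - s$origin[1L], idx[, 2L] - s$origin[2L])
}

# For every pixel, the number of 1-offsets of s that land on a 1 of f
# (offsets falling outside f count as landing on 0).
morph_count <- function(f, s) {
  if (all(s$mask == 1)) {
    top <- s$origin[1L] - 1L
    bottom <- nrow(s$mask) - s$origin[1L]
    left <- s$origin[2L] - 1L
    right <- ncol(s$mask) - s$origin[2L]
    return(box_sum(f, top, bottom, left, right))
  }
  h <- nrow(f)
  w <- ncol(f)
  off <- se_offsets(s)
  out <- matrix(0, h, w)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1L]
    dc <- off[k, 2L]
    rs <- max(1L, 1L - dr):min(h, h - dr)
    cs <- max(1L, 1L - dc):min(w, w - dc)
    if (length(rs) > 0L && length(cs) > 0L) {
      out[rs, cs] <- out[rs, cs] + f[rs + dr, cs + dc, drop = FALSE]
    }
  }
  out
}

#' Does the structuring element fit / hit the image at a position?
#'
#' `fits` is true when every 1-pixel of `s`, placed with its origin at
#' `pos`, lands on a 1 of `f`; `hits` is true when at least one does.
#' Pixels of `s` falling outside the image compare against 0.
#'
#' @param f Binary matrix.
#' @param s A [struct_el()].
#' @param pos Integer `(row, col)`, 1-based, inside `f`.
#' @return Single logical.
#' @export
fits <- function(f, s, pos) {
  stop_if_not_binary(f)
  stopifnot(inherits(s, "struct_el"))
  off <- se_offsets(s)
  r <- pos[1L] + off[, 1L]
  c <- pos[2L] + off[, 2L]
  inside <- r >= 1L & r <= nrow(f) & c >= 1L & c <= ncol(f)
  if (!all(inside)) return(FALSE)
  all(f[cbind(r, c)] == 1)
}

#' @rdname fits
#' @export
hits <- function(f, s, pos) {
  stop_if_not_binary(f)
  stopifnot(inherits(s, "struct_el"))
  off <- se_offsets(s)
  r <- pos[1L] + off[, 1L]
  c <- pos[2L] + off[, 2L]
  inside <- r >= 1L & r <= nrow(f) & c >= 1L & c <= ncol(f)
  any(f[cbind(r, c)[inside, , drop = FALSE]] == 1)
}

#' Binary erosion
#'
#' `g(x, y) = 1` exactly where the structuring element fits the image with
#' its origin at `(x, y)`; since out-of-image pixels count as background,
#' erosion strips a layer from both inner and outer region boundaries.
#'
#' @param f Binary matrix.
#' @param s A [struct_el()]; default all-ones 22x22.
#' @return Binary matrix, same size as `f`.
#' @export
erode <- function(f, s = se_square()) {
  stop_if_not_binary(f)
  stopifnot(inherits(s, "struct_el"))
  (morph_count(f, s) == sum(s$mask)) * 1
}

#' Binary dilation
#'
#' `g(x, y) = 1` exactly where the structuring element hits the image with
#' its origin at `(x, y)`; dilation adds a layer of pixels to region
#' boundaries.
#'
#' @inheritParams erode
#' @return Binary matrix, same size as `f`.
#' @export
dilate <- function(f, s = se_square()) {
  stop_if_not_binary(f)
  stopifnot(inherits(s, "struct_el"))
  (morph_count(f, s) > 0) * 1
}

#' Morphological opening of a tumor mask
#'
#' Erosion followed by dilation with the reflected element (the opening
#' `f` \eqn{\circ} `s`), removing every connected foreground component that
#' cannot contain the structuring element -- in particular thin skull
#' boundaries and isolated noise pixels -- while regrowing the surviving
#' tumor region to (approximately) its original extent.  Dilating with the
#' reflected element keeps the operation idempotent and position-preserving
#' for any origin choice; for symmetric elements it coincides with dilating
#' by `s` itself.
#'
#' @inheritParams erode
#' @return Binary matrix, same size as `f`.
#' @export
clean_mask <- function(f, s = se_square()) {
  dilate(erode(f, s), reflect_se(s))
}

#' Foreground area of a binary mask
#'
#' @param f Binary matrix.
#' @return Number of 1-pixels.
#' @export
tumor_area <- function(f) {
  stop_if_not_binary(f)
  sum(f)
}
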