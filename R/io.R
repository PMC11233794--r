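# Reading and writing 8-bit grayscale images.

#' Read a grayscale image
#'
#' Reads an 8-bit PNG (or JPEG, if the \pkg{jpeg} package is installed) and
#' returns it as a numeric matrix of intensities in `[0, 255]`.  Color images
#' are converted to luma with the Rec. 601 weights.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return Numeric matrix (rows = image height) with values in `[0, 255]`.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    stop(sprintf("unsupported image format: '%s'", ext), call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] >= 3L) {
      arr <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  arr * 255
}

#' Write a grayscale image as 8-bit PNG
#'
#' Intensities are rounded half away from zero and clipped to `[0, 255]`
#' before writing; internal arithmetic elsewhere in the package stays in
#' real numbers, quantization happens only here.
#'
#' @param img Numeric matrix of intensities on the 0--255 scale.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  stop_if_not_matrix(img)
  png::writePNG(quantize_8bit(img) / 255, path)
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask Binary matrix over `{0, 1}`.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stop_if_not_binary(mask)
  png::writePNG(mask, path)
  invisible(path)
}

#' Read a 0/255 (or any thresholdable) PNG as a binary mask
#'
#' Pixels strictly above half intensity become 1.
#'
#' @param path Path to the mask image.
#' @return Binary matrix over `{0, 1}`.
#' @export
read_mask <- function(path) {
  img <- read_gray(path)
  (img > 127.5) * 1
}
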