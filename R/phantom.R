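# Synthetic brain-MRI phantoms: skull ring, noisy tissue, optional tumor
# blob whose pixel area determines the grade label.

#' Phantom image specification
#'
#' Describes a synthetic head phantom: a bright skull ring (annulus), a noisy
#' brain-tissue interior, a dark exterior, and zero or one bright elliptical
#' tumor blob.  The tumor, when present, must lie strictly inside the inner
#' edge of the skull ring.
#'
#' @param height,width Image dimensions in pixels.
#' @param skull_center `(row, col)` of the ring center; default image center.
#' @param skull_outer_radius Outer ring radius, pixels; must not exceed
#'   `min(height, width) / 2`.
#' @param skull_thickness Ring thickness, pixels.
#' @param skull_intensity Ring intensity, 0--255.
#' @param tissue_intensity Brain-tissue base intensity, 0--255.
#' @param background_intensity Exterior base intensity, 0--255.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (intensity units; applied everywhere, clipped to `[0, 255]`).
#' @param tumor `NULL` for a healthy phantom, else a list with `center`
#'   `(row, col)`, `semi_axes` `(a, b)` in pixels, and `intensity` 0--255.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(height = 600L, width = 600L,
                         skull_center = c(height / 2, width / 2),
                         skull_outer_radius = floor(0.45 * min(height, width)),
                         skull_thickness = 12,
                         skull_intensity = 255,
                         tissue_intensity = 120,
                         background_intensity = 10,
                         noise_sd = 8,
                         tumor = NULL) {
  if (height < 1 || width < 1) stop("dimensions must be positive", call. = FALSE)
  if (skull_outer_radius > min(height, width) / 2) {
    stop("skull_outer_radius exceeds half the smaller image dimension", call. = FALSE)
  }
  ints <- c(skull_intensity, tissue_intensity, background_intensity)
  if (any(ints < 0 | ints > 255)) stop("intensities must be in [0, 255]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  inner_radius <- skull_outer_radius - skull_thickness
  if (inner_radius <= 0) stop("skull ring thicker than its radius", call. = FALSE)
  if (!is.null(tumor)) {
    stopifnot(is.list(tumor), length(tumor$center) == 2L,
              length(tumor$semi_axes) == 2L, length(tumor$intensity) == 1L)
    if (tumor$intensity < 0 || tumor$intensity > 255) {
      stop("tumor intensity must be in [0, 255]", call. = FALSE)
    }
    if (any(tumor$semi_axes <= 0)) stop("tumor semi-axes must be positive", call. = FALSE)
    d <- sqrt(sum((tumor$center - skull_center)^2))
    if (d + max(tumor$semi_axes) >= inner_radius) {
      stop("tumor must lie strictly inside the skull ring", call. = FALSE)
    }
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         skull_center = skull_center, skull_outer_radius = skull_outer_radius,
         skull_thickness = skull_thickness, skull_intensity = skull_intensity,
         tissue_intensity = tissue_intensity,
         background_intensity = background_intensity,
         noise_sd = noise_sd, tumor = tumor),
    class = "phantom_spec"
  )
}

#' Render a phantom image and its ground-truth tumor mask
#'
#' Deterministic geometry plus seeded additive Gaussian noise: the same
#' `spec` and `seed` reproduce the image bit for bit, and two seeds differ
#' only in the noise field.  The mask marks exactly the pixels `(r, c)`
#' satisfying the tumor-ellipse inequality
#' `((r - cr)/a)^2 + ((c - cc)/b)^2 <= 1`; it carries no noise.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the noise field.
#' @return List with `image` (numeric matrix, 0--255) and `mask` (binary
#'   matrix; all zeros for a healthy phantom).
#' @export
make_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height
  w <- spec$width
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- (rr - spec$skull_center[1L])^2 + (cc - spec$skull_center[2L])^2
  inner <- spec$skull_outer_radius - spec$skull_thickness
  img <- matrix(spec$background_intensity, h, w)
  img[d2 <= inner^2] <- spec$tissue_intensity
  ring <- d2 > inner^2 & d2 <= spec$skull_outer_radius^2
  img[ring] <- spec$skull_intensity
  mask <- matrix(0, h, w)
  if (!is.null(spec$tumor)) {
    t <- spec$tumor
    e <- ((rr - t$center[1L]) / t$semi_axes[1L])^2 +
      ((cc - t$center[2L]) / t$semi_axes[2L])^2
    mask[e <= 1] <- 1
    img[mask == 1] <- t$intensity
  }
  if (spec$noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- clip(img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w), 0, 255)
  }
  list(image = img, mask = mask)
}

#' Grade bins: tumor area thresholds
#'
#' Strictly increasing pixel-area thresholds `a1 < a2 < a3 < a4`
#' partitioning tumor area into Grade I `(0, a1]`, Grade II `(a1, a2]`,
#' Grade III `(a2, a3]`, Grade IV `(a3, a4]`; area 0 is Healthy.  The
#' ordinal grade-vs-size relation is the modeled quantity; the default
#' pixel values (at the 600x600 standard size) are a calibration chosen so
#' that the smallest grade's blobs still survive a morphological opening by
#' the 22x22 structuring element.
#'
#' @param a1,a2,a3,a4 Area thresholds in pixels.
#' @return A `grade_bins` object.
#' @export
grade_bins <- function(a1 = 1500, a2 = 3000, a3 = 5500, a4 = 9000) {
  v <- c(a1, a2, a3, a4)
  if (a1 <= 0 || any(diff(v) <= 0)) {
    stop("bins must be strictly increasing with a1 > 0", call. = FALSE)
  }
  structure(list(thresholds = v), class = "grade_bins")
}

#' Map a tumor pixel area to its grade label
#'
#' Area 0 is Healthy; otherwise membership in the left-open/right-closed
#' bins of [grade_bins()] decides the grade.  Areas beyond the last
#' threshold are outside the calibrated range and raise an error.
#'
#' @param area Non-negative pixel count (vectorized).
#' @param bins A [grade_bins()].
#' @return Character vector of labels from [grade_levels()].
#' @export
#' @examples
#' grade_from_area(c(0, 400, 401), grade_bins(100, 400, 900, 1600))
grade_from_area <- function(area, bins = grade_bins()) {
  stopifnot(inherits(bins, "grade_bins"))
  if (any(area < 0)) stop("area must be non-negative", call. = FALSE)
  th <- bins$thresholds
  if (any(area > th[4L])) {
    stop(sprintf("area %g exceeds the calibrated range (max %g)",
                 max(area), th[4L]), call. = FALSE)
  }
  ifelse(area == 0, "Healthy",
         c("Grade I", "Grade II", "Grade III", "Grade IV")[
           findInterval(area, th, left.open = TRUE) + 1L])
}

#' Dataset generation specification
#'
#' Per-class image counts, grade bins, and per-class tumor-area sampling
#' ranges.  Each tumor class's range must lie strictly inside its grade bin
#' with the stated margin, and the ranges must be pairwise disjoint, so that
#' blob area alone separates the classes.
#'
#' @param n_per_class Images per class; either a single count or a named
#'   vector over [grade_levels()].
#' @param bins A [grade_bins()].
#' @param area_ranges Named list of `(lo, hi)` pixel-area ranges for the four
#'   tumor grades.
#' @param margin Minimum distance (pixels) between a range end and its bin
#'   boundary.
#' @param height,width,noise_sd Phantom geometry/noise forwarded to
#'   [phantom_spec()].
#' @param seed Master seed; per-image seeds are derived from it by a stable
#'   counter.
#' @return A `dataset_spec` object.
#' @export
dataset_spec <- function(n_per_class = 50L,
                         bins = grade_bins(),
                         area_ranges = list(
                           "Grade I"   = c(1000, 1400),
                           "Grade II"  = c(1800, 2800),
                           "Grade III" = c(3400, 5200),
                           "Grade IV"  = c(6000, 8500)
                         ),
                         margin = 100,
                         height = 600L, width = 600L,
                         noise_sd = 8,
                         seed = 1L) {
  stopifnot(inherits(bins, "grade_bins"))
  lv <- grade_levels()
  if (length(n_per_class) == 1L) {
    n_per_class <- stats::setNames(rep(as.integer(n_per_class), 5L), lv)
  }
  if (!all(lv %in% names(n_per_class)) || any(n_per_class < 1L)) {
    stop("n_per_class must give a count >= 1 for every class", call. = FALSE)
  }
  grades <- lv[1:4]
  if (!all(grades %in% names(area_ranges))) {
    stop("area_ranges must cover Grade I..IV", call. = FALSE)
  }
  lo_bin <- c(0, bins$thresholds[1:3])
  hi_bin <- bins$thresholds
  for (i in seq_along(grades)) {
    r <- area_ranges[[grades[i]]]
    if (r[1L] >= r[2L]) stop("area ranges must satisfy lo < hi", call. = FALSE)
    if (r[1L] - lo_bin[i] < margin && i > 1L || r[1L] <= lo_bin[i] ||
        hi_bin[i] - r[2L] < 0 || (hi_bin[i] - r[2L]) < margin) {
      stop(sprintf("area range for %s straddles or crowds its bin boundary",
                   grades[i]), call. = FALSE)
    }
  }
  rng <- do.call(rbind, area_ranges[grades])
  ord <- order(rng[, 1L])
  if (any(rng[ord, 1L][-1L] <= rng[ord, 2L][-4L])) {
    stop("per-class area ranges must be pairwise disjoint", call. = FALSE)
  }
  structure(
    list(n_per_class = n_per_class[lv], bins = bins,
         area_ranges = area_ranges, margin = margin,
         height = as.integer(height), width = as.integer(width),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "dataset_spec"
  )
}

# Sample one tumor geometry with target pixel area inside [lo, hi].
sample_tumor <- function(lo, hi, inner_radius, center) {
  target <- runif(1L, lo, hi)
  aspect <- runif(1L, 0.9, 1.1)          # near-circular: a/b ratio
  ab <- target / pi
  a <- sqrt(ab * aspect)
  b <- sqrt(ab / aspect)
  rmax <- inner_radius - max(a, b) - 8
  r <- rmax * sqrt(runif(1L))
  th <- runif(1L, 0, 2 * pi)
  list(center = center + r * c(cos(th), sin(th)),
       semi_axes = c(a, b), intensity = 230)
}

# Deterministic per-image geometry sampling shared by generate_dataset()
# and generate_phantom_masks(): one record per image with its derived seed,
# label and tumor geometry (validated to land inside the class's bin after
# rasterization).
sample_dataset_geometry <- function(dspec) {
  records <- list()
  counter <- 0L
  inner_radius <- floor(0.45 * min(dspec$height, dspec$width)) - 12
  center <- c(dspec$height / 2, dspec$width / 2)
  for (label in grade_levels()) {
    rng <- if (label == "Healthy") NULL else dspec$area_ranges[[label]]
    for (i in seq_len(dspec$n_per_class[[label]])) {
      counter <- counter + 1L
      seed_i <- derive_seed(dspec$seed, counter)
      set.seed(seed_i)
      tumor <- NULL
      if (!is.null(rng)) {
        # resample on the rare rasterization landing outside the class bin
        for (try in 1:20) {
          tumor <- sample_tumor(rng[1L], rng[2L], inner_radius, center)
          area <- sum(ellipse_mask(dspec$height, dspec$width, tumor))
          if (identical(grade_from_area(area, dspec$bins), label)) break
          tumor <- NULL
        }
        if (is.null(tumor)) {
          stop(sprintf("could not sample a %s tumor inside its bin", label),
               call. = FALSE)
        }
      }
      records[[counter]] <- list(label = label, seed = seed_i, tumor = tumor,
                                 index = counter)
    }
  }
  records
}

#' Generate a labeled phantom dataset on disk
#'
#' Writes one subfolder per class under `out_dir/images` (8-bit grayscale
#' PNGs) and the matching ground-truth masks under `out_dir/masks`, plus a
#' `manifest.csv` with columns `path, label, area_px, split, seed,
#' mask_path`.  Every image's rasterized tumor area is checked to map back
#' to its folder label under [grade_from_area()].  Regenerating with the
#' same spec and seed is byte-identical.
#'
#' @param dspec A [dataset_spec()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data.frame, invisibly the same as the CSV.
#' @export
generate_dataset <- function(dspec, out_dir) {
  stopifnot(inherits(dspec, "dataset_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  records <- sample_dataset_geometry(dspec)
  rows <- vector("list", length(records))
  for (rec in records) {
    img_dir <- file.path(out_dir, "images", rec$label)
    msk_dir <- file.path(out_dir, "masks", rec$label)
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
    spec <- phantom_spec(height = dspec$height, width = dspec$width,
                         noise_sd = dspec$noise_sd, tumor = rec$tumor)
    ph <- make_phantom(spec, seed = rec$seed)
    fn <- sprintf("img_%04d.png", rec$index)
    img_path <- file.path(img_dir, fn)
    msk_path <- file.path(msk_dir, fn)
    write_gray(ph$image, img_path)
    write_mask(ph$mask, msk_path)
    rows[[rec$index]] <- data.frame(
      path = img_path, label = rec$label, area_px = sum(ph$mask),
      split = NA_character_, seed = rec$seed, mask_path = msk_path,
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Generate ground-truth phantom masks in memory
#'
#' Samples exactly the same deterministic per-image tumor geometries as
#' [generate_dataset()] (same spec and seed give pixel-identical masks) but
#' renders only the binary ground-truth masks, skipping the grayscale
#' rendering and disk I/O.  Convenient for classifier experiments that
#' consume masks directly.
#'
#' @param dspec A [dataset_spec()].
#' @return List with `masks` (list of binary matrices), `labels` (character)
#'   and `areas` (pixel counts).
#' @export
generate_phantom_masks <- function(dspec) {
  stopifnot(inherits(dspec, "dataset_spec"))
  records <- sample_dataset_geometry(dspec)
  masks <- lapply(records, function(rec) {
    if (is.null(rec$tumor)) {
      matrix(0, dspec$height, dspec$width)
    } else {
      ellipse_mask(dspec$height, dspec$width, rec$tumor)
    }
  })
  list(masks = masks,
       labels = vapply(records, `[[`, character(1L), "label"),
       areas = vapply(masks, sum, numeric(1L)))
}

# Rasterized ellipse mask area helper (same inequality as make_phantom).
ellipse_mask <- function(h, w, tumor) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  e <- ((rr - tumor$center[1L]) / tumor$semi_axes[1L])^2 +
    ((cc - tumor$center[2L]) / tumor$semi_axes[2L])^2
  (e <= 1) * 1
}
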