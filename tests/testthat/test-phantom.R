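# Small-geometry dataset spec used across these tests: 200x200 phantoms
# with proportionally scaled grade bins and sampling ranges.
small_dspec <- function(n = 3L, seed = 9L) {
  dataset_spec(
    n_per_class = n,
    bins = grade_bins(220, 420, 700, 1100),
    area_ranges = list(
      "Grade I"   = c(120, 190),
      "Grade II"  = c(260, 390),
      "Grade III" = c(460, 650),
      "Grade IV"  = c(760, 1050)
    ),
    margin = 30,
    height = 200L, width = 200L, seed = seed
  )
}

test_that("phantom geometry is exact and noise is the only stochastic term", {
  healthy <- make_phantom(phantom_spec(), seed = 1)
  expect_equal(sum(healthy$mask), 0)
  expect_identical(dim(healthy$image), c(600L, 600L))

  spec <- phantom_spec(tumor = list(center = c(300, 300),
                                    semi_axes = c(30, 30), intensity = 230))
  ph <- make_phantom(spec, seed = 1)
  # rasterized circle area close to pi r^2 and exactly the inequality count
  expect_lt(abs(sum(ph$mask) - pi * 900) / (pi * 900), 0.05)
  brute <- 0
  for (r in 1:600) for (c in 1:600) {
    if (((r - 300) / 30)^2 + ((c - 300) / 30)^2 <= 1) brute <- brute + 1
  }
  expect_equal(sum(ph$mask), brute)

  ph2 <- make_phantom(spec, seed = 2)
  expect_identical(ph$mask, ph2$mask)
  expect_false(identical(ph$image, ph2$image))
  # without noise the renderings coincide: only the noise field differs
  spec0 <- phantom_spec(noise_sd = 0,
                        tumor = list(center = c(300, 300),
                                     semi_axes = c(30, 30), intensity = 230))
  expect_identical(make_phantom(spec0, 1), make_phantom(spec0, 2))
  # bit-for-bit reproducibility
  expect_identical(make_phantom(spec, 5), make_phantom(spec, 5))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(skull_outer_radius = 400), "exceeds")
  expect_error(phantom_spec(tumor = list(center = c(300, 540),
                                         semi_axes = c(30, 30),
                                         intensity = 230)),
               "inside the skull ring")
  expect_error(phantom_spec(tissue_intensity = 300), "0, 255")
})

test_that("grade bins map areas with left-open right-closed intervals", {
  bins <- grade_bins(100, 400, 900, 1600)
  expect_identical(grade_from_area(0, bins), "Healthy")
  expect_identical(grade_from_area(400, bins), "Grade II")
  expect_identical(grade_from_area(401, bins), "Grade III")
  expect_identical(grade_from_area(c(1, 100, 101, 900, 1600), bins),
                   c("Grade I", "Grade I", "Grade II", "Grade III", "Grade IV"))
  expect_error(grade_from_area(1601, bins), "calibrated range")
  expect_error(grade_from_area(-1, bins), "non-negative")
  expect_error(grade_bins(100, 90, 900, 1600), "increasing")
})

test_that("dataset spec validates counts, margins and disjoint ranges", {
  expect_error(dataset_spec(n_per_class = 0L), "count >= 1")
  # range straddles a bin boundary
  expect_error(dataset_spec(area_ranges = list(
    "Grade I" = c(1000, 1600), "Grade II" = c(1800, 2800),
    "Grade III" = c(3400, 5200), "Grade IV" = c(6000, 8500))),
    "straddles|crowds")
})

test_that("generated datasets are labeled consistently, reproducible and separable", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  man <- generate_dataset(small_dspec(), out1)
  expect_equal(nrow(man), 15)
  expect_equal(unname(table(man$label)[grade_levels()]), rep(3L, 5),
               ignore_attr = TRUE)

  # the folder label matches the grade recomputed from the written mask
  for (i in seq_len(nrow(man))) {
    area <- tumor_area(read_mask(man$mask_path[i]))
    expect_equal(area, man$area_px[i])
    expect_identical(grade_from_area(area, small_dspec()$bins), man$label[i])
  }

  # regeneration is byte-identical (manifest and every image)
  man2 <- generate_dataset(small_dspec(), out2)
  man2$path <- sub(out2, out1, man2$path, fixed = TRUE)
  man2$mask_path <- sub(out2, out1, man2$mask_path, fixed = TRUE)
  expect_identical(man, man2)
  f1 <- list.files(out1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(out2, recursive = TRUE, full.names = TRUE)
  expect_identical(unname(tools::md5sum(sort(f1[!grepl("manifest", f1)]))),
                   unname(tools::md5sum(sort(f2[!grepl("manifest", f2)]))))

  # area alone linearly separates the classes: a 1-D threshold classifier
  # from the class area ranges scores 100% on the manifest
  cuts <- c(-1, 0.5, 220, 420, 700, Inf)
  pred <- c("Healthy", "Grade I", "Grade II", "Grade III", "Grade IV")[
    findInterval(man$area_px, cuts)]
  expect_identical(pred, man$label)
})

test_that("in-memory mask generation matches the on-disk dataset", {
  out <- withr::local_tempdir()
  man <- generate_dataset(small_dspec(n = 2L), out)
  gm <- generate_phantom_masks(small_dspec(n = 2L))
  expect_identical(gm$labels, man$label)
  expect_equal(gm$areas, man$area_px)
  for (i in seq_along(gm$masks)) {
    expect_equal(gm$masks[[i]], read_mask(man$mask_path[i]))
  }
})
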