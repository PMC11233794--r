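test_that("adaptive threshold follows the local-mean-offset rule with strict ties-to-background", {
  cst <- matrix(50, 7, 7)
  # literal mean-minus-C: every pixel of a constant image is above M - C
  expect_true(all(adaptive_threshold(cst, 3, 2) == 1))
  # a pixel exactly equal to its threshold is background (C = 0)
  expect_true(all(adaptive_threshold(cst, 3, 0) == 0))

  # bright 3x3 patch on a dark field: with the mean-plus-C mode exactly the
  # bright pixels clear their neighborhood mean
  img <- matrix(10, 9, 9)
  img[4:6, 4:6] <- 200
  got <- adaptive_threshold(img, 9, 5, mode = "mean_plus_c")
  expect_equal(got, oracle_adaptive_threshold(img, 9, 5, "mean_plus_c"))
  expect_equal(sum(got), 9)
  expect_true(all(got[4:6, 4:6] == 1))
})

test_that("adaptive threshold agrees with the loop oracle and is shift invariant", {
  set.seed(101)
  for (i in 1:10) {
    img <- matrix(sample(0:255, 81, replace = TRUE), 9, 9)
    w <- sample(c(3, 5), 1)
    C <- runif(1, 0, 20)
    mode <- sample(c("mean_minus_c", "mean_plus_c"), 1)
    expect_equal(adaptive_threshold(img, w, C, mode),
                 oracle_adaptive_threshold(img, w, C, mode))
    # adding a constant shifts pixel and neighborhood mean equally
    expect_equal(adaptive_threshold(img + 37.5, w, C, mode),
                 adaptive_threshold(img, w, C, mode))
  }
  expect_error(adaptive_threshold(matrix(0, 3, 3), 4, 1), "odd")
})

test_that("fit and hit follow their universal/existential definitions", {
  f <- matrix(0, 5, 5); f[2:3, 2:3] <- 1
  s2 <- struct_el(matrix(1, 2, 2), c(1, 1))
  expect_true(fits(f, s2, c(2, 2)))
  expect_true(hits(f, s2, c(2, 2)))
  s1 <- struct_el(matrix(1, 1, 1), c(1, 1))
  expect_false(fits(f, s1, c(1, 1)))
  expect_false(hits(f, s1, c(1, 1)))

  set.seed(111)
  for (i in 1:5) {
    f <- random_binary(8, 8)
    s <- random_se(3, 3)
    for (r in 1:8) for (c in 1:8) {
      expect_identical(fits(f, s, c(r, c)), oracle_fits(f, s, c(r, c)))
      expect_identical(hits(f, s, c(r, c)), oracle_hits(f, s, c(r, c)))
    }
  }
})

test_that("erosion and dilation match exhaustive fit/hit oracles", {
  ones <- matrix(1, 10, 10)
  s3 <- struct_el(matrix(1, 3, 3))
  e <- erode(ones, s3)
  expect_equal(sum(e), 64)                       # interior 8x8 survives
  expect_true(all(e[2:9, 2:9] == 1))
  expect_true(all(erode(matrix(0, 6, 6), s3) == 0))
  expect_true(all(dilate(matrix(0, 6, 6), s3) == 0))

  single <- matrix(0, 7, 7); single[4, 4] <- 1
  d <- dilate(single, s3)
  expect_equal(sum(d), 9)
  expect_true(all(d[3:5, 3:5] == 1))

  set.seed(121)
  for (i in 1:8) {
    f <- random_binary(12, 12)
    s <- random_se(sample(2:4, 1), sample(2:4, 1))
    expect_equal(erode(f, s), oracle_erode(f, s))
    expect_equal(dilate(f, s), oracle_dilate(f, s))
  }
})

test_that("erosion/dilation duality and ordering hold on random images", {
  set.seed(131)
  for (i in 1:8) {
    f <- random_binary(10, 10)
    s <- random_se(3, 3)
    # both operators probe position + offset, so complementation swaps
    # fit and hit with the same element wherever the probe window stays
    # inside the image (zero padding breaks it on the border frame)
    lhs <- 1 - erode(f, s)
    rhs <- dilate(1 - f, s)
    expect_equal(lhs[4:7, 4:7], rhs[4:7, 4:7])
    # origin pixel set to 1 forces anti-extensivity/extensivity
    m <- s$mask; m[s$origin[1], s$origin[2]] <- 1
    s1 <- struct_el(m, s$origin)
    expect_true(all(erode(f, s1) <= f))
    expect_true(all(f <= dilate(f, s1)))
  }
})

test_that("opening removes small components, preserves large squares and is idempotent", {
  blob <- matrix(0, 40, 40); blob[6:35, 6:35] <- 1
  opened <- clean_mask(blob, se_square(22))
  expect_equal(sum(opened), 900)
  expect_equal(opened, blob)                     # position preserved

  small <- matrix(0, 30, 30); small[10:19, 10:19] <- 1
  expect_equal(sum(clean_mask(small, se_square(22))), 0)

  # thin skull-like ring around a large blob: ring removed, blob retained
  f <- matrix(0, 60, 60)
  f[5:6, 5:56] <- 1; f[55:56, 5:56] <- 1; f[5:56, 5:6] <- 1; f[5:56, 55:56] <- 1
  f[20:45, 20:45] <- 1
  s <- se_square(10)
  opened2 <- clean_mask(f, s)
  e <- oracle_erode(f, s)
  want <- oracle_dilate(e, reflect_se(s))
  expect_equal(opened2, want)
  expect_true(all(opened2[5:6, 10:50] == 0))     # ring gone
  expect_true(all(opened2[20:45, 20:45] == 1))   # blob intact

  set.seed(141)
  for (i in 1:5) {
    f <- random_binary(15, 15)
    s <- random_se(sample(2:3, 1), sample(2:3, 1))
    once <- clean_mask(f, s)
    expect_equal(clean_mask(once, s), once)
    expect_true(all(once %in% c(0, 1)))
  }
})

test_that("tumor area counts foreground pixels", {
  expect_equal(tumor_area(matrix(0, 5, 5)), 0)
  sq <- matrix(0, 40, 40); sq[6:35, 6:35] <- 1
  expect_equal(tumor_area(sq), 900)
  set.seed(151)
  f <- random_binary(9, 13)
  acc <- 0
  for (i in seq_len(nrow(f))) for (j in seq_len(ncol(f))) acc <- acc + f[i, j]
  expect_equal(tumor_area(f), acc)
})

test_that("structuring element constructor validates mask and origin", {
  expect_error(struct_el(matrix(0, 2, 2)), "at least one")
  expect_error(struct_el(matrix(1, 2, 2), c(3, 1)), "origin")
  s <- se_square(22)
  expect_identical(s$origin, c(12L, 12L))
  expect_identical(dim(s$mask), c(22L, 22L))
  r <- reflect_se(struct_el(matrix(c(1, 0, 1, 1), 2, 2), c(1, 2)))
  expect_identical(r$origin, c(2L, 1L))
})
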