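test_that("sign binarization maps zero to +1 and everything else by sign", {
  expect_identical(sign_binarize(0), 1)
  expect_identical(sign_binarize(-0.3), -1)
  expect_identical(sign_binarize(c(-2, 0, 5)), c(-1, 1, 1))
  m <- matrix(c(-1.5, 0, 2, -0.01), 2, 2)
  expect_identical(sign_binarize(m), matrix(c(-1, 1, 1, -1), 2, 2))
  expect_error(sign_binarize(c(1, NA)), "finite")
})

test_that("hard sigmoid is the clipped linear ramp", {
  expect_identical(hard_sigmoid(1), 1)
  expect_identical(hard_sigmoid(-1), 0)
  expect_identical(hard_sigmoid(0), 0.5)
  expect_identical(hard_sigmoid(c(-5, 5)), c(0, 1))
  x <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(hard_sigmoid(x), (x + 1) / 2)
})

test_that("stochastic binarization saturates, is seeded and unbiased at zero", {
  expect_true(all(stochastic_binarize(rep(3, 50), 1) == 1))
  expect_true(all(stochastic_binarize(rep(-3, 50), 1) == -1))
  x <- rnorm(20)
  expect_identical(stochastic_binarize(x, 7), stochastic_binarize(x, 7))
  draws <- stochastic_binarize(rep(0, 10000), 5)
  expect_true(all(draws %in% c(-1, 1)))
  expect_lt(abs(mean(draws)), 0.03)
})

test_that("convolution forward pass obeys the dimension formula and the loop oracle", {
  x <- matrix(runif(16), 4, 4)
  id <- conv_layer(array(1, c(1, 1, 1, 1)))
  expect_equal(conv_forward(x, id)[, , 1], x)

  big <- conv_layer(array(rnorm(3 * 3 * 1 * 8), c(3, 3, 1, 8)))
  expect_identical(dim(conv_forward(matrix(0, 64, 64), big)), c(62L, 62L, 8L))

  set.seed(201)
  for (i in 1:10) {
    d <- sample(1:2, 1)
    x <- array(rnorm(36 * d), c(6, 6, d))
    k <- array(rnorm(9 * d * 2), c(3, 3, d, 2))
    stride <- sample(1:2, 1); pad <- sample(0:1, 1)
    layer <- conv_layer(k, stride, pad)
    expect_equal(conv_forward(x, layer), oracle_conv(x, k, stride, pad),
                 tolerance = 1e-9)
  }
  expect_error(conv_forward(matrix(0, 2, 2),
                            conv_layer(array(1, c(3, 3, 1, 1)))), "larger")
  expect_error(conv_forward(array(0, c(4, 4, 2)), id), "depth")
})

test_that("max pooling keeps per-window maxima and the depth dimension", {
  expect_equal(maxpool(matrix(c(1, 3, 2, 4), 2, 2))[1, 1, 1], 4)
  x4 <- matrix(1:16, 4, 4)
  expect_identical(dim(maxpool(x4)), c(2L, 2L, 1L))
  set.seed(211)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  expect_equal(maxpool(x), oracle_maxpool(x))
  expect_equal(maxpool(x, 4, 4), oracle_maxpool(x, 4, 4))
  expect_error(maxpool(matrix(0, 3, 3), 4), "larger")
})

test_that("min-max normalization centers by the mean and scales by the range", {
  r <- minmax_normalize(matrix(c(0, 10, 0, 10), 2, 2))
  expect_equal(sort(unique(as.vector(r$values))), c(-0.5, 0.5))
  cst <- minmax_normalize(matrix(5, 3, 3))
  expect_true(all(cst$values == 0))
  set.seed(221)
  x <- array(rnorm(4 * 4 * 3, sd = 10), c(4, 4, 3))
  out <- minmax_normalize(x)$values
  expect_true(all(out >= -1 & out <= 1))
  out01 <- minmax_normalize(x, variant = "minmax01")$values
  expect_true(all(out01 >= 0 & out01 <= 1))

  # running state blends with momentum 0.9 and drives inference mode
  s1 <- minmax_normalize(x)$state
  x2 <- x + 2
  s2 <- minmax_normalize(x2, state = s1)$state
  expect_equal(s2$m, 0.9 * s1$m + 0.1 * (s1$m + 2))
  inf <- minmax_normalize(x, state = s2, mode = "running")
  expect_identical(inf$state$m, s2$m)
  expect_error(minmax_normalize(x, mode = "running"), "requires a state")
})

test_that("fully connected layer computes g(wx + b)", {
  id <- fc_layer(diag(3))
  expect_equal(fc_forward(c(1, -2, 3), id), c(1, -2, 3))
  lr <- fc_layer(matrix(c(1, 0, 0, 1), 2, 2), b = c(-3, 1), activation = relu)
  expect_equal(fc_forward(c(1, 2), lr), c(0, 3))
  set.seed(231)
  w <- matrix(rnorm(6), 3, 2); b <- rnorm(3); x <- rnorm(2)
  want <- numeric(3)
  for (i in 1:3) want[i] <- w[i, 1] * x[1] + w[i, 2] * x[2] + b[i]
  expect_equal(fc_forward(x, fc_layer(w, b)), want)
  expect_error(fc_forward(c(1, 2, 3), lr), "mismatch")
})

test_that("softmax yields a probability simplex point with lowest-index ties", {
  eq <- softmax_predict(rep(0, 5))
  expect_equal(eq$probabilities, rep(0.2, 5))
  expect_identical(eq$class, 1L)
  two <- softmax_predict(c(0, log(3)))
  expect_equal(two$probabilities, c(0.25, 0.75))
  expect_identical(two$class, 2L)
  set.seed(241)
  for (i in 1:20) {
    p <- softmax_predict(rnorm(7, sd = 20))$probabilities
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
  }
  # large logits remain stable
  expect_equal(sum(softmax_predict(c(1000, 1001, 999))$probabilities), 1)
})
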