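# Reference numerical primitives: dilated convolution, batch normalization,
# leakyReLU, weighted cross-entropy, SGD with momentum.

test_that("atrous convolution handles identity, zero and 1-D reduction cases", {
  x <- array(rnorm(5 * 6 * 3), c(5, 6, 3))

  # 1x1 identity kernel passes the input through for any dilation rate
  id <- array(0, c(1, 1, 3, 3))
  for (c in 1:3) id[1, 1, c, c] <- 1
  for (r in c(1L, 3L))
    expect_equal(atrous_convolve(x, conv_kernel(id, dilation = r)), x)

  # all-zero input with zero bias stays zero
  k <- conv_kernel(array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4)), dilation = 2)
  expect_equal(atrous_convolve(array(0, c(7, 7, 2)), k),
               array(0, c(7, 7, 4)))

  # row [1..5], kernel [1,1,1], rate 2, no padding: single tap 1 + 3 + 5
  k3 <- conv_kernel(array(1, c(1, 3, 1, 1)), dilation = 2)
  out <- atrous_convolve(array(1:5, c(1, 5, 1)), k3, padding = "valid")
  expect_equal(dim(out), c(1L, 1L, 1L))
  expect_equal(out[1, 1, 1], 9)
})

test_that("atrous convolution rejects channel mismatch and bad rates", {
  k <- conv_kernel(array(1, c(3, 3, 2, 1)))
  expect_error(atrous_convolve(array(0, c(4, 4, 3)), k), "channel mismatch")
  expect_error(conv_kernel(array(1, c(3, 3, 1, 1)), dilation = 0),
               "positive integer")
  expect_error(conv_kernel(array(1, c(2, 2, 1, 1))), "odd")
})

test_that("rate-1 atrous convolution matches the brute-force standard convolution", {
  set.seed(11)
  for (case in 1:6) {
    x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
    w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
    b <- rnorm(3)
    got <- atrous_convolve(x, conv_kernel(w, b, dilation = 1))
    expect_equal(got, brute_conv(x, w, b, r = 1), tolerance = 1e-9)
  }
})

test_that("dilated convolution equals standard convolution with a zero-inflated kernel", {
  set.seed(12)
  for (r in 2:4) {
    x <- array(rnorm(15 * 14 * 2), c(15, 14, 2))
    w <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
    got <- atrous_convolve(x, conv_kernel(w, dilation = r))
    via_inflated <- atrous_convolve(x, conv_kernel(inflate_kernel(w, r),
                                                   dilation = 1))
    expect_equal(got, via_inflated, tolerance = 1e-9)
  }
})

test_that("batch normalization matches the hand formulas and degenerate cases", {
  # constant batch: zero variance, epsilon guards the division
  out <- batch_normalize(list(array(3, c(2, 2)), array(3, c(2, 2))))
  expect_true(all(abs(unlist(out)) < 1e-6))

  # {1, 2, 3} in one channel -> approximately {-1.2247, 0, 1.2247}
  out <- batch_normalize(list(1, 2, 3))
  expect_equal(unlist(out), c(-1.224699, 0, 1.224699), tolerance = 1e-4)
  expect_equal(unlist(out), bn_oracle(c(1, 2, 3)), tolerance = 1e-12)

  # default epsilon is 5e-5
  expect_equal(batch_norm_state()$epsilon, 5e-5)
  expect_error(batch_normalize(list()), "non-empty")
})

test_that("normalized output has near-zero mean and near-unit variance per channel", {
  set.seed(13)
  batch <- lapply(1:4, function(i) array(rnorm(6 * 5 * 3, mean = 5, sd = 3),
                                         c(6, 5, 3)))
  out <- batch_normalize(batch)
  for (c in 1:3) {
    vals <- unlist(lapply(out, function(a) a[, , c]))
    expect_lt(abs(mean(vals)), 1e-6)
    v <- mean((vals - mean(vals))^2)
    expect_gt(v, 1 - 1e-3)
    expect_lte(v, 1)
  }
  # gamma/beta rescale and shift
  st <- batch_norm_state(scale = 2, offset = -1)
  out2 <- batch_normalize(batch, st)
  expect_equal(out2[[1]], out[[1]] * 2 - 1, tolerance = 1e-12)
})

test_that("leakyReLU follows the two-branch definition", {
  expect_equal(leaky_relu(0), 0)
  expect_equal(leaky_relu(-2, slope = 0.1), -0.2)
  x <- c(-3, -0.5, 0, 0.5, 3)
  expect_equal(leaky_relu(x, 0.1), c(-0.3, -0.05, 0, 0.5, 3))
  expect_error(leaky_relu(x, slope = 1.5), "in \\(0, 1\\)")
})

test_that("weighted cross-entropy matches hand evaluation and edge cases", {
  # perfect prediction -> 0
  expect_equal(weighted_cross_entropy(c(1, 0), c(1, 0)), 0)
  # all-zero weights -> 0
  expect_equal(weighted_cross_entropy(c(0.3, 0.7), c(1, 0), weights = c(0, 0)), 0)
  # N=1, K=2, uniform weights, P=(0.5,0.5), T=(1,0): -log 0.5
  expect_equal(weighted_cross_entropy(c(0.5, 0.5), c(1, 0)), log(2),
               tolerance = 1e-12)
  # weights scale per-class contributions
  p <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  t <- rbind(c(1, 0), c(0, 1))
  expect_equal(weighted_cross_entropy(p, t, weights = c(2, 1)),
               (2 * -log(0.8) + 1 * -log(0.7)) / 2, tolerance = 1e-12)
  # probability 0 at the true class is clamped, not infinite
  expect_true(is.finite(weighted_cross_entropy(c(0, 1), c(1, 0))))
})

test_that("weighted cross-entropy decreases as the true-class probability rises", {
  ps <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(ps, function(p)
    weighted_cross_entropy(c(p, 1 - p), c(1, 0)), 0)
  expect_true(all(diff(losses) < 0))
})

test_that("SGDM step matches hand evaluation and reduces to plain gradient descent", {
  # zero gradient, zero velocity, zero l2: fixed point
  st <- optimizer_state(0.01, 0.9, l2 = 0)
  out <- sgdm_step(c(1, -2), c(0, 0), st)
  expect_equal(out$params, c(1, -2))

  # theta=1, grad=0.5, lr=0.01, momentum=0, l2=0 -> 0.995
  out <- sgdm_step(1, 0.5, optimizer_state(0.01, 0, l2 = 0))
  expect_equal(out$params, 0.995, tolerance = 1e-12)

  # momentum accumulates velocity across steps
  st <- optimizer_state(0.1, 0.5, l2 = 0)
  s1 <- sgdm_step(0, 1, st)                    # v = -0.1
  s2 <- sgdm_step(s1$params, 1, s1$state)      # v = -0.15
  expect_equal(s2$params, -0.25, tolerance = 1e-12)

  # L2 adds l2 * theta to the gradient
  out <- sgdm_step(2, 0, optimizer_state(0.1, 0, l2 = 0.5))
  expect_equal(out$params, 2 - 0.1 * (0.5 * 2), tolerance = 1e-12)

  expect_error(sgdm_step(c(1, 2), 1), "same length")
})

test_that("repeated SGDM steps converge on a 1-D quadratic below the stability bound", {
  # f(x) = 0.5 * c * x^2, gradient c*x; plain GD stable for lr < 2/c
  cc <- 4
  for (mom in c(0, 0.9)) {
    st <- optimizer_state(learning_rate = 0.1, momentum = mom, l2 = 0)
    x <- 5
    for (i in 1:400) {
      out <- sgdm_step(x, cc * x, st)
      x <- out$params; st <- out$state
    }
    expect_lt(abs(x), 1e-6)
  }
})
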