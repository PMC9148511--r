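# The runnable model: construction, forward-pass contracts, agreement with
# the reference primitives, translation covariance, gradient correctness.

test_that("construction fails on an inconsistent channel chain", {
  spec <- tiny_spec()
  spec$layers$in_channels[2] <- 99L
  expect_error(build_network(spec), "channel chain")
})

test_that("softmax outputs are probabilities at every pixel and deterministic", {
  net <- build_network(tiny_spec(c(10L, 12L, 2L)), seed = 5)
  set.seed(1)
  img <- array(runif(10 * 12 * 2), c(10, 12, 2))
  p1 <- forward_probs(net, img)[[1]]
  expect_equal(dim(p1), c(10L, 12L, 2L))
  expect_true(all(abs(p1[, , 1] + p1[, , 2] - 1) < 1e-6))
  expect_true(all(p1 >= 0 & p1 <= 1))
  # same seed at construction -> identical weights -> identical output
  net2 <- build_network(tiny_spec(c(10L, 12L, 2L)), seed = 5)
  expect_identical(forward_probs(net2, img)[[1]], p1)
})

test_that("the accelerated forward pass agrees with composing the reference primitives", {
  # full 16-layer architecture at a reduced working resolution, random
  # weights and non-trivial batch-norm statistics
  net <- build_network(dilatedskinnet_spec(), input_size = c(16L, 20L),
                       seed = 7)
  for (i in seq_along(net$layers)) {
    if (!net$layers[[i]]$bn) next
    cout <- net$layers[[i]]$cout
    net$layers[[i]]$gamma <- runif(cout, 0.5, 1.5)
    net$layers[[i]]$beta <- rnorm(cout, sd = 0.2)
    net$layers[[i]]$run_mean <- rnorm(cout, sd = 0.2)
    net$layers[[i]]$run_var <- runif(cout, 0.5, 2)
  }
  img <- array(runif(16 * 20 * 3), c(16, 20, 3))
  fast <- forward_probs(net, img)[[1]]
  ref <- dilatedskinnet:::reference_forward(net, img)
  expect_equal(fast, ref, tolerance = 1e-4)
  expect_lt(max(abs(fast - ref)), 1e-8)
})

test_that("pre-softmax output is translation covariant away from the border", {
  # full architecture at full working resolution; shift the content of a
  # constant-background image and compare interior logits
  net <- build_network(dilatedskinnet_spec(), seed = 11)
  H <- 192L; W <- 256L
  set.seed(21)
  base <- array(0.5, c(H, W, 3))
  patch <- array(runif(24 * 24 * 3), c(24, 24, 3))
  img1 <- base; img1[85:108, 117:140, ] <- patch
  dy <- 2L; dx <- 3L
  img2 <- base; img2[(85 + dy):(108 + dy), (117 + dx):(140 + dx), ] <- patch
  logits <- function(img) {
    X <- dilatedskinnet:::stack_images(list(img))
    dilatedskinnet:::nn_forward(net, X, H, W, 1L)$logits
  }
  z1 <- array(logits(img1), c(H, W, 2))
  z2 <- array(logits(img2), c(H, W, 2))
  # interior pixels whose receptive field stays inside the image under both
  # placements (RF 179 -> margin 89 + shift)
  rows <- 92:100; cols <- 95:160
  expect_equal(z2[rows + dy, cols + dx, ], z1[rows, cols, ],
               tolerance = 1e-4)
})

test_that("backpropagation matches finite differences on a tiny network", {
  spec <- tiny_spec()
  net <- build_network(spec, seed = 3)
  H <- 6L; W <- 7L; N <- 2L
  set.seed(9)
  X <- matrix(rnorm(H * W * N * 2), H * W * N, 2)
  tgt <- rbinom(H * W * N, 1, 0.5)
  wc <- c(0.8, 1.2)
  lossfun <- function(net) {
    fw <- dilatedskinnet:::nn_forward(net, X, H, W, N, training = TRUE)
    dilatedskinnet:::softmax_wce_grad(fw$logits, as.integer(tgt), wc,
                                      1e-12)$loss
  }
  fw <- dilatedskinnet:::nn_forward(net, X, H, W, N, training = TRUE,
                                    keep_cache = TRUE)
  sg <- dilatedskinnet:::softmax_wce_grad(fw$logits, as.integer(tgt), wc,
                                          1e-12)
  bw <- dilatedskinnet:::nn_backward(net, fw$cache, sg$grad, H, W, N,
                                     want_input_grad = TRUE)
  eps <- 1e-6
  for (i in seq_along(net$layers)) {
    for (fld in c("W", "b", "gamma", "beta")) {
      if (is.null(net$layers[[i]][[fld]])) next
      g <- switch(fld, W = bw$grads[[i]]$dW, b = bw$grads[[i]]$db,
                  gamma = bw$grads[[i]]$dgamma, beta = bw$grads[[i]]$dbeta)
      for (j in sample(length(net$layers[[i]][[fld]]),
                       min(4L, length(net$layers[[i]][[fld]])))) {
        np <- net; np$layers[[i]][[fld]][j] <- np$layers[[i]][[fld]][j] + eps
        nm <- net; nm$layers[[i]][[fld]][j] <- nm$layers[[i]][[fld]][j] - eps
        fd <- (lossfun(np) - lossfun(nm)) / (2 * eps)
        expect_equal(g[j], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("the weighted-CE gradient used in training matches the reference loss", {
  set.seed(31)
  Z <- matrix(rnorm(40), 20, 2)
  tgt <- rbinom(20, 1, 0.4)
  w <- c(0.7, 1.6)
  sg <- dilatedskinnet:::softmax_wce_grad(Z, as.integer(tgt), w, 1e-12)
  P <- dilatedskinnet:::softmax_rows(Z)
  Tm <- cbind(1 - tgt, tgt)
  expect_equal(sg$loss, weighted_cross_entropy(P, Tm, w), tolerance = 1e-12)
})

test_that("empirical receptive field matches the analytic value on small stacks", {
  layers <- data.frame(
    name = c("c1", "c2", "f"), block = c(1L, 1L, 2L),
    kernel = c(3L, 3L, 1L), out_channels = c(3L, 3L, 2L),
    dilation = c(2L, 3L, NA_integer_),
    batch_norm = c(TRUE, TRUE, FALSE), activation = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  spec <- network_spec(layers, input_shape = c(40L, 40L, 1L))
  net <- build_network(spec, seed = 2)
  # RF = 1 + 2*2 + 2*3 = 11
  expect_equal(unname(receptive_field(spec)), c(11L, 11L))
  expect_equal(unname(empirical_receptive_field(net, c(40L, 40L), seed = 4)),
               c(11L, 11L))
})
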