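# Runnable network: weight initialization, and the accelerated forward /
# backward pass. Mini-batch activations are stored as dense matrices with
# one row per pixel (height-fastest, then width, then batch member) and one
# column per channel; dilated convolution is im2col (compiled gather) +
# BLAS matrix multiply. Agreement with the reference tap-summation
# semantics in core-ops is part of the test contract.

LEAKY_SLOPE <- 0.1
BN_EPS <- 5e-5
BN_MOMENTUM <- 0.9   # running-statistics update factor

#' Build a runnable network from a specification
#'
#' Initializes convolution weights with leakyReLU-aware variance scaling
#' (`sd = sqrt(2 / ((1 + a^2) * fan_in))`, fan-in `k^2 * C_in`), zero
#' biases, unit batch-norm scale and zero offset, and unit/zero running
#' variance/mean. The network is fully convolutional, so `input_size` fixes
#' only the nominal working resolution (used for batching and reported
#' shapes); the forward pass accepts any spatial size.
#'
#' @param spec a [network_spec()], typically [dilatedskinnet_spec()].
#' @param input_size integer `(height, width)`; defaults to the spec's
#'   input shape.
#' @param seed optional integer seed fixing the initial weights.
#' @return object of class `dilated_net`.
#' @export
build_network <- function(spec = dilatedskinnet_spec(),
                          input_size = spec$input_shape[1:2],
                          seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  L <- spec$layers
  if (any(L$in_channels != c(spec$input_shape[3], L$out_channels[-nrow(L)])))
    stop("inconsistent channel chain in network specification")
  if (!is.null(seed)) set.seed(seed)
  layers <- vector("list", nrow(L))
  for (i in seq_len(nrow(L))) {
    k <- L$kernel[i]; cin <- L$in_channels[i]; cout <- L$out_channels[i]
    fan_in <- k * k * cin
    sd <- sqrt(2 / ((1 + LEAKY_SLOPE^2) * fan_in))
    layers[[i]] <- list(
      name = L$name[i], k = k, r = max(1L, L$dilation[i], na.rm = TRUE),
      cin = cin, cout = cout,
      bn = L$batch_norm[i], act = L$activation[i],
      W = matrix(rnorm(fan_in * cout, sd = sd), fan_in, cout),
      b = numeric(cout),
      gamma = if (L$batch_norm[i]) rep(1, cout) else NULL,
      beta = if (L$batch_norm[i]) rep(0, cout) else NULL,
      run_mean = if (L$batch_norm[i]) rep(0, cout) else NULL,
      run_var = if (L$batch_norm[i]) rep(1, cout) else NULL
    )
  }
  structure(list(spec = spec, input_size = as.integer(input_size),
                 layers = layers, slope = LEAKY_SLOPE, eps = BN_EPS,
                 seed = seed),
            class = "dilated_net")
}

#' @export
print.dilated_net <- function(x, ...) {
  p <- count_parameters(x$spec)
  cat("dilated_net:", length(x$layers), "conv layers,",
      p$total, "learnable parameters, nominal input",
      paste(x$input_size, collapse = "x"), "\n")
  invisible(x)
}

# ---- fast conv primitives ---------------------------------------------------

conv_fwd_fast <- function(X, H, W, N, layer) {
  if (layer$k == 1L) {
    Y <- X %*% layer$W
  } else {
    P <- im2col_dilated(X, H, W, N, layer$k, layer$r)
    Y <- P %*% layer$W
  }
  if (any(layer$b != 0)) Y <- sweep(Y, 2L, layer$b, "+")
  Y
}

# ---- forward / backward -----------------------------------------------------

# X: (H*W*N) x C_in matrix. Returns logits and, if keep_cache, the per-layer
# intermediates needed for backprop (including the im2col patch matrix,
# which backprop reuses for the weight gradient). training = TRUE uses
# mini-batch BN statistics (and updates running stats in the returned
# $layers).
nn_forward <- function(net, X, H, W, N, training = FALSE,
                       keep_cache = FALSE) {
  layers <- net$layers
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  A <- X
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$k == 1L) {
      P <- A
    } else {
      P <- im2col_dilated(A, H, W, N, ly$k, ly$r)
    }
    Z <- P %*% ly$W
    if (any(ly$b != 0)) Z <- affine_cols(Z, rep(1, ly$cout), ly$b)
    st <- NULL
    if (ly$bn) {
      if (training) {
        mv <- col_mean_var(Z)
        mu <- mv$mean
        v <- mv$var
        layers[[i]]$run_mean <- BN_MOMENTUM * ly$run_mean + (1 - BN_MOMENTUM) * mu
        layers[[i]]$run_var <- BN_MOMENTUM * ly$run_var + (1 - BN_MOMENTUM) * v
      } else {
        mu <- ly$run_mean
        v <- ly$run_var
      }
      Y <- bn_act_forward(Z, mu, v, net$eps, ly$gamma, ly$beta,
                          net$slope, ly$act)
      st <- list(Z = Z, mu = mu, var = v, batch_stats = training)
    } else if (ly$act) {
      Y <- leaky_forward(Z, net$slope)
      st <- list(A_out = Y)
    } else {
      Y <- Z
    }
    if (keep_cache) {
      # keep the im2col patch matrix for backprop reuse only while small;
      # large ones (high resolution x wide layers) are cheaper to rebuild
      # than to hold across the whole backward pass
      st$P <- if (ly$k == 1L || length(P) > 2^23) NULL else P
      st$X_in <- A
      cache[[i]] <- st
    }
    A <- Y
  }
  list(logits = A, cache = cache, layers = layers)
}

# dLogits: gradient of the loss wrt the final-layer output.
# Returns per-layer parameter gradients and optionally the input gradient.
nn_backward <- function(net, cache, dLogits, H, W, N,
                        want_input_grad = FALSE) {
  layers <- net$layers
  grads <- vector("list", length(layers))
  dY <- dLogits
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    st <- cache[[i]]
    g <- list()
    if (ly$bn) {
      # fused leakyReLU + batch-norm backward; with fixed running
      # statistics batch norm is a plain per-channel affine, with
      # mini-batch statistics the mean/variance terms couple all pixels
      bb <- bn_act_backward(dY, st$Z, st$mu, st$var, net$eps, ly$gamma,
                            ly$beta, net$slope, ly$act, st$batch_stats)
      g$dgamma <- bb$dgamma
      g$dbeta <- bb$dbeta
      dZ <- bb$dZ
    } else if (ly$act) {
      dZ <- leaky_backward(dY, st$A_out, net$slope)
    } else {
      dZ <- dY
    }
    P <- if (ly$k == 1L) st$X_in else
      st$P %||% im2col_dilated(st$X_in, H, W, N, ly$k, ly$r)
    g$dW <- crossprod(P, dZ)
    g$db <- colSums(dZ)
    grads[[i]] <- g
    if (i > 1L || want_input_grad) {
      dP <- dZ %*% t(ly$W)
      dY <- if (ly$k == 1L) dP else
        col2im_dilated(dP, H, W, N, ly$cin, ly$k, ly$r)
    }
  }
  list(grads = grads, dX = if (want_input_grad) dY else NULL)
}

# softmax over the channel (column) axis, numerically stabilized
softmax_rows <- function(Z) softmax_mat(Z)

# Stack a list of H x W x C image arrays into the (H*W*N) x C batch matrix.
stack_images <- function(images) {
  do.call(rbind, lapply(images, function(img) {
    d <- dim(img)
    matrix(as.numeric(img), d[1] * d[2], d[3])
  }))
}

#' Forward pass: per-pixel class probabilities
#'
#' Runs a batch of images through the network and returns softmax
#' probabilities over the two classes (channel 1 background, channel 2
#' lesion) at every pixel.
#'
#' @param net a `dilated_net` from [build_network()].
#' @param images list of `H x W x 3` arrays (all the same size), or a single
#'   array.
#' @param training logical; use mini-batch statistics (TRUE) or running
#'   statistics (FALSE) in batch normalization.
#' @return list of `H x W x 2` probability arrays, one per image.
#' @export
forward_probs <- function(net, images, training = FALSE) {
  if (!is.list(images)) images <- list(images)
  d <- dim(images[[1]])
  H <- d[1]; W <- d[2]; N <- length(images)
  X <- stack_images(images)
  fw <- nn_forward(net, X, H, W, N, training = training)
  P <- softmax_rows(fw$logits)
  lapply(seq_len(N), function(n) {
    rows <- (n - 1L) * H * W + seq_len(H * W)
    array(P[rows, ], c(H, W, ncol(P)))
  })
}

# ---- reference-path forward (core_ops composition) --------------------------

# Compose the reference primitives layer-by-layer; used in tests to check
# that the accelerated path agrees with the tap-summation semantics.
reference_forward <- function(net, image) {
  x <- as_feature_map(image)
  for (ly in net$layers) {
    kern <- conv_kernel(array(ly$W, c(ly$k, ly$k, ly$cin, ly$cout)),
                        bias = ly$b, dilation = ly$r)
    x <- atrous_convolve(x, kern, padding = "same")
    if (ly$bn) {
      st <- batch_norm_state(scale = ly$gamma, offset = ly$beta,
                             epsilon = net$eps,
                             mean = ly$run_mean, variance = ly$run_var)
      x <- batch_normalize(list(x), st)[[1]]
    }
    if (ly$act) x <- leaky_relu(x, net$slope)
  }
  # pixelwise softmax over the channel axis
  m <- pmax(x[, , 1], x[, , 2])
  e1 <- exp(x[, , 1] - m); e2 <- exp(x[, , 2] - m)
  s <- e1 + e2
  array(c(e1 / s, e2 / s), dim(x))
}

# ---- empirical receptive field ----------------------------------------------

#' Gradient-support receptive field
#'
#' Measures the receptive field empirically: backpropagates a one-hot
#' gradient from a single center output pixel through the network on a
#' random input and reports the bounding box of the nonzero input gradient.
#' This is the oracle counterpart of the analytic [receptive_field()].
#'
#' @param net a `dilated_net`; the input must be large enough to contain the
#'   receptive field (the nominal 192x256 is sufficient for the published
#'   stack).
#' @param input_size integer `(height, width)`; defaults to the network's
#'   nominal size.
#' @param seed integer seed for the random probe input.
#' @return integer vector `c(height, width)` of the gradient-support
#'   bounding box.
#' @export
empirical_receptive_field <- function(net, input_size = net$input_size,
                                      seed = 1L) {
  H <- input_size[1]; W <- input_size[2]
  set.seed(seed)
  cin <- net$layers[[1]]$cin
  X <- matrix(rnorm(H * W * cin), H * W, cin)
  fw <- nn_forward(net, X, H, W, 1L, training = FALSE, keep_cache = TRUE)
  cout <- ncol(fw$logits)
  ctr_h <- (H + 1L) %/% 2L; ctr_w <- (W + 1L) %/% 2L
  dL <- matrix(0, H * W, cout)
  dL[ctr_h + H * (ctr_w - 1L), 1L] <- 1
  bw <- nn_backward(net, fw$cache, dL, H, W, 1L, want_input_grad = TRUE)
  g <- matrix(rowSums(abs(bw$dX)) > 0, H, W)
  rows <- which(rowSums(g) > 0)
  cols <- which(colSums(g) > 0)
  c(height = diff(range(rows)) + 1L, width = diff(range(cols)) + 1L)
}
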