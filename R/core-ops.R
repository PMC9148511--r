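#' @useDynLib dilatedskinnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
NULL

# ---- constructors -----------------------------------------------------------

#' Convolution kernel set
#'
#' Bundles a rank-4 weight array (`k_h x k_w x C_in x C_out`), a per-output-
#' channel bias vector and an atrous dilation rate into a kernel object for
#' [atrous_convolve()]. Rank-2 (`k_h x k_w`) and rank-3 (`k_h x k_w x C_in`)
#' weight arrays are promoted to rank 4 with singleton channel dimensions.
#'
#' @param weights numeric array of kernel weights; both spatial dimensions
#'   must be odd.
#' @param bias numeric vector of length `C_out` (default all zero).
#' @param dilation positive integer tap spacing `r`; a rate of 1 is
#'   standard convolution.
#' @return an object of class `conv_kernel`.
#' @export
#' @examples
#' k <- conv_kernel(array(1, c(3, 3, 1, 1)), dilation = 2)
conv_kernel <- function(weights, bias = NULL, dilation = 1L) {
  d <- dim(weights)
  if (is.null(d)) d <- c(1L, length(weights))
  if (length(d) == 2L) d <- c(d, 1L, 1L)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop("kernel weights must have rank 2, 3 or 4")
  weights <- array(as.numeric(weights), d)
  if (d[1] %% 2L == 0L || d[2] %% 2L == 0L)
    stop("kernel spatial dimensions must be odd (got ", d[1], "x", d[2], ")")
  dilation <- as.integer(dilation)
  if (is.na(dilation) || dilation < 1L)
    stop("dilation rate must be a positive integer")
  if (is.null(bias)) bias <- numeric(d[4])
  if (length(bias) != d[4])
    stop("bias must have length C_out = ", d[4])
  if (!all(is.finite(weights)) || !all(is.finite(bias)))
    stop("kernel weights and bias must be finite")
  structure(list(weights = weights, bias = as.numeric(bias),
                 dilation_rate = dilation),
            class = "conv_kernel")
}

#' Batch-normalization state
#'
#' Holds the learned per-channel scale (gamma) and offset (beta), the
#' variance-smoothing constant epsilon, and optionally fixed per-channel
#' statistics. When `mean`/`variance` are `NULL`, [batch_normalize()]
#' computes them from the mini-batch; when supplied (e.g. running statistics
#' at inference time) they are used as-is.
#'
#' @param scale per-channel multiplier gamma (recycled across channels).
#' @param offset per-channel offset beta.
#' @param epsilon small positive smoothing constant added to the variance
#'   before the square root; default `5e-5`.
#' @param mean,variance optional fixed per-channel statistics.
#' @return an object of class `batch_norm_state`.
#' @export
batch_norm_state <- function(scale = 1, offset = 0, epsilon = 5e-5,
                             mean = NULL, variance = NULL) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive scalar")
  if (!is.null(variance) && any(variance < 0))
    stop("variance entries must be nonnegative")
  structure(list(scale = as.numeric(scale), offset = as.numeric(offset),
                 epsilon = epsilon,
                 batch_mean = if (is.null(mean)) NULL else as.numeric(mean),
                 batch_variance = if (is.null(variance)) NULL else as.numeric(variance)),
            class = "batch_norm_state")
}

#' Optimizer state for SGD with momentum
#'
#' @param learning_rate positive step size alpha; default 0.01.
#' @param momentum momentum coefficient in `[0, 1)`; default 0.9.
#' @param l2 L2 (weight-decay) coefficient added to the gradient as
#'   `l2 * theta`; default 0.005.
#' @param velocity optional accumulator shaped like the parameters
#'   (initialized to zero on first use).
#' @return an object of class `optimizer_state`.
#' @export
optimizer_state <- function(learning_rate = 0.01, momentum = 0.9,
                            l2 = 0.005, velocity = NULL) {
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop("learning_rate must be positive")
  if (!is.numeric(momentum) || momentum < 0 || momentum >= 1)
    stop("momentum must lie in [0, 1)")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 l2 = l2, velocity = velocity),
            class = "optimizer_state")
}

# ---- atrous convolution -----------------------------------------------------

as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- c(1L, length(x))
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) != 3L) stop("feature map must have rank 2 or 3")
  if (any(d < 1L)) stop("feature map dimensions must be >= 1")
  if (!all(is.finite(x))) stop("feature map must contain finite values only")
  array(as.numeric(x), d)
}

#' Atrous (dilated) convolution, reference semantics
#'
#' Direct tap-summation implementation of dilated 2-D convolution: each
#' output value is the sum over kernel taps placed at offsets spaced
#' `dilation` pixels apart, plus the bias. With `dilation = 1` this is the
#' standard convolution. The implementation enumerates taps explicitly and is
#' intended as the reference semantics (and test oracle) for the accelerated
#' im2col path used inside the network.
#'
#' @param input a feature map: numeric array `H x W x C_in` (a matrix is
#'   treated as one channel).
#' @param kernel a [conv_kernel()] whose `C_in` matches the input channels.
#' @param padding `"same"` (zero-pad so output spatial size equals input) or
#'   `"valid"` (no padding; output shrinks by the effective kernel extent).
#' @return numeric array `H_out x W_out x C_out`.
#' @export
#' @examples
#' x <- array(1:25, c(5, 5, 1))
#' k <- conv_kernel(array(1/9, c(3, 3, 1, 1)))
#' dim(atrous_convolve(x, k))
atrous_convolve <- function(input, kernel, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  x <- as_feature_map(input)
  if (!inherits(kernel, "conv_kernel")) stop("kernel must be a conv_kernel")
  dw <- dim(kernel$weights)
  kh <- dw[1]; kw <- dw[2]; cin <- dw[3]; cout <- dw[4]
  r <- kernel$dilation_rate
  if (dim(x)[3] != cin)
    stop("channel mismatch: input has ", dim(x)[3], " channels, kernel expects ", cin)
  keff_h <- kh + (kh - 1L) * (r - 1L)
  keff_w <- kw + (kw - 1L) * (r - 1L)
  if (padding == "same") {
    ph <- (keff_h - 1L) %/% 2L
    pw <- (keff_w - 1L) %/% 2L
    xp <- array(0, c(dim(x)[1] + 2L * ph, dim(x)[2] + 2L * pw, cin))
    xp[ph + seq_len(dim(x)[1]), pw + seq_len(dim(x)[2]), ] <- x
    x <- xp
  }
  ho <- dim(x)[1] - (keff_h - 1L)
  wo <- dim(x)[2] - (keff_w - 1L)
  if (ho < 1L || wo < 1L)
    stop("input too small for the effective kernel extent under valid padding")
  out <- array(0, c(ho, wo, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(kernel$bias[co], ho, wo)
    for (ci in seq_len(cin)) {
      for (kj in seq_len(kw)) {
        for (ki in seq_len(kh)) {
          w <- kernel$weights[ki, kj, ci, co]
          if (w == 0) next
          acc <- acc + w * x[(ki - 1L) * r + seq_len(ho),
                             (kj - 1L) * r + seq_len(wo), ci]
        }
      }
    }
    out[, , co] <- acc
  }
  out
}

# ---- batch normalization ----------------------------------------------------

#' Batch normalization, reference semantics
#'
#' Standardizes each channel over all pixels of all batch members
#' (`xhat = (x - mu_B) / sqrt(sigma2_B + eps)`, population variance), then
#' applies the learned affine map `gamma * xhat + beta`. If the state carries
#' fixed `batch_mean`/`batch_variance` they are used instead of the computed
#' mini-batch statistics (inference mode).
#'
#' @param batch a non-empty list of numeric arrays of identical shape; the
#'   last dimension of a rank-3 array is taken as the channel axis, any other
#'   shape is treated as a single channel.
#' @param state a [batch_norm_state()].
#' @return a list of normalized arrays shaped like the input, with the
#'   per-channel statistics used attached as attributes `batch_mean` and
#'   `batch_variance`.
#' @export
batch_normalize <- function(batch, state = batch_norm_state()) {
  if (!is.list(batch)) batch <- list(batch)
  if (length(batch) == 0L) stop("batch must be non-empty")
  shapes <- lapply(batch, function(b) dim(b) %||% length(b))
  if (length(unique(vapply(shapes, paste, "", collapse = "x"))) != 1L)
    stop("all batch members must have the same shape")
  d <- dim(batch[[1]])
  nchan <- if (!is.null(d) && length(d) == 3L) d[3] else 1L
  # per-channel values across the whole batch
  chan_values <- function(c) {
    unlist(lapply(batch, function(b) {
      if (nchan == 1L) as.numeric(b) else as.numeric(b[, , c])
    }), use.names = FALSE)
  }
  gamma <- rep_len(state$scale, nchan)
  beta <- rep_len(state$offset, nchan)
  mu <- state$batch_mean
  v <- state$batch_variance
  if (is.null(mu) || is.null(v)) {
    mu <- numeric(nchan); v <- numeric(nchan)
    for (c in seq_len(nchan)) {
      xc <- chan_values(c)
      mu[c] <- mean(xc)
      v[c] <- mean((xc - mu[c])^2)
    }
  } else {
    mu <- rep_len(mu, nchan); v <- rep_len(v, nchan)
  }
  inv_sd <- 1 / sqrt(v + state$epsilon)
  out <- lapply(batch, function(b) {
    y <- b
    if (nchan == 1L) {
      y[] <- gamma[1] * (as.numeric(b) - mu[1]) * inv_sd[1] + beta[1]
    } else {
      for (c in seq_len(nchan))
        y[, , c] <- gamma[c] * (b[, , c] - mu[c]) * inv_sd[c] + beta[c]
    }
    y
  })
  attr(out, "batch_mean") <- mu
  attr(out, "batch_variance") <- v
  out
}

# ---- activation -------------------------------------------------------------

#' Leaky rectified linear activation
#'
#' Elementwise `x` for `x >= 0`, `slope * x` otherwise. The network uses
#' slope 0.1.
#'
#' @param x numeric array.
#' @param slope scalar `a` in `(0, 1)`; default 0.1.
#' @return array shaped like `x`.
#' @export
leaky_relu <- function(x, slope = 0.1) {
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0 || slope >= 1)
    stop("slope must be a scalar in (0, 1)")
  y <- x
  neg <- x < 0
  y[neg] <- slope * x[neg]
  y
}

# ---- loss -------------------------------------------------------------------

PROB_CLAMP <- 1e-12

#' Weighted cross-entropy loss
#'
#' `Loss = (1/N) * sum_n sum_i w_i * T_ni * (-log P_ni)` over N observations
#' (pixels) and K classes: nonnegative, and zero exactly when every true
#' class is predicted with probability 1. Probabilities are clamped to
#' `[1e-12, 1]` before the logarithm so that an exact softmax underflow does
#' not produce an infinite loss.
#'
#' @param predictions `N x K` matrix of class probabilities (rows on the
#'   simplex); a vector is taken as a single observation.
#' @param targets `N x K` one-hot matrix of true labels.
#' @param weights nonnegative class-weight vector of length K.
#' @return scalar loss.
#' @export
#' @examples
#' weighted_cross_entropy(c(0.5, 0.5), c(1, 0), weights = c(1, 1))  # -log 0.5
weighted_cross_entropy <- function(predictions, targets, weights = NULL) {
  p <- rbind(predictions)
  t <- rbind(targets)
  if (!all(dim(p) == dim(t)))
    stop("predictions and targets must have the same shape")
  k <- ncol(p)
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k) stop("weights must have length K = ", k)
  if (any(weights < 0) || !all(is.finite(weights)))
    stop("class weights must be finite and nonnegative")
  if (all(weights == 0)) return(0)
  p <- pmin(pmax(p, PROB_CLAMP), 1)
  n <- nrow(p)
  -sum(t(t * log(p)) * weights) / n
}

# ---- optimizer --------------------------------------------------------------

#' One step of stochastic gradient descent with momentum
#'
#' Classical momentum: `v <- momentum * v - lr * (grad + l2 * params)`,
#' `params <- params + v`. With zero momentum and zero L2 this reduces to
#' plain gradient descent `theta - lr * grad`.
#'
#' @param params numeric parameter vector/array.
#' @param gradient gradient of the loss, same shape as `params`.
#' @param state an [optimizer_state()]; its velocity is initialized to zero
#'   on first use.
#' @return list with updated `params` and `state` (carrying the velocity).
#' @export
sgdm_step <- function(params, gradient, state = optimizer_state()) {
  if (length(params) != length(gradient))
    stop("params and gradient must have the same length")
  v <- state$velocity
  if (is.null(v)) v <- params * 0
  if (length(v) != length(params))
    stop("velocity shape does not match params")
  v <- state$momentum * v - state$learning_rate * (gradient + state$l2 * params)
  params <- params + v
  state$velocity <- v
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
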