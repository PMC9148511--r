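# Independent brute-force oracles used to check the package's operations.
# These deliberately use naive nested loops / direct enumeration, not the
# vectorized or compiled paths under test.

# direct five-loop dilated cross-correlation, zero same-padding or valid
brute_conv <- function(x, w, bias = NULL, r = 1L, padding = "same") {
  d <- dim(x); kh <- dim(w)[1]; kw <- dim(w)[2]
  cin <- dim(w)[3]; cout <- dim(w)[4]
  if (is.null(bias)) bias <- numeric(cout)
  keff_h <- kh + (kh - 1L) * (r - 1L)
  keff_w <- kw + (kw - 1L) * (r - 1L)
  if (padding == "same") {
    ph <- (keff_h - 1L) %/% 2L; pw <- (keff_w - 1L) %/% 2L
    xp <- array(0, c(d[1] + 2L * ph, d[2] + 2L * pw, cin))
    xp[ph + seq_len(d[1]), pw + seq_len(d[2]), ] <- x
    x <- xp
  }
  ho <- dim(x)[1] - (keff_h - 1L); wo <- dim(x)[2] - (keff_w - 1L)
  out <- array(0, c(ho, wo, cout))
  for (co in seq_len(cout))
    for (i in seq_len(ho))
      for (j in seq_len(wo)) {
        acc <- bias[co]
        for (ci in seq_len(cin))
          for (ki in seq_len(kh))
            for (kj in seq_len(kw))
              acc <- acc + x[i + (ki - 1L) * r, j + (kj - 1L) * r, ci] *
                w[ki, kj, ci, co]
        out[i, j, co] <- acc
      }
  out
}

# insert explicit zeros between kernel taps: k -> k + (k-1)(r-1)
inflate_kernel <- function(w, r) {
  kh <- dim(w)[1]; kw <- dim(w)[2]
  nh <- kh + (kh - 1L) * (r - 1L); nw <- kw + (kw - 1L) * (r - 1L)
  out <- array(0, c(nh, nw, dim(w)[3], dim(w)[4]))
  out[seq(1L, nh, by = r), seq(1L, nw, by = r), , ] <- w
  out
}

# hand evaluation of the batch-norm formulas on a flat numeric vector
bn_oracle <- function(x, gamma = 1, beta = 0, eps = 5e-5) {
  mu <- sum(x) / length(x)
  v <- sum((x - mu)^2) / length(x)
  gamma * (x - mu) / sqrt(v + eps) + beta
}

# point-in-ellipse rasterization by direct double loop over pixel centers
ellipse_mask_oracle <- function(H, W, cy, cx, a, b, theta) {
  m <- matrix(0L, H, W)
  for (i in seq_len(H))
    for (j in seq_len(W)) {
      xr <- cos(theta) * (j - cx) + sin(theta) * (i - cy)
      yr <- -sin(theta) * (j - cx) + cos(theta) * (i - cy)
      if ((xr / a)^2 + (yr / b)^2 <= 1) m[i, j] <- 1L
    }
  m
}

# nearest-neighbor index-mapping oracle: src = floor(i * H / H') (0-based)
resize_nearest_oracle <- function(x, target) {
  H <- dim(x)[1]; W <- dim(x)[2]
  out <- if (length(dim(x)) == 2L) matrix(0, target[1], target[2]) else
    array(0, c(target, dim(x)[3]))
  for (i in seq_len(target[1]))
    for (j in seq_len(target[2])) {
      si <- floor((i - 1) * H / target[1]) + 1
      sj <- floor((j - 1) * W / target[2]) + 1
      if (length(dim(x)) == 2L) out[i, j] <- x[si, sj]
      else out[i, j, ] <- x[si, sj, ]
    }
  out
}

# pixel-enumeration confusion counts
confusion_oracle <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# small three-layer network specification reused across tests
tiny_spec <- function(input_shape = c(6L, 7L, 2L)) {
  layers <- data.frame(
    name = c("a", "b", "f"), block = c(1L, 1L, 2L),
    kernel = c(3L, 1L, 1L), out_channels = c(4L, 3L, 2L),
    dilation = c(2L, 1L, NA_integer_),
    batch_norm = c(TRUE, TRUE, FALSE), activation = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  network_spec(layers, input_shape = input_shape)
}

# fast phantom settings for tests
test_phantom_params <- function(...) {
  phantom_params(image_size = c(48L, 64L), ...)
}
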