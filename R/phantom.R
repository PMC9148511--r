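# Synthetic dermoscopic phantoms: star-convex lesion blobs (ellipse with a
# radial Fourier perturbation) on a skin-toned background, with optional
# artifact overlays emulating the classic dermoscopy nuisances -- hairline
# occlusions, gel bubbles, illumination gradients and low contrast. The
# ground-truth mask is by construction the exact pixel support of the
# rendered lesion shape.

#' Phantom generator parameters
#'
#' @param image_size integer `(height, width)`; default `c(192, 256)`.
#' @param lesion_area_fraction_range interval within `(0, 0.9)` from which
#'   the lesion's area fraction of the image is drawn.
#' @param border_irregularity nonnegative amplitude of the radial Fourier
#'   perturbation of the lesion contour; 0 gives an exact ellipse.
#' @param hairlines,bubbles,illumination,low_contrast logical artifact
#'   toggles. When enabled, each sample draws a random number/strength of
#'   the artifact (possibly none for hairs and bubbles).
#' @param skin_color,lesion_color base RGB triplets in `[0, 1]` around which
#'   per-sample tones are jittered.
#' @param noise_sd standard deviation of the per-pixel Gaussian texture
#'   noise.
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = c(192L, 256L),
                           lesion_area_fraction_range = c(0.05, 0.30),
                           border_irregularity = 0.25,
                           hairlines = TRUE, bubbles = TRUE,
                           illumination = TRUE, low_contrast = TRUE,
                           skin_color = c(0.85, 0.64, 0.55),
                           lesion_color = c(0.45, 0.28, 0.22),
                           noise_sd = 0.02) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 8L))
    stop("image_size must be two positive integers (>= 8)")
  fr <- lesion_area_fraction_range
  if (length(fr) != 2L || fr[1] >= fr[2] || fr[1] <= 0 || fr[2] >= 0.9)
    stop("lesion_area_fraction_range must be an ordered interval within (0, 0.9)")
  if (border_irregularity < 0) stop("border_irregularity must be nonnegative")
  structure(list(image_size = image_size,
                 lesion_area_fraction_range = fr,
                 border_irregularity = border_irregularity,
                 hairlines = isTRUE(hairlines), bubbles = isTRUE(bubbles),
                 illumination = isTRUE(illumination),
                 low_contrast = isTRUE(low_contrast),
                 skin_color = skin_color, lesion_color = lesion_color,
                 noise_sd = noise_sd),
            class = "phantom_params")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Radial perturbation field delta(phi) as a low-order Fourier series with
# random coefficients; normalized so the continuous lesion area is
# independent of the perturbation (mean of (1 + delta)^2 equals 1 after
# rescaling).
radial_field_values <- function(coef, phi) {
  orders <- 2:6
  d <- 0
  for (j in seq_along(orders))
    d <- d + coef$cc[j] * cos(orders[j] * phi) +
      coef$ss[j] * sin(orders[j] * phi)
  pmin(pmax(d, -0.6), 0.6)
}

sample_radial_field <- function(irregularity, a, limit) {
  orders <- 2:6
  coef <- list(cc = stats::rnorm(length(orders), sd = irregularity / orders),
               ss = stats::rnorm(length(orders), sd = irregularity / orders))
  grid <- seq(0, 2 * pi, length.out = 721L)[-721L]
  repeat {
    scale <- 1 / sqrt(mean((1 + radial_field_values(coef, grid))^2))
    maxfac <- scale * (1 + max(radial_field_values(coef, grid)))
    # damp the perturbation until the blob's circumscribed radius fits the
    # image; the area normalization is recomputed afterwards, so the lesion
    # area is unaffected
    if (a * maxfac <= limit || all(coef$cc == 0 & coef$ss == 0)) break
    coef$cc <- coef$cc * 0.7
    coef$ss <- coef$ss * 0.7
  }
  list(coef = coef, scale = scale, maxfac = maxfac)
}

#' Generate one dermoscopic phantom with its ground-truth mask
#'
#' The lesion is a randomized star-convex blob: an ellipse (random area
#' fraction, aspect ratio and orientation) whose contour radius is modulated
#' by a low-order random Fourier series scaled by `border_irregularity`. The
#' mask is the exact pixel support of that blob. The lesion is rendered
#' darker and warmer than the surrounding skin with a subtly darker core;
#' optional overlays add thin dark hair curves (which occlude the image but,
#' as in real ground truth, leave the mask untouched), bright gel-bubble
#' discs, a linear illumination gradient, and global contrast compression.
#'
#' @param params a [phantom_params()].
#' @param seed optional integer seed; with a seed the sample is bit-wise
#'   reproducible.
#' @return object of class `image_sample`: list with `image`
#'   (`H x W x 3`, values in `[0, 1]`), `mask` (`H x W`, binary 0/1) and
#'   `meta` (seed, lesion geometry, artifact draw).
#' @export
#' @examples
#' s <- generate_sample(phantom_params(image_size = c(48, 64)), seed = 1)
#' mean(s$mask)
generate_sample <- function(params = phantom_params(), seed = NULL) {
  stopifnot(inherits(params, "phantom_params"))
  if (!is.null(seed)) set.seed(seed)
  H <- params$image_size[1]; W <- params$image_size[2]
  fr <- params$lesion_area_fraction_range
  margin <- 0.05 * diff(fr)
  f <- stats::runif(1, fr[1] + margin, fr[2] - margin)
  q <- stats::runif(1, 0.55, 0.95)          # aspect ratio b/a
  a <- sqrt(f * H * W / (pi * q))
  b <- a * q
  if (2 * a > 0.96 * min(H, W))
    stop("infeasible lesion area fraction ", signif(f, 3),
         " for image size ", H, "x", W)
  theta0 <- stats::runif(1, 0, pi)
  rad <- sample_radial_field(params$border_irregularity, a,
                             limit = 0.48 * min(H, W))
  ext <- a * rad$maxfac                     # circumscribed radius
  cy_rng <- c(max(ext + 1, 0.38 * H), min(H - ext - 1, 0.62 * H))
  cx_rng <- c(max(ext + 1, 0.38 * W), min(W - ext - 1, 0.62 * W))
  cy <- if (cy_rng[1] < cy_rng[2]) stats::runif(1, cy_rng[1], cy_rng[2]) else
    mean(pmin(pmax(cy_rng, ext + 1), H - ext - 1))
  cx <- if (cx_rng[1] < cx_rng[2]) stats::runif(1, cx_rng[1], cx_rng[2]) else
    mean(pmin(pmax(cx_rng, ext + 1), W - ext - 1))

  # pixel-center coordinates in the ellipse frame
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  xr <- cos(theta0) * xx + sin(theta0) * yy
  yr <- -sin(theta0) * xx + cos(theta0) * yy
  u <- sqrt((xr / a)^2 + (yr / b)^2)        # normalized elliptical radius
  phi <- atan2(yr / b, xr / a)
  mask <- (u <= rad$scale * (1 + radial_field_values(rad$coef, phi))) * 1L
  dim(mask) <- c(H, W)

  # appearance
  skin <- clamp01(params$skin_color + stats::runif(3, -0.06, 0.06))
  lesion <- clamp01(params$lesion_color + stats::runif(3, -0.06, 0.06))
  img <- array(0, c(H, W, 3))
  core <- 0.72 + 0.28 * pmin(u, 1)          # darker toward the lesion core
  inside <- mask == 1L
  for (c in 1:3) {
    plane <- matrix(skin[c], H, W)
    plane[inside] <- (lesion[c] * core)[inside]
    img[, , c] <- plane
  }
  img <- img + array(stats::rnorm(H * W * 3, sd = params$noise_sd), c(H, W, 3))

  artifacts <- list(hairs = 0L, bubbles = 0L, illumination = 0,
                    contrast = 1)
  if (params$hairlines) {
    nh <- sample(0:4, 1)
    artifacts$hairs <- nh
    if (nh > 0) for (i in seq_len(nh)) img <- draw_hair(img)
  }
  if (params$bubbles) {
    nb <- sample(0:3, 1)
    artifacts$bubbles <- nb
    if (nb > 0) for (i in seq_len(nb)) img <- draw_bubble(img)
  }
  if (params$illumination) {
    amp <- stats::runif(1, 0.05, 0.15)
    artifacts$illumination <- amp
    ang <- stats::runif(1, 0, 2 * pi)
    proj <- cos(ang) * xx + sin(ang) * yy
    field <- 1 + amp * proj / max(abs(range(proj)))
    img <- img * array(rep(field, 3), c(H, W, 3))
  }
  if (params$low_contrast && stats::runif(1) < 0.4) {
    fac <- stats::runif(1, 0.55, 0.8)
    artifacts$contrast <- fac
    m <- mean(img)
    img <- m + (img - m) * fac
  }
  img <- clamp01(img)

  structure(list(image = img, mask = mask,
                 meta = list(seed = seed,
                             lesion = list(center = c(cy, cx),
                                           axes = c(a, b), angle = theta0,
                                           area_fraction_target = f),
                             artifacts = artifacts,
                             params = params)),
            class = "image_sample")
}

# thin dark quadratic Bezier curve crossing the image
draw_hair <- function(img) {
  H <- dim(img)[1]; W <- dim(img)[2]
  side <- sample(1:2, 1)
  if (side == 1L) {                         # left-right
    p0 <- c(stats::runif(1, 1, H), 1)
    p2 <- c(stats::runif(1, 1, H), W)
  } else {                                  # top-bottom
    p0 <- c(1, stats::runif(1, 1, W))
    p2 <- c(H, stats::runif(1, 1, W))
  }
  p1 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
  tt <- seq(0, 1, length.out = 4L * (H + W))
  py <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
  px <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
  iy <- round(py); ix <- round(px)
  keep <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
  idx <- unique(cbind(iy[keep], ix[keep]))
  shade <- stats::runif(1, 0.7, 1.1)
  col <- c(0.16, 0.11, 0.08) * shade
  for (c in 1:3) {
    plane <- img[, , c]
    plane[idx] <- col[c]
    img[, , c] <- plane
  }
  img
}

# bright gel-bubble disc
draw_bubble <- function(img) {
  H <- dim(img)[1]; W <- dim(img)[2]
  rad <- stats::runif(1, 2, max(3, min(H, W) / 18))
  cy <- stats::runif(1, 1 + rad, H - rad)
  cx <- stats::runif(1, 1 + rad, W - rad)
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  d <- sqrt(yy^2 + xx^2)
  disc <- d <= rad
  gain <- stats::runif(1, 0.15, 0.3)
  for (c in 1:3) {
    plane <- img[, , c]
    plane[disc] <- plane[disc] + gain * (1 - plane[disc])
    img[, , c] <- plane
  }
  img
}

#' Nearest-neighbor resize
#'
#' Each output pixel takes the value of its nearest source pixel
#' (`src = floor(i * H / H_out)` in 0-based coordinates, independently per
#' axis), so binary masks remain strictly binary. This is the preprocessing
#' used to bring arbitrarily sized dermoscopic images to the network's
#' working resolution.
#'
#' @param x numeric matrix or `H x W x C` array.
#' @param target integer `(height, width)`.
#' @return resized matrix/array.
#' @export
resize_nearest <- function(x, target) {
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L))
    stop("target must be two positive integers")
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("x must be a matrix or rank-3 array")
  H <- d[1]; W <- d[2]
  mi <- floor((seq_len(target[1]) - 1L) * H / target[1]) + 1L
  mj <- floor((seq_len(target[2]) - 1L) * W / target[2]) + 1L
  if (length(d) == 2L) x[mi, mj, drop = FALSE] else x[mi, mj, , drop = FALSE]
}

#' @rdname resize_nearest
#' @param sample an `image_sample`; image and mask are resized congruently.
#' @export
resize_sample <- function(sample, target) {
  stopifnot(inherits(sample, "image_sample"))
  sample$image <- resize_nearest(sample$image, target)
  sample$mask <- resize_nearest(sample$mask, target)
  sample$meta$resized_to <- as.integer(target)
  sample
}

#' Augmentation specification
#'
#' Random geometric augmentation: rotation angle drawn uniformly from
#' `rotation_degrees`, isotropic scaling by `1 + u/100` and per-axis pixel
#' translation with `u` drawn uniformly from `scale_translate_factors`.
#'
#' @param rotation_degrees ordered interval of rotation angles in degrees.
#' @param scale_translate_factors ordered interval for the scale (percent
#'   deviation) and translation (pixel) draws.
#' @param rotate,scale,translate logical toggles per transform.
#' @return object of class `augment_spec`.
#' @export
augment_spec <- function(rotation_degrees = c(15, 20),
                         scale_translate_factors = c(-6, 5),
                         rotate = TRUE, scale = TRUE, translate = TRUE) {
  if (rotation_degrees[1] > rotation_degrees[2] ||
      scale_translate_factors[1] > scale_translate_factors[2])
    stop("intervals must be ordered")
  structure(list(rotation_degrees = rotation_degrees,
                 scale_translate_factors = scale_translate_factors,
                 rotate = isTRUE(rotate), scale = isTRUE(scale),
                 translate = isTRUE(translate)),
            class = "augment_spec")
}

reflect_index <- function(i, n) {
  # fold arbitrary integer indices into [1, n] by mirror reflection
  period <- 2L * n
  j <- ((i - 1L) %% period + period) %% period
  ifelse(j < n, j + 1L, period - j)
}

#' Randomly augment an image/mask pair
#'
#' Applies one random affine transform (rotation about the image center,
#' isotropic scaling, pixel translation) identically to the image and its
#' mask. The image is resampled bilinearly with mirror-reflected borders
#' (avoiding spurious dark corners that could resemble lesions); the mask is
#' resampled by nearest neighbor with background fill, so it stays strictly
#' binary. With all transforms disabled the sample is returned unchanged.
#'
#' @param sample an `image_sample`.
#' @param spec an [augment_spec()].
#' @param seed optional integer seed for the parameter draw.
#' @return the augmented `image_sample`; the forward affine map used is
#'   stored in `meta$transform` (`matrix` M, `shift` t, `center`), with
#'   output pixel `p_out = M %*% (p_in - center) + center + t` in (row, col)
#'   coordinates.
#' @export
augment <- function(sample, spec = augment_spec(), seed = NULL) {
  stopifnot(inherits(sample, "image_sample"), inherits(spec, "augment_spec"))
  if (!spec$rotate && !spec$scale && !spec$translate) return(sample)
  if (!is.null(seed)) set.seed(seed)
  theta <- if (spec$rotate)
    stats::runif(1, spec$rotation_degrees[1], spec$rotation_degrees[2]) * pi / 180 else 0
  s <- if (spec$scale)
    1 + stats::runif(1, spec$scale_translate_factors[1],
                     spec$scale_translate_factors[2]) / 100 else 1
  tvec <- if (spec$translate)
    stats::runif(2, spec$scale_translate_factors[1],
                 spec$scale_translate_factors[2]) else c(0, 0)

  H <- dim(sample$mask)[1]; W <- dim(sample$mask)[2]
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  M <- s * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Minv <- solve(M)

  # inverse-map every output pixel center to source coordinates
  oy <- matrix(seq_len(H), H, W) - ctr[1] - tvec[1]
  ox <- matrix(seq_len(W), H, W, byrow = TRUE) - ctr[2] - tvec[2]
  sy <- Minv[1, 1] * oy + Minv[1, 2] * ox + ctr[1]
  sx <- Minv[2, 1] * oy + Minv[2, 2] * ox + ctr[2]

  # bilinear image sampling with reflected borders
  y0 <- floor(sy); x0 <- floor(sx)
  wy <- sy - y0; wx <- sx - x0
  iy0 <- reflect_index(y0, H); iy1 <- reflect_index(y0 + 1, H)
  ix0 <- reflect_index(x0, W); ix1 <- reflect_index(x0 + 1, W)
  img <- array(0, dim(sample$image))
  for (c in seq_len(dim(sample$image)[3])) {
    plane <- sample$image[, , c]
    img[, , c] <-
      (1 - wy) * (1 - wx) * plane[cbind(c(iy0), c(ix0))] +
      (1 - wy) * wx       * plane[cbind(c(iy0), c(ix1))] +
      wy       * (1 - wx) * plane[cbind(c(iy1), c(ix0))] +
      wy       * wx       * plane[cbind(c(iy1), c(ix1))]
  }

  # nearest-neighbor mask sampling, background outside the source grid
  ry <- round(sy); rx <- round(sx)
  inside <- ry >= 1 & ry <= H & rx >= 1 & rx <= W
  mask <- matrix(0L, H, W)
  mask[inside] <- sample$mask[cbind(ry[inside], rx[inside])]

  sample$image <- img
  sample$mask <- mask
  sample$meta$transform <- list(matrix = M, shift = tvec, center = ctr,
                                angle = theta, scale = s)
  sample
}

#' Generate a reproducible phantom dataset
#'
#' Draws `n` independent samples from per-sample seeds derived from the
#' master seed, so the whole dataset is reproducible end-to-end and
#' individual samples can be regenerated in isolation.
#'
#' @param n number of samples (>= 1).
#' @param params a [phantom_params()].
#' @param seed master integer seed.
#' @return list of `image_sample` objects; the derived per-sample seeds are
#'   attached as attribute `seeds`.
#' @export
generate_dataset <- function(n, params = phantom_params(), seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- lapply(seq_len(n), function(i) {
    s <- generate_sample(params, seed = seeds[i])
    s$meta$id <- sprintf("phantom_%04d", i)
    s
  })
  attr(out, "seeds") <- seeds
  out
}
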