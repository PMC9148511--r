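# Synthetic dermoscopic phantoms: determinism, mask/shape agreement,
# resizing and augmentation.

test_that("phantom generation is deterministic and respects the area-fraction range", {
  p <- phantom_params()   # default 192x256
  s1 <- generate_sample(p, seed = 7)
  s2 <- generate_sample(p, seed = 7)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)

  expect_true(all(s1$image >= 0 & s1$image <= 1))
  expect_true(all(s1$mask %in% c(0L, 1L)))
  fr <- mean(s1$mask)
  expect_gte(fr, p$lesion_area_fraction_range[1])
  expect_lte(fr, p$lesion_area_fraction_range[2])
})

test_that("zero border irregularity yields an exact discrete ellipse", {
  p <- phantom_params(image_size = c(96, 128), border_irregularity = 0,
                      hairlines = FALSE, bubbles = FALSE)
  s <- generate_sample(p, seed = 11)
  les <- s$meta$lesion
  oracle <- ellipse_mask_oracle(96, 128, les$center[1], les$center[2],
                                les$axes[1], les$axes[2], les$angle)
  expect_identical(s$mask, oracle)
  # discrete area close to the targeted continuous area
  expect_equal(mean(s$mask), les$area_fraction_target, tolerance = 0.05)
})

test_that("the lesion is darker than the surrounding skin and artifacts stay in range", {
  p <- test_phantom_params()
  for (seed in 1:5) {
    s <- generate_sample(p, seed = seed)
    inside <- s$mask == 1
    lum <- apply(s$image, 1:2, mean)
    expect_gt(mean(lum[!inside]), mean(lum[inside]))
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
})

test_that("infeasible area fractions are rejected", {
  expect_error(phantom_params(lesion_area_fraction_range = c(0.2, 0.95)),
               "within \\(0, 0.9\\)")
  p <- phantom_params(image_size = c(24, 24),
                      lesion_area_fraction_range = c(0.85, 0.89))
  expect_error(generate_sample(p, seed = 1), "infeasible")
})

test_that("nearest-neighbor resize matches the index-mapping oracle", {
  # identity when target equals source
  m <- matrix(runif(30), 5, 6)
  expect_identical(resize_nearest(m, c(5, 6)), m)

  # 2x2 checkerboard -> 4x4 block replication
  cb <- matrix(c(1, 0, 0, 1), 2, 2)
  up <- resize_nearest(cb, c(4, 4))
  expect_equal(up, matrix(c(1, 1, 0, 0,
                            1, 1, 0, 0,
                            0, 0, 1, 1,
                            0, 0, 1, 1), 4, 4))

  # random sizes, both directions, against the double-loop oracle
  set.seed(51)
  for (i in 1:10) {
    src <- c(sample(3:17, 1), sample(3:17, 1))
    dst <- c(sample(3:17, 1), sample(3:17, 1))
    x <- array(runif(prod(src) * 3), c(src, 3))
    expect_equal(resize_nearest(x, dst), resize_nearest_oracle(x, dst))
  }

  # binary masks stay binary
  mk <- matrix(rbinom(15 * 17, 1, 0.4), 15, 17)
  out <- resize_nearest(mk, c(29, 8))
  expect_true(all(out %in% c(0, 1)))
})

test_that("augmentation is deterministic, keeps masks binary, and moves the centroid correctly", {
  s <- generate_sample(
    test_phantom_params(hairlines = FALSE, bubbles = FALSE,
                        lesion_area_fraction_range = c(0.05, 0.15)),
    seed = 13)

  # disabled transforms return the sample unchanged
  off <- augment_spec(rotate = FALSE, scale = FALSE, translate = FALSE)
  expect_identical(augment(s, off, seed = 1), s)

  a1 <- augment(s, seed = 5)
  a2 <- augment(s, seed = 5)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  expect_true(all(a1$mask %in% c(0L, 1L)))

  # mask centroid follows the affine map within a pixel
  tr <- a1$meta$transform
  cen <- function(m) {
    idx <- which(m == 1, arr.ind = TRUE)
    colMeans(idx)
  }
  c0 <- cen(s$mask)
  expected <- as.vector(tr$matrix %*% (c0 - tr$center)) + tr$center + tr$shift
  got <- cen(a1$mask)
  expect_lt(max(abs(got - expected)), 1)
})

test_that("image and mask stay congruent under augmentation", {
  # nearest-neighbor warped mask vs thresholded bilinear warp of the mask
  # as a continuous field: overlap must be nearly perfect
  s <- generate_sample(test_phantom_params(hairlines = FALSE, bubbles = FALSE),
                       seed = 17)
  soft <- s
  soft$image <- array(rep(s$mask, 3), c(dim(s$mask), 3))  # mask as image
  for (seed in c(3, 8)) {
    a <- augment(soft, seed = seed)
    hard <- (a$image[, , 1] >= 0.5) * 1L
    jac <- score_masks(a$mask, hard)[["JAC"]]
    expect_gte(jac, 0.95)
  }
})

test_that("dataset generation is reproducible and derives per-sample seeds", {
  p <- test_phantom_params()
  d1 <- generate_dataset(5, p, seed = 99)
  d2 <- generate_dataset(5, p, seed = 99)
  expect_identical(d1, d2)

  # n = 1 equals generate_sample under the derived seed
  d <- generate_dataset(1, p, seed = 123)
  set.seed(123)
  derived <- sample.int(.Machine$integer.max - 1L, 1)
  s <- generate_sample(p, seed = derived)
  expect_identical(d[[1]]$image, s$image)
  expect_identical(d[[1]]$mask, s$mask)

  # empirical mean area fraction sits inside the configured interval
  d <- generate_dataset(60, p, seed = 7)
  mean_fr <- mean(vapply(d, function(s) mean(s$mask), 0))
  expect_gte(mean_fr, p$lesion_area_fraction_range[1])
  expect_lte(mean_fr, p$lesion_area_fraction_range[2])
})

test_that("samples round-trip through the ISIC-style folder layout", {
  d <- generate_dataset(3, test_phantom_params(), seed = 31)
  dir <- file.path(tempfile(), "phantoms")
  write_samples(d, dir)
  files <- list.files(dir)
  expect_length(files, 6L)   # 3 images + 3 masks
  back <- load_samples(dir)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, d[[i]]$mask)
    # PNG quantizes to 8 bits
    expect_lt(max(abs(back[[i]]$image - d[[i]]$image)), 1 / 255)
  }
  # images without a mask are skipped (with a message) by default
  png::writePNG(d[[1]]$image, file.path(dir, "orphan.png"))
  expect_message(load_samples(dir), "orphan")
  expect_length(suppressMessages(load_samples(dir)), 3L)
  expect_length(suppressMessages(load_samples(dir, require_mask = FALSE)), 4L)
})
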