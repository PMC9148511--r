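# Folder I/O mirroring the ISIC layout: paired `<id>.png` / `<id>_mask.png`
# files, masks encoded 0/255.

#' Write image/mask pairs to a folder
#'
#' @param samples list of `image_sample` objects.
#' @param dir output directory (created if missing).
#' @param prefix id prefix used when a sample carries no `meta$id`.
#' @return character vector of the ids written, invisibly.
#' @export
write_samples <- function(samples, dir, prefix = "phantom") {
  if (inherits(samples, "image_sample")) samples <- list(samples)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    id <- s$meta$id %||% sprintf("%s_%04d", prefix, i)
    ids[i] <- id
    png::writePNG(s$image, file.path(dir, paste0(id, ".png")))
    if (!is.null(s$mask))
      png::writePNG(s$mask * 1.0, file.path(dir, paste0(id, "_mask.png")))
  }
  invisible(ids)
}

#' Load an ISIC-style folder of image/mask pairs
#'
#' Scans `dir` for PNG images and pairs each `<id>.png` with its
#' `<id>_mask.png` when present (masks are binarized at 0.5). Images are
#' returned as `H x W x 3` arrays in `[0, 1]`; grayscale files are expanded
#' to three channels. Only PNG is supported (there is no JPEG reader in the
#' package's dependency set); convert JPEG folders to PNG first.
#'
#' @param dir directory to scan.
#' @param require_mask if TRUE, images without a mask file are dropped with
#'   a message; if FALSE they are kept with `mask = NULL`.
#' @return list of `image_sample` objects (possibly empty), sorted by id.
#' @export
load_samples <- function(dir, require_mask = TRUE) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "\\.png$", ignore.case = TRUE))
  mask_files <- grepl("_mask\\.png$", files, ignore.case = TRUE)
  image_files <- files[!mask_files]
  out <- list()
  for (f in image_files) {
    id <- tools::file_path_sans_ext(f)
    img <- png::readPNG(file.path(dir, f))
    if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
    mask_path <- file.path(dir, paste0(id, "_mask.png"))
    mask <- NULL
    if (file.exists(mask_path)) {
      m <- png::readPNG(mask_path)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      mask <- (m >= 0.5) * 1L
      if (!identical(dim(mask), dim(img)[1:2]))
        stop("mask size does not match image for id ", id)
    } else if (require_mask) {
      message("skipping ", id, ": no mask file")
      next
    }
    out[[length(out) + 1L]] <-
      structure(list(image = img, mask = mask, meta = list(id = id)),
                class = "image_sample")
  }
  out
}
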