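# The published layer table encoded as data, plus structural analyses that
# can be checked without running the network: per-layer output shapes under
# same-padding/stride-1, learnable-parameter counts, and the analytic
# receptive field.

#' Network specification constructor
#'
#' @param layers data frame with columns `name`, `block`, `kernel`,
#'   `out_channels`, `dilation` (NA for the final 1x1 classifier),
#'   `batch_norm`, `activation`.
#' @param input_shape integer vector `(height, width, channels)`.
#' @return object of class `network_spec` with derived `in_channels`.
#' @export
network_spec <- function(layers, input_shape = c(192L, 256L, 3L)) {
  stopifnot(is.data.frame(layers), length(input_shape) == 3L)
  needed <- c("name", "block", "kernel", "out_channels", "dilation",
              "batch_norm", "activation")
  if (!all(needed %in% names(layers)))
    stop("layer table is missing columns: ",
         paste(setdiff(needed, names(layers)), collapse = ", "))
  if (!all(layers$kernel %in% c(1L, 3L)))
    stop("kernel sizes must be 1x1 or 3x3")
  if (any(!is.na(layers$dilation) & layers$dilation < 1L))
    stop("dilation rates must be >= 1 when present")
  layers$in_channels <- c(input_shape[3],
                          layers$out_channels[-nrow(layers)])
  structure(list(input_shape = as.integer(input_shape), layers = layers),
            class = "network_spec")
}

#' The DilatedSkinNet architecture
#'
#' Returns the published 16-convolution-layer atrous network as data: five
#' blocks of 3x3 dilated convolutions (with interleaved 1x1 channel-reduction
#' layers) at dilation rates 1 through 14, each followed by batch
#' normalization and leakyReLU, closed by a 1x1 two-channel classifier that
#' feeds a pixelwise softmax. All layers keep the 192x256 spatial resolution
#' (stride 1, same padding); there is no pooling.
#'
#' The dilation rate stored for 1x1 layers is kept for fidelity with the
#' published table but is mathematically inert (a single tap has no spacing).
#'
#' @return a [network_spec()].
#' @export
#' @examples
#' spec <- dilatedskinnet_spec()
#' nrow(spec$layers)  # 16 convolutional layers
dilatedskinnet_spec <- function() {
  layers <- data.frame(
    name = c("Conv1",
             "Conv2_1", "Conv2_2",
             "Conv3_1", "Conv3_2", "Conv3_3",
             "Conv4_1", "Conv4_2", "Conv4_3", "Conv4_4",
             "Conv5_1", "Conv5_2", "Conv5_3", "Conv5_4", "Conv5_5",
             "final_Conv"),
    block = c(1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 4L,
              5L, 5L, 5L, 5L, 5L, 6L),
    kernel = c(3L, 3L, 3L, 3L, 1L, 3L, 3L, 1L, 3L, 3L,
               3L, 1L, 3L, 1L, 3L, 1L),
    out_channels = c(8L, 16L, 16L, 32L, 16L, 32L, 64L, 32L, 64L, 64L,
                     128L, 64L, 128L, 64L, 128L, 2L),
    dilation = c(1L, 2L, 4L, 4L, 6L, 8L, 8L, 10L, 10L, 12L,
                 12L, 12L, 14L, 14L, 14L, NA_integer_),
    stringsAsFactors = FALSE
  )
  layers$batch_norm <- layers$name != "final_Conv"
  layers$activation <- layers$name != "final_Conv"
  network_spec(layers, input_shape = c(192L, 256L, 3L))
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Network specification:", nrow(x$layers), "convolutional layers,",
      "input", paste(x$input_shape, collapse = "x"), "\n")
  print(arch_report(x), row.names = FALSE)
  invisible(x)
}

#' Per-layer output shapes
#'
#' Analytic output shapes under same padding and stride 1: every layer keeps
#' the input height and width and emits its configured channel count; the
#' closing softmax keeps the final classifier's two channels.
#'
#' @param spec a [network_spec()].
#' @return data frame with columns `name`, `height`, `width`, `channels`
#'   (one row per conv layer plus a `Softmax` row).
#' @export
compute_shape_report <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  h <- spec$input_shape[1]; w <- spec$input_shape[2]
  data.frame(
    name = c(spec$layers$name, "Softmax"),
    height = h, width = w,
    channels = c(spec$layers$out_channels,
                 spec$layers$out_channels[nrow(spec$layers)]),
    stringsAsFactors = FALSE
  )
}

#' Learnable-parameter counts
#'
#' Closed-form per-layer counts: `k_h*k_w*C_in*C_out` convolution weights
#' plus `C_out` biases, plus `2*C_out` batch-norm scale/offset parameters
#' for layers followed by batch normalization.
#'
#' @param spec a [network_spec()].
#' @return list with `per_layer` (data frame), `conv_total`, `bn_total`,
#'   `total`.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  L <- spec$layers
  conv_weights <- L$kernel^2 * L$in_channels * L$out_channels
  conv_bias <- L$out_channels
  bn <- ifelse(L$batch_norm, 2L * L$out_channels, 0L)
  per_layer <- data.frame(name = L$name,
                          conv_weights = conv_weights,
                          conv_bias = conv_bias,
                          bn_params = bn,
                          total = conv_weights + conv_bias + bn,
                          stringsAsFactors = FALSE)
  list(per_layer = per_layer,
       conv_total = sum(conv_weights + conv_bias),
       bn_total = sum(bn),
       total = sum(per_layer$total))
}

#' Analytic receptive field
#'
#' The theoretical receptive field of one output pixel under stride 1:
#' `RF = 1 + sum_layers (k_eff - 1)` with effective kernel extent
#' `k_eff = k + (k - 1) * (r - 1)`. 1x1 layers contribute nothing regardless
#' of their stored dilation rate.
#'
#' @param spec a [network_spec()].
#' @return integer vector `c(height, width)`.
#' @seealso [empirical_receptive_field()] for the gradient-support oracle.
#' @export
receptive_field <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  L <- spec$layers
  r <- ifelse(is.na(L$dilation), 1L, L$dilation)
  keff <- L$kernel + (L$kernel - 1L) * (r - 1L)
  rf <- 1L + sum(keff - 1L)
  c(height = rf, width = rf)
}

#' Architecture report table
#'
#' One row per convolutional layer mirroring the published architecture
#' table (layer, kernel, feature maps, dilation rate, output size), suitable
#' for diffing against the publication or exporting as JSON.
#'
#' @param spec a [network_spec()].
#' @param json optional path; when given the table is also written as JSON.
#' @return data frame (invisibly returns the same when `json` is written).
#' @export
arch_report <- function(spec, json = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  L <- spec$layers
  h <- spec$input_shape[1]; w <- spec$input_shape[2]
  out <- data.frame(
    layer = L$name,
    block = L$block,
    kernel = paste0(L$kernel, "x", L$kernel),
    feature_maps = L$out_channels,
    dilation_rate = L$dilation,
    output_size = paste0(h, "x", w, "x", L$out_channels),
    stringsAsFactors = FALSE
  )
  if (!is.null(json))
    jsonlite::write_json(out, json, dataframe = "rows", pretty = TRUE)
  out
}
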