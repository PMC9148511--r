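#' ISIC challenge data bookkeeping
#'
#' The published training/validation/test split sizes of the ISIC 2016-2018
#' lesion-segmentation challenges as used for the network's experiments
#' (ISIC 2016's 900 training images split 7:3 into 630/270; ISIC 2018's
#' labeled pool split so 780 images serve as the test set), together with
#' the stated overall totals. Useful as a bookkeeping cross-check when
#' loading real ISIC folders.
#'
#' @return data frame with columns `dataset`, `training`, `validation`,
#'   `test`; the stated grand totals are attached as attribute
#'   `stated_totals`.
#' @export
#' @examples
#' counts <- isic_challenge_counts()
#' colSums(counts[, -1])  # matches attr(counts, "stated_totals")
isic_challenge_counts <- function() {
  df <- data.frame(
    dataset = c("ISIC 2016", "ISIC 2017", "ISIC 2018"),
    training = c(630L, 2000L, 1816L),
    validation = c(270L, 150L, 100L),
    test = c(379L, 366L, 780L),
    stringsAsFactors = FALSE
  )
  attr(df, "stated_totals") <- c(training = 4446L, validation = 520L,
                                 test = 1525L)
  df
}
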