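#' Derive a child seed from a parent seed and a string key
#'
#' Stable string-keyed seed derivation used throughout the package so that
#' every sub-computation (weight draws, fold assignment, candidate sampling,
#' bootstrap) gets its own reproducible stream from a single master seed.
#' The result is always a non-negative integer below 2^28.
#'
#' @param seed Integer parent seed.
#' @param key Character key naming the sub-stream.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, "weights")
derive_seed <- function(seed, key) {
  h <- rlang::hash(paste(seed, key, sep = "/"))
  strtoi(substr(h, 1L, 7L), base = 16L)
}

expit <- function(x) stats::plogis(x)

#' @importFrom rlang abort warn inform %||% .data
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# predictor columns of a survey dataset, in order
predictor_cols <- function(data) {
  grep("^x[0-9]+$", names(data), value = TRUE)
}

as_predictor_matrix <- function(data) {
  cols <- predictor_cols(data)
  out <- as.matrix(data[cols])
  storage.mode(out) <- "double"
  out
}

dataset_hash <- function(data) {
  cols <- c(predictor_cols(data), "y", "weight", "stratum")
  rlang::hash(lapply(data[cols], unname))
}
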