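#' @useDynLib vcgrpeak, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn %||% .data
#' @importFrom stats fft rnorm runif rbinom sd quantile kmeans predict
#' @importFrom utils head tail
NULL

# internal: stop with a classed condition so tests can target failures precisely
vcg_abort <- function(msg, class) {
  abort(msg, class = c(class, "vcgrpeak_error"))
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
}
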