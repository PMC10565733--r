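# Internal error helpers. Two condition classes are distinguished so that the
# command-line wrapper can map them onto distinct exit codes:
# "isoclust_config_error" (bad parameters / configuration) and
# "isoclust_data_error" (inputs that cannot be analysed).

abort_config <- function(message, ...) {
  abort(message, class = "isoclust_config_error", ...)
}

abort_data <- function(message, ...) {
  abort(message, class = "isoclust_data_error", ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Sigma-weighted (inverse-variance) mean of intensities sharing one index.
# sigma == 0 entries would give infinite weight; they are guarded by flooring
# the sigma used for weighting at the machine epsilon, which reduces to an
# exact average when all sigmas are equal (including all zero).
weighted_merge <- function(intensity, sigma) {
  w <- 1 / pmax(sigma, .Machine$double.eps)^2
  c(
    intensity = sum(w * intensity) / sum(w),
    sigma = sqrt(1 / sum(w))
  )
}
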