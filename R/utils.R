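#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx dnorm median optim pnorm qnorm quantile rbinom
#'   rnorm runif setNames uniroot
#' @importFrom utils write.csv read.csv
#' @importFrom rlang .data
NULL

# Derive a reproducible integer sub-seed from a master seed and integer keys.
# Keeps everything below 2^31 so set.seed() accepts it on 32-bit integers.
seed_stream <- function(master, ...) {
  keys <- c(...)
  x <- as.numeric(master) %% 2147483647
  for (k in keys) {
    x <- (x * 69069 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(x)
}

# Minimum-jerk position profile on tau in [0, 1]: smooth 0 -> 1 step with
# zero velocity and acceleration at both ends.
minjerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

# Time derivative of minjerk with respect to tau.
minjerk_deriv <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  30 * tau^2 - 60 * tau^3 + 30 * tau^4
}

# Saccade duration from amplitude: main-sequence-like linear rule,
# 20 ms base plus 2 ms per degree, bounded to a physiological range.
saccade_duration <- function(amplitude_deg) {
  pmin(pmax(0.020 + 0.002 * abs(amplitude_deg), 0.020), 0.060)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Column of a data frame if present, else a default (avoids tibble's
# unknown-column warning on `$`).
col_or <- function(df, name, default = NULL) {
  if (name %in% names(df)) df[[name]] else default
}
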