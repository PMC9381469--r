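#' @importFrom rlang abort hash
#' @importFrom stats pnorm dnorm qnorm rnorm runif rbinom rpois plogis sd cor
#'   t.test lm coef residuals setNames median complete.cases
#' @importFrom methods is new validObject slot slotNames
#' @importFrom utils read.csv write.csv
NULL

# Structured conditions so callers (and the CLI) can distinguish configuration
# errors from data-contract errors.
configError <- function(msg, ...) {
  rlang::abort(msg, class = "spineCalib_config_error", ...)
}

dataError <- function(msg, ...) {
  rlang::abort(msg, class = "spineCalib_data_error", ...)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Decimal display rounding with the conventional half-up tie-break (base R's
#' `round()` rounds half to even). Used wherever thresholds are reported at
#' one-decimal precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' roundHalfUp(c(0.25, 0.35), 1)
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Mean and variance of a normal truncated to [lower, upper].
truncnormMoments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  d <- (dnorm(a) - dnorm(b)) / z
  m <- mean + sd * d
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z - d^2)
  list(mean = m, var = v)
}

# Inversion sampler for the truncated normal (deterministic given RNG stream).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Format numerics for canonical CSV output: NA -> "", full precision otherwise.
formatNumCsv <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}
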