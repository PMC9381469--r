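# Independent brute-force oracles, kept deliberately separate from the
# package's implementation paths.

# Pearson r by direct summation of the textbook formula.
pearsonBrute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); syy <- sum(y * y); sxy <- sum(x * y)
  (n * sxy - sx * sy) /
    (sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2))
}

# OLS slope/intercept from the closed-form normal equations.
olsBrute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x * x) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# Two-sided paired permutation test by sign flips of the differences
# (exhaustive up to 2^n flips for small n).
permutePairedP <- function(d, nmax = 2^14) {
  n <- length(d)
  obs <- abs(mean(d))
  if (2^n <= nmax) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats <- abs(signs %*% d) / n
    mean(stats >= obs - 1e-15)
  } else {
    stats <- replicate(nmax, abs(mean(d * sample(c(-1, 1), n, TRUE))))
    mean(stats >= obs - 1e-15)
  }
}
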