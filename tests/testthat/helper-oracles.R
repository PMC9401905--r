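# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical paths: brute-force quadrature on a fine fixed
# grid, closed-form normal equations, and exhaustive simplex grid search.

# Band-equivalent reflectance by trapezoidal quadrature on a fine regular
# grid (default 0.01 nm), linearly interpolating spectrum and response.
oracle_band_reflectance <- function(spectrum, response, step = 0.01) {
  s <- min(response$wavelength_nm); e <- max(response$wavelength_nm)
  grid <- seq(s, e, by = step)
  R <- approx(spectrum$wavelength_nm, spectrum$reflectance, xout = grid,
              rule = 2)$y
  S <- approx(response$wavelength_nm, response$weight, xout = grid,
              yleft = 0, yright = 0)$y
  trapz <- function(y) sum(diff(grid) * (y[-length(y)] + y[-1]) / 2)
  trapz(R * S) / trapz(S)
}

# Closed-form simple linear regression via accumulated sums.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  pred <- slope * x + intercept
  sse <- sum((y - pred)^2); sst <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       r2 = 1 - sse / sst, rmse = sqrt(sse / n))
}

# Exhaustive search over the abundance simplex at a fixed step; returns
# the minimal residual sum of squares and the best abundance vector.
# Only practical for <= 4 endmembers.
oracle_simplex_grid <- function(pixel, spectra, step = 0.01) {
  m <- nrow(spectra)
  stopifnot(m <= 4)
  k <- round(1 / step)
  best <- Inf; best_a <- NULL
  if (m == 2) {
    for (i in 0:k) {
      a <- c(i, k - i) / k
      r <- pixel - as.numeric(a %*% spectra)
      v <- sum(r^2)
      if (v < best) { best <- v; best_a <- a }
    }
  } else if (m == 3) {
    for (i in 0:k) for (j in 0:(k - i)) {
      a <- c(i, j, k - i - j) / k
      r <- pixel - as.numeric(a %*% spectra)
      v <- sum(r^2)
      if (v < best) { best <- v; best_a <- a }
    }
  } else {
    for (i in 0:k) for (j in 0:(k - i)) for (l in 0:(k - i - j)) {
      a <- c(i, j, l, k - i - j - l) / k
      r <- pixel - as.numeric(a %*% spectra)
      v <- sum(r^2)
      if (v < best) { best <- v; best_a <- a }
    }
  }
  list(rss = best, abundance = best_a)
}

# Random point on the unit simplex (normalized exponentials).
random_simplex <- function(m) {
  z <- rexp(m)
  z / sum(z)
}
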