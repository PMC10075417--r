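# Independent oracles used across test files. These deliberately re-derive
# quantities by brute force and must stay independent of the package's own
# code paths.

# Sheather-Jones solve-the-equation objective, written from the published
# fixed-point equation for a Gaussian kernel (pairwise sums, IQR scale
# estimate). The package's bandwidth is checked against the zero of this
# function located by grid search.
sj_objective_oracle <- function(x, h) {
  n <- length(x)
  phi4 <- function(u) (u^4 - 6 * u^2 + 3) * stats::dnorm(u)
  phi6 <- function(u) (u^6 - 15 * u^4 + 45 * u^2 - 15) * stats::dnorm(u)
  lambda <- stats::IQR(x)
  a <- 0.920 * lambda * n^(-1 / 7)
  b <- 0.912 * lambda * n^(-1 / 9)
  D <- outer(x, x, "-")
  TD <- -sum(phi6(D / b)) / (n * (n - 1) * b^7)
  SD <- sum(phi4(D / a)) / (n * (n - 1) * a^5)
  alpha2 <- 1.357 * (SD / TD)^(1 / 7) * h^(5 / 7)
  SD2 <- sum(phi4(D / alpha2)) / (n * (n - 1) * alpha2^5)
  (1 / (2 * sqrt(pi)) / (n * SD2))^(1 / 5) - h
}

sj_bandwidth_oracle <- function(x, h_grid = seq(0.01, 1, by = 0.002)) {
  obj <- vapply(h_grid, function(h) sj_objective_oracle(x, h), numeric(1))
  sgn <- sign(obj)
  flip <- which(sgn[-1] != sgn[-length(sgn)])[1]
  stopifnot(!is.na(flip))
  (h_grid[flip] + h_grid[flip + 1]) / 2
}

# Exhaustive threshold search for the highest-density region on a grid:
# for every candidate threshold (each observed density value), compute the
# mass of cells at or above it, and keep the largest threshold whose mass
# reaches the coverage.
hdr_threshold_oracle <- function(grid, dens, coverage) {
  dx <- grid[2] - grid[1]
  mass <- dens * dx
  mass <- mass / sum(mass)
  cand <- sort(unique(dens), decreasing = TRUE)
  best <- NA_real_
  for (t in cand) {
    if (sum(mass[dens >= t]) >= coverage) {
      best <- t
      break
    }
  }
  best
}

# Local convenience: a kde_model-like object from an analytic density, so
# hdr() can be exercised against closed-form quantiles.
analytic_density_model <- function(f, from, to, n = 4096) {
  grid <- seq(from, to, length.out = n)
  m <- list(grid = grid, density = f(grid), bandwidth = NA_real_,
            n = NA_integer_, input_range = c(from, to))
  class(m) <- "kde_model"
  m
}

expect_no_error <- function(expr) expect_error(expr, NA)
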