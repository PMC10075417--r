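test_that("SJ bandwidth agrees with a brute-force solve of the objective", {
  set.seed(42)
  x <- rnorm(200)
  h_pkg <- sj_bandwidth(x)
  h_oracle <- sj_bandwidth_oracle(x)
  expect_lt(abs(h_pkg - h_oracle) / h_oracle, 0.10)
})

test_that("SJ bandwidth is scale-equivariant and rejects degenerate input", {
  set.seed(7)
  x <- rnorm(100)
  expect_equal(sj_bandwidth(3 * x), 3 * sj_bandwidth(x), tolerance = 1e-6)
  expect_error(sj_bandwidth(rep(1, 50)), "degenerate")
  expect_error(sj_bandwidth(rnorm(5)), "at least 8")
})

test_that("fit_kde returns a normalised density on a 3-bandwidth grid", {
  # single kernel: unit Gaussian centred at the value
  m <- fit_kde(2.5, bandwidth = 1)
  expect_equal(m$grid[which.max(m$density)], 2.5, tolerance = 0.01)
  expect_equal(max(m$density), dnorm(0), tolerance = 0.01)
  expect_equal(m$grid[1], 2.5 - 3, tolerance = 1e-8)

  set.seed(11)
  x <- rnorm(10000)
  m <- fit_kde(x, bandwidth = "auto")
  at0 <- approx(m$grid, m$density, xout = 0)$y
  expect_lt(abs(at0 - 1 / sqrt(2 * pi)) / (1 / sqrt(2 * pi)), 0.05)

  for (vals in list(rnorm(50), rexp(200), runif(9))) {
    mm <- fit_kde(vals, bandwidth = 0.2)
    dx <- mm$grid[2] - mm$grid[1]
    expect_equal(sum(mm$density) * dx, 1, tolerance = 0.001)
  }
  expect_error(fit_kde(numeric(0)), "no finite values")
})

test_that("hdr reproduces analytic normal quantiles", {
  m <- analytic_density_model(dnorm, -6, 6)
  h95 <- hdr(m, 0.95)
  expect_equal(nrow(h95$intervals), 1)
  expect_equal(h95$intervals$lo, -1.96, tolerance = 0.02)
  expect_equal(h95$intervals$hi, 1.96, tolerance = 0.02)
  # nesting in coverage
  h99 <- hdr(m, 0.99)
  expect_lte(h99$intervals$lo, h95$intervals$lo)
  expect_gte(h99$intervals$hi, h95$intervals$hi)
})

test_that("hdr splits a bimodal density and matches the brute-force threshold", {
  f <- function(x) 0.5 * dnorm(x, -3, 0.5) + 0.5 * dnorm(x, 3, 0.5)
  m <- analytic_density_model(f, -6, 6)
  h <- hdr(m, 0.90)
  expect_equal(nrow(h$intervals), 2)
  expect_lt(h$intervals$hi[1], 0)
  expect_gt(h$intervals$lo[2], 0)
  t_oracle <- hdr_threshold_oracle(m$grid, m$density, 0.90)
  expect_equal(h$density_threshold, t_oracle, tolerance = 1e-12)
  # mode sits inside its interval
  expect_true(h$intervals$lo[h$mode_interval] <= h$mode &&
                h$mode <= h$intervals$hi[h$mode_interval])
})

test_that("hdr mass is within [coverage, coverage + 0.01] across cases", {
  set.seed(3)
  cases <- list(rnorm(300), c(rnorm(150, -2), rnorm(150, 2)), rexp(200))
  for (x in cases) {
    m <- fit_kde(x, bandwidth = "auto")
    for (cov in c(0.90, 0.95, 0.99)) {
      h <- hdr(m, cov)
      mass <- sum(h$intervals$mass)
      expect_gte(mass, cov)
      expect_lte(mass, cov + 0.01)
    }
  }
})

test_that("local_range recovers analytic normal bounds and behaves lawfully", {
  set.seed(123)
  x <- rnorm(300, 0.70950, 0.00050)
  rng <- local_range(x, coverage = 0.99)
  expect_equal(rng$lo, 0.70950 - qnorm(0.995) * 0.00050, tolerance = 3e-4)
  expect_equal(rng$hi, 0.70950 + qnorm(0.995) * 0.00050, tolerance = 3e-4)
  # translation equivariance (same draws, shifted)
  rng_shift <- local_range(x + 0.001, coverage = 0.99)
  expect_equal(rng_shift$lo, rng$lo + 0.001, tolerance = 2e-5)
  expect_equal(rng_shift$hi, rng$hi + 0.001, tolerance = 2e-5)
  # monotone in coverage
  rng95 <- local_range(x, coverage = 0.95)
  expect_lte(rng$lo, rng95$lo)
  expect_gte(rng$hi, rng95$hi)
  # full hull >= mode interval
  hull <- local_range(x, coverage = 0.99, anchor = "full_hull")
  expect_lte(hull$lo, rng$lo)
  expect_gte(hull$hi, rng$hi)
  # small reference sets warn
  expect_warning(local_range(rnorm(12, 0.7095, 5e-4)), "underestimate")
})
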