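make_diet_records <- function(n, d13c_mean = -19.7, d13c_sd = 0.4,
                              d15n_mean = 9.2, d15n_sd = 0.5,
                              site = "STB", prefix = site) {
  isotope_records(id = sprintf("%s_%03d", prefix, seq_len(n)), site = site,
                  age_class = "adult",
                  bone_d13c = rnorm(n, d13c_mean, d13c_sd),
                  bone_d15n = rnorm(n, d15n_mean, d15n_sd))
}

test_that("diet_variability recovers an analytic normal 99% interval", {
  set.seed(31)
  rec <- make_diet_records(1000, d13c_sd = 0.4)
  v <- diet_variability(rec)
  c13 <- v[v$isotope == "d13c", ]
  expect_equal(c13$lo, -19.7 - qnorm(0.995) * 0.4, tolerance = 0.02)
  expect_equal(c13$hi, -19.7 + qnorm(0.995) * 0.4, tolerance = 0.02)
  expect_equal(c13$mean, -19.7, tolerance = 0.05)
  expect_equal(c13$sd, 0.4, tolerance = 0.05)
})

test_that("pooling sites equals computing on concatenated values", {
  set.seed(32)
  a <- make_diet_records(40, site = "PEL")
  b <- make_diet_records(40, site = "UTH")
  pooled <- rbind(as.data.frame(a), as.data.frame(b))
  class(pooled) <- class(a)
  v_pool <- diet_variability(pooled)
  manual <- suppressWarnings(
    local_range(pooled$bone_d13c, coverage = 0.99))
  got <- v_pool[v_pool$isotope == "d13c", ]
  expect_equal(got$group, "PEL+UTH")
  expect_equal(got$lo, manual$lo)
  expect_equal(got$hi, manual$hi)
})

test_that("degenerate and small groups are handled explicitly", {
  rec <- isotope_records(id = c("a", "b", "c", "d", "e", "f", "g", "h"),
                         site = "STB", age_class = "adult",
                         bone_d13c = rep(-19.7, 8),
                         bone_d15n = rep(9.2, 8))
  expect_error(suppressWarnings(diet_variability(rec)), "degenerate")
  set.seed(33)
  small <- make_diet_records(5)
  expect_warning(diet_variability(small), "n = 5")
})

test_that("detect_outliers flags values outside the group HDI, boundary in", {
  variability <- data.frame(
    group = rep("STB", 2), isotope = c("d13c", "d15n"),
    lo = c(-20.8, 7.5), hi = c(-18.6, 10.9), coverage = 0.99,
    n = 30, mean = c(-19.7, 9.2), sd = c(0.4, 0.6))
  rec <- isotope_records(
    id = c("in", "hi13", "at_lo", "no_data"), site = "STB",
    bone_d13c = c(-19.5, -15.0, -20.8, NA),
    bone_d15n = c(9.0, 9.0, 9.0, NA))
  out <- detect_outliers(rec, variability, "bone")
  expect_equal(out$outlier, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$direction_d13c[2], "above")
  expect_true(is.na(out$direction_d13c[4]))
  # raising coverage never adds outliers
  wider <- variability
  wider$lo <- wider$lo - 0.5
  wider$hi <- wider$hi + 0.5
  out_wide <- detect_outliers(rec, wider, "bone")
  expect_lte(sum(out_wide$outlier), sum(out$outlier))
})

test_that("bone_dentine_deltas computes symmetric deltas and group means", {
  rec <- isotope_records(
    id = c("a", "b", "c"), site = "STB",
    bone_d13c = c(-19.0, -20.0, -19.5), bone_d15n = c(9.0, 9.5, 8.5),
    dentine_bulk_d13c = c(-16.0, -20.0, -19.5),
    dentine_bulk_d15n = c(10.0, 9.5, 8.5))
  res <- bone_dentine_deltas(rec, c(a = TRUE, b = FALSE, c = FALSE))
  expect_equal(res$deltas$delta_d13c, c(3.0, 0, 0))
  expect_true(all(res$deltas$delta_d13c >= 0))
  expect_equal(res$deltas$large_delta, c(TRUE, FALSE, FALSE))
  gm <- res$group_means
  expect_equal(gm$mean_delta_d13c[gm$notable], 3.0)
  expect_equal(gm$mean_delta_d13c[!gm$notable], 0.0)
  # identical tissues -> all deltas zero
  same <- bone_dentine_deltas(isotope_records(
    id = "z", site = "STB", bone_d13c = -19, bone_d15n = 9,
    dentine_bulk_d13c = -19, dentine_bulk_d15n = 9))
  expect_equal(same$deltas$delta_d13c, 0)
})

test_that("childhood-diet/notable association: concordance and null rate", {
  ids <- sprintf("i%02d", 1:20)
  concordant <- setNames(rep(c(TRUE, FALSE), each = 10), ids)
  res <- association_childhood_notable(concordant, concordant)
  expect_lt(res$p_value, 0.001)

  expect_error(association_childhood_notable(
    setNames(rep(FALSE, 20), ids), setNames(rep(FALSE, 20), ids)),
    "degenerate")

  # independent flags: rejection rate at alpha = .05 stays near nominal
  set.seed(35)
  n <- 200
  rejections <- 0
  valid <- 0
  for (r in 1:400) {
    a <- setNames(runif(n) < 0.3, sprintf("x%03d", 1:n))
    b <- setNames(runif(n) < 0.4, sprintf("x%03d", 1:n))
    p <- tryCatch(association_childhood_notable(a, b)$p_value,
                  error = function(e) NA_real_)
    if (!is.na(p)) {
      valid <- valid + 1
      rejections <- rejections + (p < 0.05)
    }
  }
  expect_gt(valid, 390)
  expect_lt(rejections / valid, 0.08)
  expect_gt(rejections / valid, 0.02)
})
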