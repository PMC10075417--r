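rg <- published_sr_ranges()

test_that("classify_individual reproduces the published example calls", {
  c1 <- classify_individual(0.71135, "STB", rg$regional, rg$macro)
  expect_equal(c1$status, "mobile")
  expect_match(c1$matched_regions, "REG")

  c2 <- classify_individual(0.71481, "AED", rg$regional, rg$macro)
  expect_equal(c2$status, "migrant")
  expect_equal(c2$direction, "above")

  expect_equal(classify_individual(0.70960, "STB", rg$regional,
                                   rg$macro)$status, "local")
  expect_equal(classify_individual(NA, "AED", rg$regional,
                                   rg$macro)$status, "indeterminate")
  expect_error(classify_individual(0.71, "NOPE", rg$regional, rg$macro),
               "unknown burial region")
})

test_that("burial-range bounds are inclusive; alternative matching is strict", {
  # exactly on the burial bound -> local (conservative non-local calling)
  expect_equal(classify_individual(0.71096, "STB", rg$regional,
                                   rg$macro)$status, "local")
  # exactly on another region's bound gives no positive match; outside the
  # macro range this is a migrant
  c9 <- classify_individual(0.71195, "MUC", rg$regional, rg$macro)
  expect_equal(c9$status, "migrant")
  # strictly inside another region -> mobile
  c8 <- classify_individual(0.71096, "MUC", rg$regional, rg$macro)
  expect_equal(c8$status, "mobile")
})

test_that("status partition and range-widening monotonicity hold", {
  set.seed(21)
  sim <- generate_cohort(synthetic_config(seed = 21))
  calls <- classify_records(sim$records)
  tab <- table(factor(calls$status, levels = c("local", "mobile", "migrant",
                                               "indeterminate")))
  expect_equal(sum(tab), nrow(sim$records))

  widened <- lapply(rg$regional, function(r) {
    r$lo <- r$lo - 0.0005; r$hi <- r$hi + 0.0005; r
  })
  calls_w <- classify_records(sim$records, widened, rg$macro)
  expect_lte(sum(calls_w$status %in% c("mobile", "migrant")),
             sum(calls$status %in% c("mobile", "migrant")))
})

test_that("with no alternative regions every out-of-macro non-local is a migrant", {
  only_burial <- rg$regional["AED"]
  vals <- c(0.7130, 0.7145, 0.7070)
  for (v in vals) {
    call <- classify_individual(v, "AED", only_burial, rg$macro)
    expect_equal(call$status, "migrant")
  }
})

test_that("wald_ci matches direct evaluation and truncates", {
  expect_equal(wald_ci(36, 156), c(0.1646538, 0.2968847), tolerance = 1e-6)
  expect_equal(wald_ci(0, 50), c(0, 0))
  expect_equal(wald_ci(25, 108), c(0.152, 0.311), tolerance = 1e-3)
  expect_equal(wald_ci(107, 108)[2] <= 1, TRUE)
  expect_error(wald_ci(1, 0), "positive")
})

test_that("summarize_cohort uses assessed denominators and groups correctly", {
  t2 <- published_cohort()
  calls <- classify_records(t2)
  s <- summarize_cohort(calls)
  expect_equal(s$n_assessed, sum(!is.na(t2$enamel_sr)))
  expect_equal(s$n_nonlocal, s$n_mobile + s$n_migrant)
  by_sex <- summarize_cohort(calls, "sex")
  expect_setequal(by_sex$group, unique(t2$sex))
  expect_equal(sum(by_sex$n_assessed), s$n_assessed)
  # all-local cohort: zero proportion, CI collapses at zero
  loc <- isotope_records(id = c("l1", "l2", "l3"), site = "STB",
                         enamel_sr = c(0.7095, 0.7090, 0.7089))
  sloc <- summarize_cohort(classify_records(assign_regions(loc)))
  expect_equal(sloc$n_nonlocal, 0)
  expect_equal(sloc$ci_lo, 0)
})

test_that("mfm_by_period counts adults outside the macro range per period", {
  periods <- data.frame(period = c("p1", "p2"), n = c(60, 60),
                        migrant_fraction = c(0, 0.5))
  sim <- generate_cohort(synthetic_config(seed = 5, mobile_fraction = 0,
                                          periods = periods))
  # REG's local variability exceeds the macro range, so (as in practice) it
  # is excluded from migrant-frequency calculations
  m <- mfm_by_period(sim$records, exclude_regions = "REG")
  expect_setequal(m$period, c("p1", "p2", "all"))
  expect_equal(m$mfm[m$period == "all"],
               sum(m$k[m$period != "all"]) / sum(m$n[m$period != "all"]))
  # few/no detections in the null period (HDI false positives only)
  expect_lte(m$mfm[m$period == "p1"], 0.05)
  expect_gt(m$mfm[m$period == "p2"], 0.25)

  # excluding a region removes its records everywhere
  expect_equal(m$n[m$period == "all"],
               sum(!is.na(sim$records$enamel_sr) &
                     sim$records$region != "REG" &
                     sim$records$age_class %in%
                       c("adult", "adult_mature", "mature", "mature_senile",
                         "senile")))
  # juveniles never enter
  m_all <- mfm_by_period(sim$records)
  juv <- sim$records
  juv$age_class[1] <- "juvenile"
  m_juv <- mfm_by_period(juv)
  expect_equal(m_juv$n[m_juv$period == "all"],
               m_all$n[m_all$period == "all"] - 1)
})

test_that("compare_groups is Pearson chi-square with Bonferroni post hoc", {
  flat <- compare_groups(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  r <- compare_groups(matrix(c(20, 40, 80, 60), 2))
  expect_equal(r$statistic, 9.5238, tolerance = 1e-4)
  expect_equal(r$p_value, 0.002, tolerance = 0.05)

  m3 <- matrix(c(10, 20, 30, 40, 35, 20), nrow = 3)
  ph <- compare_groups(m3, posthoc = "pairwise_bonferroni")
  expect_equal(nrow(ph$pairwise), 3)
  expect_equal(ph$pairwise$p_adjusted,
               pmin(1, 3 * ph$pairwise$p_raw))

  expect_error(compare_groups(matrix(c(0, 0, 5, 5), 2)), "degenerate")
})
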