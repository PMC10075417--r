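test_that("section ages tile the formation windows contiguously", {
  # M1, root-only sampling: six 1-year spans tiling 3.5-9.5
  ages <- assign_section_ages("M1", 6, crown_root_boundary = 0)
  expect_equal(ages$age_lo, seq(3.5, 8.5, 1))
  expect_equal(ages$age_hi, seq(4.5, 9.5, 1))
  expect_equal(unique(ages$part), "root")

  one <- assign_section_ages("M1", 1, crown_root_boundary = 0)
  expect_equal(one$age_mid, 6.5)
  expect_equal(c(one$age_lo, one$age_hi), c(3.5, 9.5))

  mixed <- assign_section_ages("M1", 10, crown_root_boundary = 4)
  expect_equal(mixed$part, rep(c("crown", "root"), c(4, 6)))
  expect_equal(mixed$age_hi[-10], mixed$age_lo[-1])     # contiguous
  expect_true(all(diff(mixed$age_mid) > 0))             # strictly increasing
  expect_true(all(mixed$age_lo[mixed$part == "root"] >= 3.5 &
                    mixed$age_hi[mixed$part == "root"] <= 9.5))

  expect_error(assign_section_ages("M1", 4, crown_root_boundary = 5),
               "crown_root_boundary")
})

test_that("finer sectioning gives a nested refinement of the same window", {
  coarse <- assign_section_ages("M2", 4, crown_root_boundary = 0)
  fine <- assign_section_ages("M2", 8, crown_root_boundary = 0)
  expect_equal(range(c(coarse$age_lo, coarse$age_hi)),
               range(c(fine$age_lo, fine$age_hi)))
  # every coarse edge reappears among the fine edges
  expect_true(all(coarse$age_lo %in% fine$age_lo))
})

test_that("bulk dentine is the unweighted mean of root sections", {
  p <- dentine_profile("x", "M1", d13c = c(-15, -16, -16, -16),
                       d15n = c(10, 9, 9, 9), crown_root_boundary = 1)
  expect_equal(unname(bulk_from_root_sections(p)["d13c"]), -16)
  p2 <- dentine_profile("y", "M1", d13c = c(-15, -17), d15n = c(9, 9),
                        crown_root_boundary = 0)
  expect_equal(unname(bulk_from_root_sections(p2)["d13c"]), -16)
  # crown values do not enter
  p3 <- dentine_profile("z", "M1", d13c = c(-10, -15, -17),
                        d15n = c(12, 9, 9), crown_root_boundary = 1)
  expect_equal(unname(bulk_from_root_sections(p3)["d13c"]), -16)
  rootless <- dentine_profile("w", "M1", d13c = -15, d15n = 9,
                              crown_root_boundary = 1)
  expect_error(bulk_from_root_sections(rootless), "no root sections")
})

test_that("detect_shifts finds step changes and range crossings near age 15", {
  # M3 root tiles 11-20 in 1-year sections; value steps -16.0 -> -19.5
  # between the sections centred at 14.5 and 15.5
  vals <- c(rep(-16.0, 4), rep(-19.5, 5))
  p <- dentine_profile("mig", "M3", d13c = vals, d15n = rep(9, 9),
                       crown_root_boundary = 0)
  hdi <- list(d13c = c(-21.0, -18.5), d15n = c(7, 11))
  ev <- detect_shifts(p, hdi, min_step = 1.5)
  step <- ev[ev$kind == "step_change", ]
  expect_equal(nrow(step), 1)
  expect_equal(step$age_years, 15)
  expect_equal(step$magnitude, 3.5)
  entry <- ev[ev$kind == "enter_local_range", ]
  expect_equal(nrow(entry), 1)
  expect_equal(entry$age_years, 15)

  # an infinite step threshold silences step events but not crossings
  ev_inf <- detect_shifts(p, hdi, min_step = Inf)
  expect_equal(unique(ev_inf$kind), "enter_local_range")

  flat <- dentine_profile("loc", "M1", d13c = rep(-19.7, 8),
                          d15n = rep(9.2, 8), crown_root_boundary = 3)
  expect_equal(nrow(detect_shifts(flat, hdi)), 0)
})

test_that("a weaning-only decline leaves the root window quiet", {
  set.seed(41)
  p <- simulate_profile("wean", "M1", n_crown = 4, n_root = 6,
                        baseline = c(d13c = -19.7, d15n = 9.2),
                        weaning_amplitude = c(d13c = 1.0, d15n = 2.0),
                        change_age = NA, noise_sd = 0.05)
  hdi <- list(d13c = c(-21.0, -18.3), d15n = c(7.4, 11.6))
  ev <- detect_shifts(p, hdi, min_step = 1.5)
  expect_true(nrow(ev) == 0 || all(ev$age_years <= 3.5))
})

test_that("profile round-trip through CSV preserves the sections", {
  p <- simulate_profile("rt", "M1", n_crown = 2, n_root = 4, noise_sd = 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(p)[, c("id", "tooth", "section_index", "part",
                                 "d13c", "d15n")], f, row.names = FALSE)
  back <- read_profiles(f)[[1]]
  expect_equal(back$d13c, p$d13c)
  expect_equal(back$age_mid, p$age_mid)
})
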