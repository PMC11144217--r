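test_that("invalid configurations are rejected with the violated constraint named", {
  expect_error(generator_config(n_pairs = 0), class = "gpad_config_error")
  expect_error(generator_config(prop_mz = 1.2), class = "gpad_config_error")
  expect_error(generator_config(ages = c(7, 9), gps_validity = c(0.3, 0.3),
                                attrition = c(0, 0)),
               "length >= 3", class = "gpad_config_error")
  expect_error(generator_config(ages = c(7, 9, 9, 16)),
               "strictly increasing", class = "gpad_config_error")
  expect_error(generator_config(a2 = 0.8, c2 = 0.3), "a2 \\+ c2",
               class = "gpad_config_error")
  expect_error(generator_config(gps_validity = c(0.28, 0.27, 0.26, 1.2)),
               "gps_validity", class = "gpad_config_error")
  # implied genetic loading above 1: validity too high for kappa * sqrt(a2)
  expect_error(generator_config(kappa = 0.4, a2 = 0.5,
                                gps_validity = c(0.28, 0.27, 0.26, 0.43)),
               "genetic loading", class = "gpad_config_error")
  # negative residual variance
  expect_error(generator_config(stability = 0.9), class = "gpad_config_error")
  expect_error(generator_config(attrition = c(0.3, 0.65, 0.5, 1)),
               "attrition", class = "gpad_config_error")
})

test_that("cohort structure invariants hold", {
  coh <- small_cohort()
  expect_equal(nrow(coh), 2 * 1500)
  expect_false(any(duplicated(coh$individual_id)))
  tab <- table(coh$family_id)
  expect_true(all(tab == 2))
  # identical zygosity within family
  z1 <- coh$zygosity[seq(1, nrow(coh), 2)]
  z2 <- coh$zygosity[seq(2, nrow(coh), 2)]
  expect_identical(z1, z2)
  expect_true(all(coh$zygosity %in% c("MZ", "DZ")))
  expect_true(all(coh$sex %in% 0:1))
  # MZ pairs are same-sex
  mz <- coh$zygosity == "MZ"
  expect_identical(coh$sex[mz & seq_len(nrow(coh)) %% 2 == 1],
                   coh$sex[mz & seq_len(nrow(coh)) %% 2 == 0])
  # science age 7 structurally missing; every other achievement column observed
  expect_true(all(is.na(coh$ach_science_7)))
  other <- setdiff(grep("^ach_", names(coh), value = TRUE), "ach_science_7")
  for (cn in other) expect_gt(sum(!is.na(coh[[cn]])), 0)
})

test_that("same seed reproduces bit-exactly; different seeds differ; families are seed-stable under n_pairs changes", {
  cfg <- generator_config(n_pairs = 60, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  attr(a, "config") <- NULL; attr(b, "config") <- NULL
  expect_identical(a, b)
  c2 <- generate_cohort(generator_config(n_pairs = 60, seed = 100))
  expect_false(identical(a$gps, c2$gps))
  # growing the cohort leaves earlier families untouched
  big <- generate_cohort(generator_config(n_pairs = 120, seed = 99))
  expect_identical(a$gps, big$gps[seq_len(nrow(a))])
  expect_identical(a$ach_math_16, big$ach_math_16[seq_len(nrow(a))])
})

test_that("attrition controls the missing fraction", {
  coh0 <- small_cohort()
  non_structural <- setdiff(grep("^ach_", names(coh0), value = TRUE),
                            "ach_science_7")
  expect_identical(sum(is.na(coh0[non_structural])), 0L)
  p <- c(0.1, 0.5, 0.2, 0.3)
  coh <- generate_cohort(generator_config(n_pairs = 2000, attrition = p, seed = 5))
  for (t in seq_along(p)) {
    age <- c(7, 9, 12, 16)[t]
    frac <- mean(is.na(coh[[paste0("ach_math_", age)]]))
    se <- sqrt(p[t] * (1 - p[t]) / nrow(coh))
    expect_lt(abs(frac - p[t]), 4 * se)
  }
})

test_that("theoretical covariance examples", {
  cfg <- generator_config(attrition = c(0, 0, 0, 0))
  th <- theoretical_covariance(cfg)
  # corr(GPS, achievement_t) equals the configured validity exactly
  expect_equal(unname(th["gps", paste0("ach_", c(7, 9, 12, 16))]),
               c(0.28, 0.27, 0.26, 0.43))
  # kappa = 0.6, validity 0.28 -> genetic loading 0.28/0.6
  expect_equal(gpadelta:::config_loadings(cfg)$b[1], 0.28 / 0.6,
               tolerance = 1e-12)
  # no shared environment, no SES loadings -> SES uncorrelated with achievement
  cfg0 <- generator_config(c2 = 0, ses_load_c = 0, ses_load_g = 0,
                           stability = 0.45)
  th0 <- theoretical_covariance(cfg0)
  expect_equal(unname(th0["ses", paste0("ach_", c(7, 9, 12, 16))]), rep(0, 4))
  expect_true(isSymmetric(th))
  expect_equal(unname(diag(th)), rep(1, 6))
})

test_that("degenerate noiseless configuration makes achievement equal the score", {
  cfg <- generator_config(n_pairs = 50, kappa = 1, a2 = 1, c2 = 0,
                          stability = 0, gps_validity = rep(1, 4),
                          attrition = c(0, 0, 0, 0), ses_load_g = 0,
                          science_missing_age7 = FALSE, seed = 2)
  coh <- generate_cohort(cfg)
  for (cn in grep("^ach_", names(coh), value = TRUE)) {
    expect_equal(coh[[cn]], coh$gps, tolerance = 1e-12)
  }
})

test_that("stable-propensity twin resemblance matches its ACE closed form", {
  cfg <- generator_config(n_pairs = 5000, a2 = 0.85, c2 = 0.05,
                          attrition = c(0, 0, 0, 0), seed = 31)
  coh <- generate_cohort(cfg)
  pairs <- twin_pairs(coh, "propensity")
  r_mz <- intraclass_corr(pairs, "MZ")$r
  r_dz <- intraclass_corr(pairs, "DZ")$r
  expect_lt(abs(r_mz - 0.90), 0.03)   # a2 + c2
  expect_lt(abs(r_dz - 0.475), 0.03)  # 0.5 a2 + c2
})

test_that("MZ resemblance exceeds DZ resemblance for achievement at every age", {
  coh <- generate_cohort(generator_config(n_pairs = 4000,
                                          attrition = c(0, 0, 0, 0), seed = 8))
  for (age in c(7, 9, 12, 16)) {
    pairs <- twin_pairs(coh, paste0("ach_math_", age))
    expect_gt(intraclass_corr(pairs, "MZ")$r, intraclass_corr(pairs, "DZ")$r)
  }
})

test_that("cohort CSV round trip preserves values and missingness", {
  coh <- generate_cohort(generator_config(n_pairs = 30, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$gps, coh$gps, tolerance = 1e-12)
  expect_identical(is.na(back$ach_math_9), is.na(coh$ach_math_9))
  expect_identical(back$individual_id, coh$individual_id)
})
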