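test_that("trimmed_mean follows the floor(n*trim)-per-tail rule and matches the sort-drop oracle", {
  expect_equal(trimmed_mean(1:20, 0.05), 10.5)
  expect_equal(trimmed_mean(rep(3.2, 7), 0.2), 3.2)
  set.seed(9)
  x <- rnorm(33)
  expect_equal(trimmed_mean(x, 0), mean(x))
  expect_error(trimmed_mean(numeric(0)), class = "gpad_empty_error")
  expect_error(trimmed_mean(1:5, 0.5), class = "gpad_validation_error")
  for (i in 1:500) {
    n <- sample(3:60, 1)
    x <- rnorm(n, sd = sample(1:10, 1))
    trim <- runif(1, 0, 0.45)
    expect_equal(trimmed_mean(x, trim), oracle_trimmed_mean(x, trim),
                 tolerance = 1e-12)
  }
})

test_that("regression percentages follow the printed formula", {
  expect_equal(regression_percentage(1, 0, trim = 0)$percent, 100)
  expect_equal(regression_percentage(-2, -1, trim = 0)$percent, 50)
  expect_equal(regression_percentage(0.5, 0.75, trim = 0)$percent, -50)
  # scale invariance: common rescaling leaves every percentage unchanged
  set.seed(10)
  d7 <- rnorm(100); d16 <- rnorm(100)
  p1 <- regression_percentage(d7, d16)$percent
  p2 <- regression_percentage(d7 * 3.7, d16 * 3.7)$percent
  expect_equal(p1, p2, tolerance = 1e-10)
  # eps exclusion
  r <- regression_percentage(c(1, 1e-8, -1), c(0.5, 5, -0.2), trim = 0,
                             eps = 1e-3)
  expect_equal(r$n_used, 2L)
  expect_equal(r$summary, mean(c(50, 80)))
  expect_error(regression_percentage(c(0, 0), c(1, 1), trim = 0, eps = 1),
               class = "gpad_empty_error")
})

test_that("group classification reproduces the threshold definitions exactly", {
  delta <- zs(c(-1.5, -1.2, 0, 0.3, 1.4, 1.6, -0.1, 0.2, -0.4, 0.1))
  ach <- zs(c(0, -1.4, 0.2, 0, 1.3, 0.1, 0, 0, -1.2, 1.0))
  g <- classify_groups(delta, ach)
  m <- mean(delta); s <- sd(delta)
  for (i in seq_along(delta)) {
    expected_rel <- if (delta[i] <= m - s) "underachiever" else
      if (delta[i] >= m + s) "overachiever" else "none"
    expect_identical(g$relative_group[i], expected_rel)
    expected_abs <- if (expected_rel == "underachiever" && ach[i] <= -1) {
      "underachiever"
    } else if (expected_rel == "overachiever" && ach[i] >= 1) {
      "overachiever"
    } else "none"
    expect_identical(g$absolute_group[i], expected_abs)
  }
  # absolute groups are subsets of the matching relative groups
  expect_true(all(g$relative_group[g$absolute_group == "underachiever"] ==
                    "underachiever"))
  expect_true(all(g$relative_group[g$absolute_group == "overachiever"] ==
                    "overachiever"))
})

test_that("classification validates centering and scaling", {
  set.seed(11)
  d <- rnorm(50); a <- zs(rnorm(50))
  expect_error(classify_groups(d + 5, a), class = "gpad_validation_error")
  expect_error(classify_groups(zs(d), a * 4), class = "gpad_validation_error")
})

test_that("decile sizes differ by at most one, including the N = 1981 case", {
  set.seed(12)
  for (n in c(1981, 100, 103, 57)) {
    delta <- rnorm(n)
    sizes <- table(gpadelta:::assign_deciles(delta, seq_len(n)))
    expect_equal(length(sizes), 10L)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_equal(sum(sizes), n)
  }
  # 1981 -> nine groups of 198 and one of 199
  sizes <- table(gpadelta:::assign_deciles(rnorm(1981), 1:1981))
  expect_setequal(as.integer(sizes), c(199L, rep(198L, 9)))
})

test_that("decile trajectories separate under age-increasing validity and flatten under a null delta", {
  coh <- small_cohort()
  ages <- c(7, 9, 12, 16)
  comp <- sapply(ages, function(t) {
    cols <- paste0("ach_", c("english", "math", "science"), "_", t)
    cols <- cols[colSums(!is.na(coh[cols])) > 0]
    composite(sapply(coh[cols], zscore), min_subjects = 2)
  })
  colnames(comp) <- ages
  gpa <- delta(comp[, 1], zscore(coh$gps), check = FALSE)
  dt <- decile_trajectories(gpa, comp, ages = ages, band = 0.5)
  expect_lte(max(table(dt$assignment$decile)) - min(table(dt$assignment$decile)), 1)
  # most-underachieving decile trends up, most-overachieving trends down
  expect_gt(dt$lines$slope[dt$lines$decile == 1], 0)
  expect_lt(dt$lines$slope[dt$lines$decile == 10], 0)
  # monotone-ish ordering of fitted slopes overall
  expect_lt(cor(dt$lines$decile, dt$lines$slope), 0)
  # null case: delta independent of achievement -> flat decile lines
  set.seed(13)
  noise_delta <- rnorm(nrow(comp))
  dt0 <- decile_trajectories(noise_delta, comp, ages = ages, band = 0.5)
  expect_lt(max(abs(dt0$lines$slope)), 0.03)
  expect_error(decile_trajectories(gpa[1:5], comp[1:5, ], ages = ages),
               class = "gpad_insufficient_data")
})

test_that("group trajectory summary: sign structure, subset extremity, empty groups", {
  coh <- small_cohort()
  ages <- c(7, 9, 12, 16)
  comp <- sapply(ages, function(t) {
    cols <- paste0("ach_", c("english", "math", "science"), "_", t)
    cols <- cols[colSums(!is.na(coh[cols])) > 0]
    composite(sapply(coh[cols], zscore), min_subjects = 2)
  })
  colnames(comp) <- ages
  gpsz <- zscore(coh$gps)
  gpa7 <- delta(comp[, 1], gpsz, check = FALSE)
  gpa16 <- delta(comp[, 4], gpsz, check = FALSE)
  groups <- classify_groups(gpa7, comp[, 1])
  gs <- group_trajectory_summary(groups, comp, gpa7, gpa16, ages = ages)
  tr <- gs$trajectory
  pick <- function(g, a) tr$mean[tr$group == g & tr$age == a]
  # underachievers rise toward the prediction, overachievers fall
  expect_gt(pick("relative_underachiever", 16), pick("relative_underachiever", 7))
  expect_lt(pick("relative_overachiever", 16), pick("relative_overachiever", 7))
  # absolute groups start more extreme than their relative supersets
  expect_lt(pick("absolute_underachiever", 7), pick("relative_underachiever", 7))
  expect_gt(pick("absolute_overachiever", 7), pick("relative_overachiever", 7))
  # all four groups regressed by a positive percentage, in both modes
  expect_true(all(gs$regression$pct_from_means > 0))
  expect_true(all(gs$regression$pct_individual > 0))
  # all-zero deltas -> no members, NA summaries, no error
  zero <- classify_groups(rep(0, nrow(comp)), comp[, 1], check = FALSE)
  gs0 <- group_trajectory_summary(zero, comp, gpa7, gpa16, ages = ages)
  expect_true(all(gs0$regression$n == 0))
  expect_true(all(is.na(gs0$regression$pct_from_means)))
})
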