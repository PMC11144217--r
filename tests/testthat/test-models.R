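test_that("pearson_ci matches the Fisher-z arithmetic", {
  set.seed(14)
  x <- rnorm(50)
  p <- pearson_ci(x, 2 * x + 1)
  expect_equal(p$r, 1)
  expect_equal(p$upper, 1)
  # frozen example: r = 0.5, n = 100 -> CI approx (0.337, 0.634)
  # construct data with exactly r = 0.5 via Cholesky-style mixing
  y0 <- rnorm(100)
  x0 <- rnorm(100)
  y0 <- resid(lm(y0 ~ x0))
  xs <- zs(x0); ys <- zs(y0)
  yr <- 0.5 * xs + sqrt(1 - 0.25) * ys
  p2 <- pearson_ci(xs, yr)
  expect_equal(p2$r, 0.5, tolerance = 1e-10)
  expect_equal(p2$lower, tanh(atanh(0.5) - qnorm(0.975) / sqrt(97)),
               tolerance = 1e-12)
  expect_equal(round(c(p2$lower, p2$upper), 3), c(0.337, 0.634))
  # agreement with cor.test
  ct <- cor.test(xs, yr)
  expect_equal(p2$p, ct$p.value, tolerance = 1e-12)
  # null case: CI covers 0
  set.seed(15)
  a <- rnorm(2000); b <- sample(a)
  p3 <- pearson_ci(a, b)
  expect_true(p3$lower < 0 && p3$upper > 0)
  expect_error(pearson_ci(rep(1, 10), rnorm(10)), class = "gpad_degenerate_error")
})

test_that("hierarchical regression matches the normal-equations oracle on random designs", {
  set.seed(16)
  for (i in 1:100) {
    n <- 50
    d <- data.frame(y = rnorm(n), f = rnorm(n), c1 = rnorm(n), c2 = rnorm(n),
                    c3 = rnorm(n))
    h <- hierarchical_regression(d, "y", "f", list(c("c1"), c("c2", "c3")))
    # model 1
    o1 <- oracle_ols(d$y, d[, "f", drop = FALSE])
    expect_equal(h[[1]]$r2, o1$r2, tolerance = 1e-10)
    expect_equal(h[[1]]$semipartial_r2, o1$r2, tolerance = 1e-10)
    expect_equal(h[[1]]$coefficients$estimate, unname(o1$beta), tolerance = 1e-10)
    # full model
    of <- oracle_ols(d$y, d[, c("f", "c1", "c2", "c3")])
    owof <- oracle_ols(d$y, d[, c("c1", "c2", "c3")])
    expect_equal(h[[3]]$r2, of$r2, tolerance = 1e-10)
    expect_equal(h[[3]]$semipartial_r2, of$r2 - owof$r2, tolerance = 1e-10)
    # nested F from residual sums of squares
    f_oracle <- ((o1$rss - of$rss) / 3) / (of$rss / (n - 5))
    expect_equal(h[[3]]$f, f_oracle, tolerance = 1e-10)
    expect_equal(h[[3]]$df1, 3L)
    expect_equal(h[[3]]$df2, n - 5L)
    # invariants
    expect_gte(h[[3]]$semipartial_r2, 0)
    expect_lte(h[[3]]$semipartial_r2, h[[3]]$r2 + 1e-12)
    expect_gte(h[[3]]$f, 0)
  }
})

test_that("hierarchical regression degenerate cases", {
  set.seed(17)
  n <- 200
  f <- rnorm(n)
  # covariate orthogonal to focal and outcome: semi-partial R2 barely moves
  y <- 0.5 * f + rnorm(n, sd = 0.5)
  c1 <- resid(lm(rnorm(n) ~ f + y))
  d <- data.frame(y = y, f = f, c1 = c1)
  h <- hierarchical_regression(d, "y", "f", list("c1"))
  expect_equal(h[[1]]$semipartial_r2, h[[2]]$semipartial_r2, tolerance = 1e-6)
  expect_lt(h[[2]]$delta_r2, 1e-6)
  # outcome == focal: R2 = 1 and added covariates contribute nothing
  d2 <- data.frame(y = f, f = f, c1 = rnorm(n))
  h2 <- suppressWarnings(hierarchical_regression(d2, "y", "f", list("c1")))
  expect_equal(h2[[1]]$r2, 1, tolerance = 1e-12)
  expect_equal(h2[[2]]$delta_r2, 0, tolerance = 1e-10)
  # rank-deficient design names the aliased column
  d3 <- data.frame(y = rnorm(n), f = f, c1 = f)
  expect_error(hierarchical_regression(d3, "y", "f", list("c1")),
               "c1", class = "gpad_collinearity_error")
})

test_that("moderation test recovers strong interactions, nulls, and rejects constant moderators", {
  set.seed(18)
  n <- 500
  d <- data.frame(f = rnorm(n), m = rnorm(n))
  d$y <- zs(d$f) * zs(d$m)  # outcome IS the interaction
  mt <- suppressWarnings(moderation_test(d, "y", "f", "m"))
  expect_equal(mt$interaction$estimate, 1, tolerance = 1e-6)
  expect_lt(mt$interaction$p, 1e-10)
  d$m0 <- 1
  expect_error(moderation_test(d, "y", "f", "m0"), class = "gpad_degenerate_error")
  # coverage under a zero-interaction world; 200 replicates keep the
  # Monte-Carlo error of the coverage estimate itself below ~1.6%
  cover <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    f <- rnorm(800); m <- rnorm(800)
    y <- 0.4 * f + 0.3 * m + rnorm(800)
    ci <- moderation_test(data.frame(y = y, f = f, m = m), "y", "f", "m")$interaction
    if (ci$lower <= 0 && ci$upper >= 0) cover <- cover + 1
  }
  expect_gte(cover / reps, 0.90)
})

test_that("vif matches the direct formula", {
  set.seed(19)
  n <- 400
  # orthogonalized predictors -> VIF 1
  x1 <- rnorm(n); x2 <- resid(lm(rnorm(n) ~ x1))
  v <- vif(cbind(a = x1, b = x2))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-10)
  # two predictors with r = 0.8 -> VIF = 1/(1 - 0.64)
  z1 <- zs(x1); z2 <- zs(x2)
  y2 <- 0.8 * z1 + sqrt(1 - 0.64) * z2
  v2 <- vif(cbind(z1, y2))
  expect_equal(unname(v2), rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  # perfect collinearity -> Inf with warning
  # both aliased columns warn; capture them all
  expect_warning(expect_warning(v3 <- vif(cbind(x1, 2 * x1, x2)), "collinear"))
  expect_true(is.infinite(v3[1]) || is.infinite(v3[2]))
  expect_error(vif(cbind(x1)), class = "gpad_validation_error")
})

test_that("multi-score cross-validation recovers signal and reports honest held-out R2", {
  set.seed(20)
  n <- 600
  G <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  # one informative score among four noise scores
  y <- 0.6 * G[, 3] + rnorm(n, sd = 0.8)
  cv <- multi_gps_weights(G, y, k = 10, repeats = 3, seed = 5)
  expect_gt(abs(cv$weights["s3"]), 3 * max(abs(cv$weights[c("s1", "s2", "s4", "s5")])))
  expect_equal(length(cv$cv_r2), 30L)
  expect_lte(cv$cv_r2_mean, cv$in_sample_r2 + 0.05)
  # exact linear combination -> held-out R2 ~ 1 and weights recovered
  y2 <- drop(G %*% c(0.2, -0.4, 0.1, 0.3, -0.2))
  cv2 <- suppressWarnings(  # lm warns on the deliberately exact fit
    multi_gps_weights(G, y2, k = 10, repeats = 1, seed = 5))
  expect_gt(cv2$cv_r2_mean, 0.999)
  expect_equal(unname(cv2$weights), c(0.2, -0.4, 0.1, 0.3, -0.2),
               tolerance = 1e-8)
  expect_true(all(is.finite(cv2$vif)) && all(cv2$vif >= 1))
})

test_that("cross-validated R2 does not beat in-sample R2 on average", {
  set.seed(21)
  diffs <- replicate(50, {
    n <- 150
    G <- matrix(rnorm(n * 3), n, 3)
    y <- 0.3 * G[, 1] + rnorm(n)
    cv <- multi_gps_weights(G, y, k = 5, repeats = 1, seed = sample.int(1e6, 1))
    cv$in_sample_r2 - cv$cv_r2_mean
  })
  expect_gt(mean(diffs), 0)
})

test_that("joint two-delta regression: orthogonal decomposition, oracle agreement, collinearity", {
  set.seed(22)
  n <- 1000
  x1 <- zs(rnorm(n)); x2 <- zs(resid(lm(rnorm(n) ~ x1)))
  y <- 0.5 * x1 - 0.3 * x2 + rnorm(n, sd = 0.6)
  j <- joint_delta_regression(y, x1, x2)
  r1 <- cor(y, x1); r2 <- cor(y, x2)
  expect_equal(j$r2, r1^2 + r2^2, tolerance = 1e-10)  # orthogonal predictors
  o <- oracle_ols(y, cbind(x1, x2))
  expect_equal(j$coefficients$estimate, unname(o$beta), tolerance = 1e-10)
  # perfectly collinear predictors: drop one, R2 equals single-predictor fit
  expect_warning(jc <- joint_delta_regression(y, x1, x1), "collinear")
  expect_equal(jc$r2, cor(y, x1)^2, tolerance = 1e-10)
  expect_true(jc$aliased)
})

test_that("dependent-correlation comparison agrees with a bootstrap oracle and behaves at the extremes", {
  same <- compare_correlations(0.4, 0.4, 500, overlap = 0.3)
  expect_equal(same$diff, 0)
  expect_true(same$lower < 0 && same$upper > 0)
  far <- compare_correlations(0.9, 0.1, 1000, overlap = 0.05)
  expect_true(far$different)
  expect_error(compare_correlations(1, 0.5, 100, 0.2), class = "gpad_validation_error")
  # bootstrap oracle on a seeded trivariate normal sample
  set.seed(23)
  n <- 800
  S <- matrix(c(1, 0.45, 0.25, 0.45, 1, 0.35, 0.25, 0.35, 1), 3, 3)
  L <- chol(S)
  X <- matrix(rnorm(n * 3), n, 3) %*% L
  r1 <- cor(X[, 1], X[, 2]); r2 <- cor(X[, 1], X[, 3]); r12 <- cor(X[, 2], X[, 3])
  zou <- compare_correlations(r1, r2, n, r12)
  boots <- replicate(2000, {
    idx <- sample.int(n, replace = TRUE)
    cor(X[idx, 1], X[idx, 2]) - cor(X[idx, 1], X[idx, 3])
  })
  bq <- quantile(boots, c(0.025, 0.975))
  expect_lt(abs(zou$lower - bq[[1]]), 0.01)
  expect_lt(abs(zou$upper - bq[[2]]), 0.01)
})
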