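# Independent brute-force oracles. These deliberately avoid the package's own
# code paths: explicit normal equations, sort-and-drop means, double loops.

# OLS by explicit normal equations; returns coefficients, R2, RSS.
oracle_ols <- function(y, X) {
  Xd <- cbind(1, as.matrix(X))
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  fitted <- Xd %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  list(beta = drop(beta), r2 = 1 - rss / tss, rss = rss)
}

# Trimmed mean by sort-and-slice.
oracle_trimmed_mean <- function(x, trim) {
  x <- x[!is.na(x)]
  m <- floor(length(x) * trim)
  s <- sort(x)
  mean(s[seq(m + 1, length(x) - m)])
}

# MAD filter mask by a double loop.
oracle_mad_mask <- function(x, k = 3) {
  med <- median(x)
  devs <- numeric(length(x))
  for (i in seq_along(x)) devs[i] <- abs(x[i] - med)
  m <- median(devs)
  keep <- logical(length(x))
  for (i in seq_along(x)) keep[i] <- devs[i] <= k * m
  keep
}

# Inclusion-filter count by enumeration over individuals.
oracle_inclusion_keep <- function(avail_counts, min_subjects, min_obs) {
  keep <- logical(nrow(avail_counts))
  for (i in seq_len(nrow(avail_counts))) {
    n_ages <- 0
    for (t in seq_len(ncol(avail_counts))) {
      if (avail_counts[i, t] >= min_subjects) n_ages <- n_ages + 1
    }
    keep[i] <- n_ages >= min_obs
  }
  keep
}

# Direct simulation of exchangeable twin pairs with a given within-pair
# correlation (unit variance), via the sum/difference construction.
sim_twin_pairs <- function(n, r_within) {
  s <- rnorm(n, 0, sqrt(1 + r_within))
  d <- rnorm(n, 0, sqrt(1 - r_within))
  cbind(t1 = (s + d) / sqrt(2), t2 = (s - d) / sqrt(2))
}

# Small standardized helper for tests.
zs <- function(x) (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)

# A small cached cohort shared across test files (attrition-free).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_pairs = 1500, attrition = c(0, 0, 0, 0),
                              seed = 424242)
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})
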