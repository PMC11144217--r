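# Regression machinery: correlation CIs, hierarchical regression with
# semi-partial R^2 and nested F tests, moderation, VIF, repeated
# cross-validated multi-score weighting, and dependent-correlation comparison.

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @param alpha Two-sided error rate (default 0.05 for a 95% CI).
#' @return List with `r`, `lower`, `upper`, `p` (t test) and `n`.
#' @export
#' @examples
#' set.seed(1); x <- rnorm(100)
#' pearson_ci(x, x + rnorm(100))
pearson_ci <- function(x, y, alpha = 0.05) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) gpad_stop("pearson_ci: need >= 4 complete pairs", "gpad_insufficient_data")
  if (sd(x) == 0 || sd(y) == 0) {
    gpad_stop("pearson_ci: constant input", "gpad_degenerate_error")
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    lo <- hi <- r
    p <- 0
  } else {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    crit <- qnorm(1 - alpha / 2)
    lo <- tanh(z - crit * se); hi <- tanh(z + crit * se)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, lower = lo, upper = hi, p = p, n = n)
}

# R^2 of an OLS fit of y on the columns of X (intercept added), complete
# cases assumed. Rank deficiency raises a collinearity error naming columns.
.ols_r2 <- function(y, X) {
  if (is.null(X) || ncol(X) == 0) return(list(r2 = 0, rss = sum((y - mean(y))^2),
                                              p = 0))
  fit <- lm(y ~ ., data = as.data.frame(X))
  cf <- coef(fit)
  if (anyNA(cf)) {
    gpad_stop(paste0("collinear (aliased) predictors: ",
                     paste(names(cf)[is.na(cf)], collapse = ", ")),
              "gpad_collinearity_error")
  }
  rss <- sum(resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  list(r2 = 1 - rss / tss, rss = rss, p = ncol(X), fit = fit)
}

#' Hierarchical regression with semi-partial R-squared of a focal predictor
#'
#' Fits a sequence of nested OLS models: Model 1 contains only the focal
#' predictor; each subsequent model adds one covariate block. For every model
#' the focal predictor's semi-partial (increment-to-R-squared) contribution is
#' `R2(model) - R2(model without focal)`, and a nested F test compares each
#' model against Model 1 via residual sums of squares. Complete-case analysis
#' throughout.
#'
#' @param data Data frame holding all variables.
#' @param outcome Name of the outcome column.
#' @param focal Name of the focal predictor column.
#' @param covariate_blocks List of character vectors; each element is the
#'   block of covariates added at that step (default: no blocks, Model 1
#'   only).
#' @param conf Confidence level for coefficient CIs.
#' @return A list of class `gpad_hreg`: one element per model with
#'   `predictors`, `coefficients` (estimate, std beta, CI, p), `r2`,
#'   `semipartial_r2` (of the focal predictor), and — for models after the
#'   first — `delta_r2`, `f`, `df1`, `df2`, `p_f` versus Model 1. Also
#'   carries `n` (complete cases).
#' @export
hierarchical_regression <- function(data, outcome, focal,
                                    covariate_blocks = list(), conf = 0.95) {
  vars <- c(outcome, focal, unlist(covariate_blocks))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    gpad_stop(paste0("hierarchical_regression: missing columns: ",
                     paste(missing_cols, collapse = ", ")), "gpad_validation_error")
  }
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(d)
  if (n < length(vars) + 2) {
    gpad_stop("hierarchical_regression: too few complete cases", "gpad_insufficient_data")
  }
  y <- d[[outcome]]
  preds <- focal
  models <- list()
  base <- NULL
  for (step in seq_len(length(covariate_blocks) + 1L)) {
    if (step > 1) preds <- c(preds, covariate_blocks[[step - 1L]])
    X <- d[, preds, drop = FALSE]
    full <- .ols_r2(y, X)
    wo <- .ols_r2(y, d[, setdiff(preds, focal), drop = FALSE])
    fit <- full$fit
    sm <- summary(fit)$coefficients
    crit <- qnorm(1 - (1 - conf) / 2)
    ct <- data.frame(
      term = rownames(sm),
      estimate = sm[, 1],
      std_beta = c(NA, sm[-1, 1] * vapply(preds, function(p) sd(d[[p]]), 0) / sd(y)),
      lower = sm[, 1] - crit * sm[, 2],
      upper = sm[, 1] + crit * sm[, 2],
      p = sm[, 4],
      row.names = NULL
    )
    rep <- list(
      predictors = preds,
      coefficients = ct,
      r2 = full$r2,
      semipartial_r2 = full$r2 - wo$r2,
      rss = full$rss,
      n = n
    )
    if (step == 1) {
      base <- rep
    } else {
      df1 <- length(preds) - length(base$predictors)
      df2 <- n - length(preds) - 1L
      f <- ((base$rss - full$rss) / df1) / (full$rss / df2)
      rep$delta_r2 <- full$r2 - base$r2
      rep$f <- f; rep$df1 <- df1; rep$df2 <- df2
      rep$p_f <- pf(f, df1, df2, lower.tail = FALSE)
    }
    models[[step]] <- rep
  }
  structure(models, class = "gpad_hreg", n = n)
}

#' SES (or other) moderation of a focal association
#'
#' Standardizes the focal predictor and moderator, forms their product, and
#' fits `outcome ~ focal + moderator + covariates + focal:moderator`. The
#' interaction coefficient (with CI and p) is the moderation test.
#'
#' @param data Data frame.
#' @param outcome,focal,moderator Column names.
#' @param covariates Optional character vector of additional covariates.
#' @param conf Confidence level.
#' @return List with `interaction` (estimate, lower, upper, p), `model`
#'   (the full `lm` fit) and `n`.
#' @export
moderation_test <- function(data, outcome, focal, moderator,
                            covariates = NULL, conf = 0.95) {
  vars <- c(outcome, focal, moderator, covariates)
  d <- data[complete.cases(data[vars]), vars, drop = FALSE]
  if (nrow(d) < length(vars) + 3) {
    gpad_stop("moderation_test: too few complete cases", "gpad_insufficient_data")
  }
  if (sd(d[[moderator]]) == 0) {
    gpad_stop("moderation_test: moderator is constant, no moderation estimable",
              "gpad_degenerate_error")
  }
  if (sd(d[[focal]]) == 0) {
    gpad_stop("moderation_test: focal predictor is constant", "gpad_degenerate_error")
  }
  d$..f <- zscore(d[[focal]])
  d$..m <- zscore(d[[moderator]])
  d$..fm <- d$..f * d$..m
  rhs <- c("..f", "..m", covariates, "..fm")
  fml <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- lm(fml, data = d)
  sm <- summary(fit)$coefficients
  row <- unname(sm["..fm", ])
  crit <- qnorm(1 - (1 - conf) / 2)
  list(
    interaction = list(estimate = row[1], lower = row[1] - crit * row[2],
                       upper = row[1] + crit * row[2], p = row[4]),
    model = fit,
    n = nrow(d)
  )
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing predictor `j` on
#' all the others. Perfect collinearity yields `Inf` with a warning.
#'
#' @param design Matrix or data frame of predictors (>= 2 columns, more rows
#'   than columns).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2) gpad_stop("vif: need >= 2 predictors", "gpad_validation_error")
  if (nrow(X) <= ncol(X)) gpad_stop("vif: need more rows than predictors",
                                    "gpad_validation_error")
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(X)))
  out <- setNames(numeric(ncol(X)), nms)
  for (j in seq_len(ncol(X))) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    rss <- sum(resid(fit)^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) {
      warning(sprintf("vif: predictor '%s' is perfectly collinear", nms[j]))
      out[j] <- Inf
    } else {
      out[j] <- 1 / (1 - r2)
    }
  }
  out
}

# Stratified fold assignment: within each outcome-decile stratum, deal fold
# labels round-robin after a seeded shuffle.
.make_folds <- function(y, k, stratify, seed) {
  set.seed(seed)
  n <- length(y)
  folds <- integer(n)
  if (stratify) {
    strata <- cut(rank(y, ties.method = "first"), breaks = 10, labels = FALSE)
  } else {
    strata <- rep(1L, n)
  }
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Multi-score weights by repeated k-fold cross-validation
#'
#' Repeated k-fold cross-validation of the multiple regression of a target on
#' several polygenic scores. Folds are stratified by target decile by default.
#' Held-out performance is the squared correlation between predicted and
#' observed values per fold; the reported weights come from the full-sample
#' fit, together with VIF diagnostics for the score matrix.
#'
#' @param gps_matrix Matrix/data frame of scores (columns named).
#' @param target Outcome vector.
#' @param k Folds (default 10). @param repeats Repeats (default 3).
#' @param seed Seed for fold assignment.
#' @param stratify Stratify folds by outcome decile (default `TRUE`).
#' @return List of class `gpad_cvweights`: `weights` (named, full-sample
#'   slopes), `intercept`, `cv_r2_mean`, `cv_r2_sd`, `cv_r2` (per fold x
#'   repeat), `in_sample_r2`, `vif`, `k`, `repeats`, `seed`, `n`.
#' @export
multi_gps_weights <- function(gps_matrix, target, k = 10, repeats = 3,
                              seed = 1, stratify = TRUE) {
  X <- as.matrix(gps_matrix)
  if (is.null(colnames(X))) colnames(X) <- paste0("gps_", seq_len(ncol(X)))
  ok <- complete.cases(X, target)
  X <- X[ok, , drop = FALSE]; y <- target[ok]
  n <- length(y)
  if (k < 2) gpad_stop("multi_gps_weights: k must be >= 2", "gpad_validation_error")
  if (n < 10 * k) {
    gpad_stop("multi_gps_weights: need n >= 10 * k complete cases",
              "gpad_insufficient_data")
  }
  d <- as.data.frame(X)
  cv_r2 <- numeric(0)
  for (r in seq_len(repeats)) {
    fold_seed <- seed + r - 1L
    repeat {
      folds <- .make_folds(y, k, stratify, fold_seed)
      degenerate <- any(vapply(seq_len(k), function(f) {
        sd(y[folds == f]) == 0 || sd(y[folds != f]) == 0
      }, TRUE))
      if (!degenerate) break
      fold_seed <- fold_seed + 1000L
      message("multi_gps_weights: constant-target fold, refolding with a new seed")
    }
    for (f in seq_len(k)) {
      train <- folds != f
      fit <- lm(y[train] ~ ., data = d[train, , drop = FALSE])
      pred <- predict(fit, newdata = d[!train, , drop = FALSE])
      obs <- y[!train]
      cv_r2 <- c(cv_r2, if (sd(pred) > 0) cor(pred, obs)^2 else 0)
    }
  }
  full <- lm(y ~ ., data = d)
  w <- coef(full)
  structure(list(
    weights = w[-1], intercept = w[1],
    cv_r2_mean = mean(cv_r2), cv_r2_sd = sd(cv_r2), cv_r2 = cv_r2,
    in_sample_r2 = summary(full)$r.squared,
    vif = if (ncol(X) >= 2) vif(X) else setNames(1, colnames(X)),
    k = k, repeats = repeats, seed = seed, n = n
  ), class = "gpad_cvweights")
}

#' Joint regression of achievement slopes on both discrepancy scores
#'
#' Two-predictor OLS of the standardized slope on the genomic and
#' ability-based discrepancies, reporting standardized betas and the joint
#' R-squared. Perfectly collinear predictors are handled by dropping the
#' aliased one (with a warning), in which case the joint R-squared equals the
#' single-predictor one.
#'
#' @param slope_z,gpa_delta,cog_delta Standardized vectors.
#' @param conf Confidence level.
#' @return List with `coefficients` (term, estimate, std_beta, lower, upper,
#'   p), `r2`, `n`, `aliased`.
#' @export
joint_delta_regression <- function(slope_z, gpa_delta, cog_delta, conf = 0.95) {
  ok <- complete.cases(slope_z, gpa_delta, cog_delta)
  y <- slope_z[ok]; x1 <- gpa_delta[ok]; x2 <- cog_delta[ok]
  if (length(y) < 5) gpad_stop("joint_delta_regression: too few complete cases",
                               "gpad_insufficient_data")
  fit <- lm(y ~ x1 + x2)
  cf <- coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased)) {
    warning("joint_delta_regression: predictors perfectly collinear; dropping ",
            paste(aliased, collapse = ", "))
    fit <- lm(y ~ x1)
  }
  sm <- summary(fit)$coefficients
  crit <- qnorm(1 - (1 - conf) / 2)
  sds <- c(`(Intercept)` = NA, x1 = sd(x1), x2 = sd(x2))[rownames(sm)]
  ct <- data.frame(
    term = c("(Intercept)", "gpa_delta", "cog_delta")[
      match(rownames(sm), c("(Intercept)", "x1", "x2"))],
    estimate = sm[, 1],
    std_beta = sm[, 1] * sds / sd(y),
    lower = sm[, 1] - crit * sm[, 2],
    upper = sm[, 1] + crit * sm[, 2],
    p = sm[, 4],
    row.names = NULL
  )
  list(coefficients = ct, r2 = summary(fit)$r.squared, n = length(y),
       aliased = length(aliased) > 0)
}

#' Compare two dependent overlapping correlations (Zou's method)
#'
#' For correlations `r1 = cor(j, k)` and `r2 = cor(j, h)` sharing the
#' variable `j` in one sample of size `n`, builds Zou's (2007) asymmetric
#' confidence interval for `r1 - r2` from the individual Fisher-z intervals
#' and the sampling correlation between the two estimates, which requires the
#' overlap correlation `cor(k, h)`. A difference is declared when the CI
#' excludes zero.
#'
#' @param r1,r2 The two correlations with the shared variable.
#' @param n Sample size.
#' @param overlap Correlation between the two non-shared variables.
#' @param conf Confidence level (default 0.95).
#' @return List with `diff`, `lower`, `upper`, `different` (logical).
#' @export
compare_correlations <- function(r1, r2, n, overlap, conf = 0.95) {
  for (r in c(r1, r2, overlap)) {
    if (!is_number(r) || abs(r) >= 1) {
      gpad_stop("compare_correlations: correlations must lie in (-1, 1)",
                "gpad_validation_error")
    }
  }
  if (n < 4) gpad_stop("compare_correlations: n too small", "gpad_insufficient_data")
  crit <- qnorm(1 - (1 - conf) / 2)
  se <- 1 / sqrt(n - 3)
  l1 <- tanh(atanh(r1) - crit * se); u1 <- tanh(atanh(r1) + crit * se)
  l2 <- tanh(atanh(r2) - crit * se); u2 <- tanh(atanh(r2) + crit * se)
  # sampling correlation between the two correlation estimates
  # (Pearson-Filon, as used by Zou 2007 for overlapping correlations)
  rkh <- overlap
  num <- (rkh - 0.5 * r1 * r2) * (1 - r1^2 - r2^2 - rkh^2) + rkh^3
  den <- (1 - r1^2) * (1 - r2^2)
  ccor <- num / den
  d <- r1 - r2
  lower <- d - sqrt((r1 - l1)^2 + (u2 - r2)^2 - 2 * ccor * (r1 - l1) * (u2 - r2))
  upper <- d + sqrt((u1 - r1)^2 + (r2 - l2)^2 - 2 * ccor * (u1 - r1) * (r2 - l2))
  list(diff = d, lower = lower, upper = upper,
       different = lower > 0 || upper < 0)
}
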