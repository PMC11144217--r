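# Regression toward the genomic prediction, achiever groups, and
# decile/group trajectory summaries.

#' Symmetric trimmed mean
#'
#' Drops `floor(n * trim)` smallest and the same number of largest values,
#' then averages the rest. `trim = 0` is the arithmetic mean. `NA` values are
#' removed first; infinite values take part in the ordering (and so land in
#' the trimmed tails when the trim is large enough to reach them).
#'
#' @param values Numeric vector.
#' @param trim Proportion trimmed from each tail, in `[0, 0.5)`.
#' @return The trimmed mean.
#' @export
#' @examples
#' trimmed_mean(1:20, 0.05)  # drops 1 and 20 -> 10.5
trimmed_mean <- function(values, trim = 0.05) {
  if (!is_number(trim) || trim < 0 || trim >= 0.5) {
    gpad_stop("trimmed_mean: trim must lie in [0, 0.5)", "gpad_validation_error")
  }
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) gpad_stop("trimmed_mean: empty input", "gpad_empty_error")
  m <- floor(n * trim)
  if (n - 2 * m <= 0) gpad_stop("trimmed_mean: nothing left after trimming",
                                "gpad_empty_error")
  s <- sort(values)
  mean(s[(m + 1):(n - m)])
}

#' Percentage regression toward the genomic prediction
#'
#' For each individual, `(1 - delta_16 / delta_7) * 100`: the share of the
#' initial discrepancy eliminated by the final age (100 = fully regressed to
#' the prediction, 0 = unchanged, negative = moved further away). The summary
#' is a symmetric trimmed mean, which is what keeps the near-zero-denominator
#' individuals from dominating; an explicit `eps` exclusion of small `|delta_7|`
#' is additionally available (default 0: trim only).
#'
#' @param delta_7,delta_16 Discrepancy scores at the first and final age.
#' @param trim Trim proportion per tail for the summary (default 0.05).
#' @param eps Individuals with `|delta_7| < eps` are excluded from the
#'   summary (default 0).
#' @return A list with `percent` (per-individual, `NA` where either delta is
#'   missing), `summary` (trimmed mean over eligible individuals) and
#'   `n_used`.
#' @export
regression_percentage <- function(delta_7, delta_16, trim = 0.05, eps = 0) {
  if (length(delta_7) != length(delta_16)) {
    gpad_stop("regression_percentage: inputs must have equal length",
              "gpad_validation_error")
  }
  pct <- (1 - delta_16 / delta_7) * 100
  eligible <- !is.na(delta_7) & !is.na(delta_16) & abs(delta_7) >= eps &
    !is.nan(pct)
  if (!any(eligible)) {
    gpad_stop("regression_percentage: every individual excluded from the summary",
              "gpad_empty_error")
  }
  list(
    percent = pct,
    summary = trimmed_mean(pct[eligible], trim),
    n_used = sum(eligible)
  )
}

#' Classify relative and absolute under/over-achievers
#'
#' Relative underachievers have a discrepancy at least `delta_threshold` SDs
#' below the discrepancy mean (overachievers symmetric above). Absolute
#' under/over-achievers are the subset of the corresponding relative group
#' whose age-7 achievement additionally lies beyond `-/+
#' achievement_threshold` on the standardized achievement scale.
#'
#' @param delta Standardized discrepancy scores.
#' @param achievement_7 Standardized age-7 achievement.
#' @param delta_threshold,achievement_threshold Cut-offs in SD units
#'   (default 1).
#' @param ids Optional identifiers.
#' @param check Validate approximate standardization (default `TRUE`).
#' @param tol Tolerance for the standardization check.
#' @return `data.frame` with `individual_id`, `relative_group` and
#'   `absolute_group` (each `"underachiever"`, `"overachiever"` or `"none"`).
#' @export
classify_groups <- function(delta, achievement_7, delta_threshold = 1,
                            achievement_threshold = 1, ids = NULL,
                            check = TRUE, tol = 0.2) {
  if (length(delta) != length(achievement_7)) {
    gpad_stop("classify_groups: inputs must have equal length", "gpad_validation_error")
  }
  if (check) {
    # delta's cut-offs use its own mean and SD, so only mean-zero matters for
    # it (a difference of two z-scores has SD sqrt(2(1 - r)), not 1);
    # achievement is compared against fixed z-scale thresholds, so it must be
    # fully standardized.
    v <- delta[!is.na(delta)]
    if (length(v) >= 2 && abs(mean(v)) > tol * sd(v)) {
      gpad_stop(sprintf("classify_groups: delta is not centered (mean %.3f)",
                        mean(v)), "gpad_validation_error")
    }
    v <- achievement_7[!is.na(achievement_7)]
    if (length(v) >= 2 && (abs(mean(v)) > tol || abs(sd(v) - 1) > tol)) {
      gpad_stop(sprintf(
        "classify_groups: achievement_7 is not standardized (mean %.3f, sd %.3f)",
        mean(v), sd(v)), "gpad_validation_error")
    }
  }
  if (is.null(ids)) ids <- seq_along(delta)
  m <- mean(delta, na.rm = TRUE); s <- sd(delta, na.rm = TRUE)
  rel <- rep("none", length(delta))
  if (is.na(s) || s == 0) {
    # a degenerate (constant) discrepancy admits no extremes
    return(data.frame(individual_id = ids, relative_group = rel,
                      absolute_group = rel, stringsAsFactors = FALSE))
  }
  rel[!is.na(delta) & delta <= m - delta_threshold * s] <- "underachiever"
  rel[!is.na(delta) & delta >= m + delta_threshold * s] <- "overachiever"
  abs_g <- rep("none", length(delta))
  ok <- !is.na(achievement_7)
  abs_g[ok & rel == "underachiever" & achievement_7 <= -achievement_threshold] <- "underachiever"
  abs_g[ok & rel == "overachiever" & achievement_7 >= achievement_threshold] <- "overachiever"
  data.frame(
    individual_id = ids, relative_group = rel, absolute_group = abs_g,
    stringsAsFactors = FALSE
  )
}

# Stable decile assignment: rank by (delta, id), sizes differing by <= 1,
# extras allotted to the lowest deciles first.
assign_deciles <- function(delta, ids, n_groups = 10) {
  n <- length(delta)
  ord <- order(delta, ids)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, extra), rep(0L, n_groups - extra))
  dec <- rep(seq_len(n_groups), times = sizes)
  out <- integer(n)
  out[ord] <- dec
  out
}

#' Achievement trajectories by discrepancy decile among average achievers
#'
#' Restricts to individuals whose age-7 achievement lies within `band` SDs of
#' the mean (so initial achievement is held near-constant), splits them into
#' `n_groups` discrepancy-ranked groups of near-equal size, and summarizes
#' mean achievement (with standard errors) at each age per decile, plus an
#' OLS line through each decile's per-age means. Ties are broken by a stable
#' `(delta, id)` order.
#'
#' @param delta Discrepancy scores.
#' @param achievement_by_age Matrix of standardized achievement, individuals x
#'   ages, with ages as column names or supplied via `ages`.
#' @param ages Assessment ages (defaults to numeric column names).
#' @param band Half-width of the eligibility band on age-7 achievement
#'   (default 0.5 SD); the first column of `achievement_by_age` is the
#'   age-7 score.
#' @param n_groups Number of groups (default 10).
#' @param ids Optional identifiers.
#' @return A list with `assignment` (id, decile for eligible individuals),
#'   `summary` (decile x age: mean, se, n) and `lines` (decile: intercept,
#'   slope of the fitted line through the per-age means).
#' @export
decile_trajectories <- function(delta, achievement_by_age, ages = NULL,
                                band = 0.5, n_groups = 10, ids = NULL) {
  m <- as.matrix(achievement_by_age)
  if (is.null(ages)) ages <- as.numeric(colnames(m))
  if (any(is.na(ages)) || length(ages) != ncol(m)) {
    gpad_stop("decile_trajectories: supply numeric ages matching the columns",
              "gpad_validation_error")
  }
  if (is.null(ids)) ids <- seq_along(delta)
  ach7 <- m[, 1]
  eligible <- !is.na(delta) & !is.na(ach7) & abs(ach7) <= band
  if (sum(eligible) < n_groups) {
    gpad_stop("decile_trajectories: fewer eligible individuals than groups",
              "gpad_insufficient_data")
  }
  dec <- assign_deciles(delta[eligible], ids[eligible], n_groups)
  me <- m[eligible, , drop = FALSE]
  rows <- list(); lines <- list()
  for (d in seq_len(n_groups)) {
    sub <- me[dec == d, , drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    nn <- colSums(!is.na(sub))
    se <- apply(sub, 2, function(col) {
      k <- sum(!is.na(col)); if (k >= 2) sd(col, na.rm = TRUE) / sqrt(k) else NA_real_
    })
    rows[[d]] <- data.frame(decile = d, age = ages, mean = mu, se = se, n = nn,
                            row.names = NULL)
    okm <- is.finite(mu)
    if (sum(okm) >= 2) {
      f <- fit_slope(ages[okm], mu[okm], min_points = 2)
      lines[[d]] <- data.frame(decile = d, intercept = f$intercept, slope = f$slope)
    } else {
      lines[[d]] <- data.frame(decile = d, intercept = NA_real_, slope = NA_real_)
    }
  }
  list(
    assignment = data.frame(individual_id = ids[eligible], decile = dec,
                            stringsAsFactors = FALSE),
    summary = do.call(rbind, rows),
    lines = do.call(rbind, lines)
  )
}

#' Per-group achievement trajectories and regression percentages
#'
#' For each achiever group (relative/absolute x under/over), reports mean
#' achievement with standard errors at each age, and the group's regression
#' percentage in two modes: computed from the group-mean discrepancies
#' (`pct_from_means`), and as the trimmed mean of the members' individual
#' percentages (`pct_individual`). Empty groups yield `NA` rows, not errors.
#'
#' @param groups Output of [classify_groups()].
#' @param achievement_by_age Individuals x ages matrix of standardized
#'   achievement (rows aligned with `groups`).
#' @param delta_7,delta_16 Discrepancy scores at the first and final age.
#' @param ages Assessment ages (defaults to numeric column names).
#' @param trim Trim for the individual-percentage summary.
#' @return A list with `trajectory` (group x age: mean, se, n) and
#'   `regression` (group: n, pct_from_means, pct_individual).
#' @export
group_trajectory_summary <- function(groups, achievement_by_age, delta_7,
                                     delta_16, ages = NULL, trim = 0.05) {
  m <- as.matrix(achievement_by_age)
  if (is.null(ages)) ages <- as.numeric(colnames(m))
  specs <- list(
    relative_underachiever = groups$relative_group == "underachiever",
    relative_overachiever  = groups$relative_group == "overachiever",
    absolute_underachiever = groups$absolute_group == "underachiever",
    absolute_overachiever  = groups$absolute_group == "overachiever"
  )
  traj <- list(); regr <- list()
  for (nm in names(specs)) {
    sel <- specs[[nm]] & !is.na(specs[[nm]])
    n_mem <- sum(sel)
    if (n_mem == 0) {
      traj[[nm]] <- data.frame(group = nm, age = ages, mean = NA_real_,
                               se = NA_real_, n = 0L)
      regr[[nm]] <- data.frame(group = nm, n = 0L, pct_from_means = NA_real_,
                               pct_individual = NA_real_)
      next
    }
    sub <- m[sel, , drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    nn <- colSums(!is.na(sub))
    se <- apply(sub, 2, function(col) {
      k <- sum(!is.na(col)); if (k >= 2) sd(col, na.rm = TRUE) / sqrt(k) else NA_real_
    })
    traj[[nm]] <- data.frame(group = nm, age = ages, mean = mu, se = se, n = nn,
                             row.names = NULL)
    d7 <- delta_7[sel]; d16 <- delta_16[sel]
    okp <- !is.na(d7) & !is.na(d16)
    pm <- if (any(okp) && mean(d7[okp]) != 0) {
      (1 - mean(d16[okp]) / mean(d7[okp])) * 100
    } else NA_real_
    pi <- tryCatch(regression_percentage(d7, d16, trim = trim)$summary,
                   gpad_error = function(e) NA_real_)
    regr[[nm]] <- data.frame(group = nm, n = n_mem, pct_from_means = pm,
                             pct_individual = pi)
  }
  list(
    trajectory = do.call(rbind, c(traj, list(make.row.names = FALSE))),
    regression = do.call(rbind, c(regr, list(make.row.names = FALSE)))
  )
}
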