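# Per-individual achievement slopes and the MAD outlier filter.

#' Ordinary least-squares slope of achievement on age for one individual
#'
#' Fits a per-individual line of best fit with age as the x-variable and
#' standardized achievement as the y-variable, using whichever assessment
#' pairs are non-missing. Ages are used in raw years; centering would not
#' change the slope.
#'
#' @param ages Numeric vector of assessment ages.
#' @param scores Numeric vector of the same length, `NA` marking missed
#'   assessments.
#' @param min_points Minimum non-missing pairs required (default 3, the
#'   longitudinal inclusion rule).
#' @return A list with `slope`, `intercept` and `n_points`.
#' @export
#' @examples
#' fit_slope(c(7, 9, 12, 16), c(0.5, 0.1, -0.2, -0.4))$slope  # -4.4 / 46
fit_slope <- function(ages, scores, min_points = 3) {
  if (length(ages) != length(scores)) {
    gpad_stop("fit_slope: ages and scores must have equal length",
              "gpad_validation_error")
  }
  ok <- !is.na(ages) & !is.na(scores)
  n <- sum(ok)
  if (n < min_points) {
    gpad_stop(sprintf("fit_slope: %d non-missing points, need >= %d", n, min_points),
              "gpad_insufficient_data")
  }
  x <- ages[ok]; y <- scores[ok]
  if (length(unique(x)) < 2) {
    gpad_stop("fit_slope: zero age variance", "gpad_degenerate_error")
  }
  xc <- x - mean(x)
  slope <- sum(xc * (y - mean(y))) / sum(xc^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x), n_points = n)
}

#' Fit achievement slopes for every individual in a cohort
#'
#' Vectorized wrapper around [fit_slope()]: individuals with fewer than
#' `min_points` observed ages are retained in the output with `NA` slope and
#' `included = FALSE` rather than raising an error, matching the cohort-level
#' exclusion rule.
#'
#' @param ages Assessment ages (columns of `scores`).
#' @param scores Matrix of standardized achievement, individuals x ages.
#' @param ids Optional individual identifiers.
#' @param min_points Minimum observed ages (default 3).
#' @return A `data.frame` of slope records: `individual_id`, `slope`,
#'   `intercept`, `n_points`, `included`.
#' @export
fit_slopes <- function(ages, scores, ids = NULL, min_points = 3) {
  m <- as.matrix(scores)
  if (ncol(m) != length(ages)) {
    gpad_stop("fit_slopes: ncol(scores) must equal length(ages)",
              "gpad_validation_error")
  }
  if (is.null(ids)) ids <- seq_len(nrow(m))
  n <- nrow(m)
  slope <- rep(NA_real_, n); intercept <- rep(NA_real_, n)
  npt <- integer(n)
  for (i in seq_len(n)) {
    ok <- !is.na(m[i, ])
    npt[i] <- sum(ok)
    if (npt[i] >= min_points) {
      f <- fit_slope(ages, m[i, ], min_points)
      slope[i] <- f$slope; intercept[i] <- f$intercept
    }
  }
  data.frame(
    individual_id = ids, slope = slope, intercept = intercept,
    n_points = npt, included = npt >= min_points,
    stringsAsFactors = FALSE
  )
}

#' Raw median absolute deviation
#'
#' `median(|x_i - median(x)|)`, with no normal-consistency constant by
#' default (set `constant = 1.4826` for the scaled variant). This raw form is
#' the one used by the 3-MAD outlier rule.
#'
#' @param values Non-empty numeric vector (`NA` removed).
#' @param constant Multiplier applied to the raw MAD (default 1).
#' @return The (scaled) median absolute deviation.
#' @export
#' @examples
#' mad_raw(c(1, 2, 3, 4, 100))  # 1
mad_raw <- function(values, constant = 1) {
  values <- values[!is.na(values)]
  if (length(values) == 0) gpad_stop("mad_raw: empty input", "gpad_empty_error")
  constant * median(abs(values - median(values)))
}

#' MAD outlier filter
#'
#' Retains `x` iff `|x - median| <= k * MAD` (strict inequality removes, so a
#' value at exactly `k` MADs is kept). Single pass: the median and MAD are not
#' re-estimated after removal. When the MAD is zero but the data are not
#' constant, no filtering is possible; a warning is issued and everything is
#' retained.
#'
#' @param values Numeric vector; `NA` entries yield `NA` in the mask.
#' @param k Threshold in MAD units (default 3).
#' @param constant Passed to [mad_raw()].
#' @return Logical mask of retained entries, same length as `values`.
#' @export
mad_filter <- function(values, k = 3, constant = 1) {
  ok <- !is.na(values)
  if (!any(ok)) gpad_stop("mad_filter: empty input", "gpad_empty_error")
  med <- median(values[ok])
  m <- mad_raw(values[ok], constant)
  keep <- rep(NA, length(values))
  if (m == 0) {
    if (any(values[ok] != med)) {
      warning("mad_filter: MAD is zero with non-constant data; no values removed")
    }
    keep[ok] <- TRUE
    return(keep)
  }
  keep[ok] <- abs(values[ok] - med) <= k * m
  keep
}

#' Standardize retained slopes
#'
#' Adds a `slope_z` column: the slope standardized to mean 0, SD 1 over the
#' retained (non-outlier, included) individuals; outliers and excluded
#' individuals get `NA`.
#'
#' @param records Slope records from [fit_slopes()], with a logical `outlier`
#'   column already set by the MAD filter (rows with `NA` slope are ignored).
#' @return `records` with an added `slope_z` column.
#' @export
standardize_slopes <- function(records) {
  if (is.null(records$outlier)) records$outlier <- FALSE
  keep <- !is.na(records$slope) & !records$outlier
  if (!any(keep)) gpad_stop("standardize_slopes: no retained slopes", "gpad_empty_error")
  if (sum(keep) < 2 || sd(records$slope[keep]) == 0) {
    gpad_stop("standardize_slopes: degenerate slope scale", "gpad_degenerate_error")
  }
  z <- rep(NA_real_, nrow(records))
  z[keep] <- (records$slope[keep] - mean(records$slope[keep])) / sd(records$slope[keep])
  records$slope_z <- z
  records
}

#' Slope pipeline: fit, MAD-filter, standardize
#'
#' Convenience wrapper applying [fit_slopes()], [mad_filter()] on the raw
#' slopes (filtering before standardization), and [standardize_slopes()].
#'
#' @inheritParams fit_slopes
#' @param k_mad MAD threshold (default 3).
#' @return Slope records with `outlier` and `slope_z` columns.
#' @export
slope_records <- function(ages, scores, ids = NULL, min_points = 3, k_mad = 3) {
  rec <- fit_slopes(ages, scores, ids, min_points)
  rec$outlier <- FALSE
  has <- !is.na(rec$slope)
  if (any(has)) {
    keep <- mad_filter(rec$slope[has], k = k_mad)
    rec$outlier[has] <- !keep
  }
  standardize_slopes(rec)
}
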