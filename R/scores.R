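# Standardization, composites, and discrepancy (delta) scores.

#' Standardize a vector to mean 0, sample SD 1
#'
#' Non-missing entries are centered and scaled using the sample standard
#' deviation (denominator `n - 1`); missing entries propagate unchanged.
#'
#' @param values Numeric vector, possibly with `NA`.
#' @return Numeric vector of z-scores, same length and missingness pattern.
#' @export
#' @examples
#' zscore(c(1, 2, 3))        # -1 0 1
#' zscore(c(2, NA, 4, 6))    # -1 NA 0 1
zscore <- function(values) {
  ok <- !is.na(values)
  n_ok <- sum(ok)
  if (n_ok == 0) gpad_stop("zscore: all values missing", "gpad_empty_error")
  if (n_ok < 2) gpad_stop("zscore: need >= 2 non-missing values", "gpad_empty_error")
  s <- sd(values[ok])
  if (!is.finite(s) || s == 0) {
    gpad_stop("zscore: constant input (zero sample standard deviation)",
              "gpad_degenerate_error")
  }
  (values - mean(values[ok])) / s
}

#' Row-wise composite of standardized subject scores
#'
#' Averages per-subject z-scores for each individual over whichever subjects
#' are available, returning `NA` when fewer than `min_subjects` are present
#' (so a wave where one subject is structurally unassessed still yields a
#' composite from the remaining subjects). The composite is re-standardized by
#' default.
#'
#' @param subject_scores Matrix or data frame, one column per subject, already
#'   standardized.
#' @param min_subjects Minimum number of non-missing subjects required.
#' @param restandardize Re-standardize the composite (default `TRUE`).
#' @return Numeric vector with `NA` where too few subjects were observed.
#' @export
composite <- function(subject_scores, min_subjects = 2, restandardize = TRUE) {
  m <- as.matrix(subject_scores)
  if (ncol(m) == 0) gpad_stop("composite: zero subject columns supplied", "gpad_empty_error")
  n_avail <- rowSums(!is.na(m))
  out <- rowMeans(m, na.rm = TRUE)
  out[n_avail < min_subjects] <- NA_real_
  out[is.nan(out)] <- NA_real_
  if (restandardize && sum(!is.na(out)) >= 2) out <- zscore(out)
  out
}

#' Discrepancy between observed and predicted achievement
#'
#' Constructs a per-individual discrepancy score from standardized achievement
#' and a standardized predictor (polygenic score or cognitive ability).
#' `method = "difference"` subtracts the predictor from achievement, so
#' negative values mean underachievement relative to the prediction and
#' positive values overachievement. `method = "residualized"` instead takes
#' the re-standardized residual of the least-squares regression of achievement
#' on the predictor; the two variants are monotonically very close whenever
#' the achievement–predictor correlation is modest.
#'
#' @param achievement_z Standardized achievement vector.
#' @param predictor_z Standardized predictor vector of the same length.
#' @param method `"difference"` (default) or `"residualized"`.
#' @param check Validate that both inputs are standardized (default `TRUE`).
#' @param tol Tolerance on `|mean|` and `|sd - 1|` for the standardization
#'   check.
#' @return Numeric vector of deltas; `NA` wherever either input is missing.
#' @export
delta <- function(achievement_z, predictor_z,
                  method = c("difference", "residualized"),
                  check = TRUE, tol = 0.15) {
  method <- match.arg(method)
  if (length(achievement_z) != length(predictor_z)) {
    gpad_stop("delta: achievement and predictor must have equal length",
              "gpad_validation_error")
  }
  if (check) {
    for (nm in c("achievement_z", "predictor_z")) {
      v <- get(nm)
      v <- v[!is.na(v)]
      if (length(v) >= 2) {
        if (abs(mean(v)) > tol || abs(sd(v) - 1) > tol) {
          gpad_stop(sprintf("delta: %s is not standardized (mean %.3f, sd %.3f)",
                            nm, mean(v), sd(v)), "gpad_validation_error")
        }
      }
    }
  }
  ok <- !is.na(achievement_z) & !is.na(predictor_z)
  out <- rep(NA_real_, length(achievement_z))
  if (method == "difference") {
    out[ok] <- achievement_z[ok] - predictor_z[ok]
  } else {
    if (sum(ok) < 3) gpad_stop("delta: too few complete pairs to residualize",
                               "gpad_empty_error")
    fit <- lm(achievement_z[ok] ~ predictor_z[ok])
    r <- resid(fit)
    out[ok] <- if (sd(r) > 0) (r - mean(r)) / sd(r) else r
  }
  out
}

#' Delta scores for a scored cohort
#'
#' Convenience constructor of the per-individual discrepancy table: the
#' genomic delta (achievement minus polygenic score), the ability-based delta
#' (achievement minus g), and domain-specific deltas for English and math.
#'
#' @param ids Individual identifiers.
#' @param achievement_z,gps_z Standardized age-7 achievement composite and
#'   polygenic score.
#' @param g_z Optional standardized cognitive ability (for `cog_delta`).
#' @param english_z,math_z Optional standardized domain scores at age 7.
#' @param method Passed to [delta()].
#' @return A `data.frame` with columns `individual_id`, `gpa_delta`,
#'   `cog_delta`, `english_delta`, `math_delta`, `method`.
#' @export
delta_scores <- function(ids, achievement_z, gps_z, g_z = NULL,
                         english_z = NULL, math_z = NULL,
                         method = c("difference", "residualized")) {
  method <- match.arg(method)
  out <- data.frame(
    individual_id = ids,
    gpa_delta = delta(achievement_z, gps_z, method),
    stringsAsFactors = FALSE
  )
  out$cog_delta <- if (is.null(g_z)) NA_real_ else delta(achievement_z, g_z, method)
  out$english_delta <- if (is.null(english_z)) NA_real_ else delta(english_z, gps_z, method)
  out$math_delta <- if (is.null(math_z)) NA_real_ else delta(math_z, gps_z, method)
  out$method <- method
  out
}
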