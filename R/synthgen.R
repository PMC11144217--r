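# Synthetic twin-cohort generator.
#
# Linear-Gaussian factor model: one additive-genetic factor A (shared 100% by
# MZ twins, 50% on average by DZ twins), one family-level shared-environment
# factor C, one stable individual factor S, and age/subject-specific residuals.
# The polygenic score is a noisy proxy of A; its per-age loading on achievement
# is solved so that corr(GPS, achievement at age t) equals the configured
# validity exactly. This is an emulation of the covariance structure the
# downstream analysis assumes, not a claim about any real cohort.

#' Configuration for the synthetic twin-cohort generator
#'
#' Builds and validates the parameter set of the generative model. Defaults
#' encode the stated world the package analyses: polygenic-score validity
#' rising from 0.28 at age 7 to 0.43 at age 16, SES correlating about 0.30
#' with age-7 achievement, a stable achievement propensity with a Monte-Carlo
#' ACE decomposition, per-age attrition mirroring realistic longitudinal
#' follow-up, and a cognitive-ability proxy calibrated so the two discrepancy
#' scores (genomic and ability-based) correlate moderately (about 0.38).
#'
#' @param n_pairs Number of twin pairs (families).
#' @param prop_mz Proportion of monozygotic pairs, in `[0, 1]`.
#' @param ages Strictly increasing assessment ages (length >= 3).
#' @param a2,c2 Additive-genetic and shared-environment variance proportions of
#'   the stable achievement propensity; the non-shared proportion is
#'   `1 - a2 - c2`.
#' @param gps_validity Target correlation between the polygenic score and
#'   achievement at each age, one entry per age, each in `(0, 1]`.
#' @param kappa Correlation between the polygenic score and the latent
#'   additive-genetic factor `A`, in `(0, 1]`.
#' @param stability Loading of the stable individual factor `S` on achievement
#'   at every age; governs cross-age achievement stability.
#' @param ses_load_g,ses_load_c Loadings of family SES on the family's mean
#'   genetic factor and on the shared-environment factor. Defaults give
#'   `corr(SES, achievement at age 7)` of about 0.30.
#' @param attrition Per-age probability that an individual's assessment at that
#'   age is missing (i.i.d. across individuals and ages), each in `[0, 1)`.
#' @param seed Master integer seed. Each family draws from its own substream
#'   derived from this seed, so increasing `n_pairs` leaves earlier families
#'   unchanged.
#' @param g_load_a,g_load_s Loadings of the age-7 cognitive-ability proxy on
#'   `A` and `S`.
#' @param residual_cor Proportion of each age-specific residual shared across
#'   subjects within the same age (makes subject scores correlated beyond the
#'   common factors, as real subject marks are).
#' @param sex_beta,age_beta Optional additive effects of sex (0/1, centered)
#'   and the age-at-test jitter on achievement, in achievement SD units.
#'   Default 0; the closed-form covariance of [theoretical_covariance()] is
#'   exact only at 0.
#' @param subjects Character vector of subject names.
#' @param science_missing_age7 If `TRUE` (default) the science column at age 7
#'   is structurally missing (all `NA`), mirroring curricula in which science
#'   is not assessed at the first key stage.
#' @param extra_gps Number of additional polygenic-score columns to emit
#'   (for multi-score analyses); 0 by default.
#' @param extra_kappa Loading of each extra score on `A` (recycled).
#' @param extra_shared Loading of each extra score on the main score's unique
#'   noise component, inducing realistic inter-score correlation.
#'
#' @return A validated object of class `gpad_generator_config`.
#' @seealso [generate_cohort()], [theoretical_covariance()]
#' @export
#' @examples
#' cfg <- generator_config(n_pairs = 200, seed = 42)
#' cohort <- generate_cohort(cfg)
#' head(cohort)
generator_config <- function(n_pairs = 2000,
                             prop_mz = 1 / 3,
                             ages = c(7, 9, 12, 16),
                             a2 = 0.70,
                             c2 = 0.15,
                             gps_validity = c(0.28, 0.27, 0.26, 0.43),
                             kappa = 0.6,
                             stability = 0.5,
                             ses_load_g = 0.30,
                             ses_load_c = 0.45,
                             attrition = c(0.30, 0.65, 0.50, 0.25),
                             seed = 1L,
                             g_load_a = 0.40,
                             g_load_s = 0.65,
                             residual_cor = 0.7,
                             sex_beta = 0,
                             age_beta = 0,
                             subjects = c("english", "math", "science"),
                             science_missing_age7 = TRUE,
                             extra_gps = 0L,
                             extra_kappa = 0.45,
                             extra_shared = 0.30) {
  cfg <- structure(
    list(
      n_pairs = as.integer(n_pairs), prop_mz = prop_mz, ages = as.numeric(ages),
      a2 = a2, c2 = c2, gps_validity = as.numeric(gps_validity), kappa = kappa,
      stability = stability, ses_load_g = ses_load_g, ses_load_c = ses_load_c,
      attrition = as.numeric(attrition), seed = as.integer(seed),
      g_load_a = g_load_a, g_load_s = g_load_s, residual_cor = residual_cor,
      sex_beta = sex_beta, age_beta = age_beta, subjects = subjects,
      science_missing_age7 = isTRUE(science_missing_age7),
      extra_gps = as.integer(extra_gps),
      extra_kappa = rep_len(extra_kappa, max(1L, as.integer(extra_gps))),
      extra_shared = extra_shared
    ),
    class = "gpad_generator_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks every invariant of the generative model and raises a
#' `gpad_config_error` naming the violated constraint. Returns the
#' configuration invisibly when valid.
#'
#' @param config A `gpad_generator_config` object (or a plain list with the
#'   same fields).
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  cfg <- config
  bad <- function(msg) gpad_stop(paste0("invalid generator config: ", msg),
                                 "gpad_config_error")
  if (!is_number(cfg$n_pairs) || cfg$n_pairs < 1) bad("n_pairs must be a positive integer")
  if (!is_number(cfg$prop_mz) || cfg$prop_mz < 0 || cfg$prop_mz > 1) {
    bad("prop_mz must lie in [0, 1]")
  }
  ages <- cfg$ages
  if (length(ages) < 3) bad("ages must have length >= 3")
  if (any(diff(ages) <= 0)) bad("ages must be strictly increasing")
  if (!is_number(cfg$a2) || cfg$a2 < 0) bad("a2 must be >= 0")
  if (!is_number(cfg$c2) || cfg$c2 < 0) bad("c2 must be >= 0")
  if (cfg$a2 + cfg$c2 > 1 + 1e-12) bad("a2 + c2 must be <= 1")
  v <- cfg$gps_validity
  if (length(v) != length(ages)) bad("gps_validity must have one entry per age")
  if (any(v <= 0 | v > 1)) bad("every gps_validity entry must lie in (0, 1]")
  if (!is_number(cfg$kappa) || cfg$kappa <= 0 || cfg$kappa > 1) {
    bad("kappa must lie in (0, 1]")
  }
  if (cfg$a2 <= 0) bad("a2 must be > 0 (the polygenic score proxies the genetic factor)")
  # loading on the scaled genetic propensity sqrt(a2)*A must not exceed 1
  g_scaled <- v / (cfg$kappa * sqrt(cfg$a2))
  if (any(g_scaled > 1 + 1e-12)) {
    bad(sprintf(
      "implied genetic loading gps_validity/(kappa*sqrt(a2)) exceeds 1 at age %s",
      paste(ages[g_scaled > 1 + 1e-12], collapse = ", ")
    ))
  }
  b <- v / cfg$kappa
  u <- cfg$stability
  if (!is_number(u) || u < 0 || u >= 1) bad("stability must lie in [0, 1)")
  res_var <- 1 - b^2 - cfg$c2 - u^2
  if (any(res_var < -1e-12)) {
    bad(sprintf(
      "implied residual variance is negative at age %s (reduce gps_validity, c2 or stability)",
      paste(ages[res_var < -1e-12], collapse = ", ")
    ))
  }
  if (length(cfg$attrition) != length(ages)) bad("attrition must have one entry per age")
  if (any(cfg$attrition < 0 | cfg$attrition >= 1)) bad("attrition entries must lie in [0, 1)")
  if (cfg$ses_load_g^2 + cfg$ses_load_c^2 > 1 + 1e-12) {
    bad("ses_load_g^2 + ses_load_c^2 must be <= 1")
  }
  if (cfg$g_load_a^2 + cfg$g_load_s^2 > 1 + 1e-12) {
    bad("g_load_a^2 + g_load_s^2 must be <= 1")
  }
  if (!is_number(cfg$residual_cor) || cfg$residual_cor < 0 || cfg$residual_cor > 1) {
    bad("residual_cor must lie in [0, 1]")
  }
  if (length(cfg$subjects) < 1) bad("at least one subject is required")
  if (cfg$extra_gps < 0) bad("extra_gps must be >= 0")
  if (cfg$extra_gps > 0 && any(cfg$extra_kappa^2 + cfg$extra_shared^2 > 1 + 1e-12)) {
    bad("extra_kappa^2 + extra_shared^2 must be <= 1")
  }
  invisible(config)
}

# Deterministic per-family substream seed: linear in the family index modulo a
# Mersenne prime, so regenerating with a larger n_pairs reproduces earlier
# families bit-exactly.
family_seed <- function(master, f) {
  as.integer((abs(as.numeric(master)) * 1009 + as.numeric(f) * 48271) %% 2147483629) + 1L
}

# Per-age loadings implied by a config.
config_loadings <- function(cfg) {
  b <- cfg$gps_validity / cfg$kappa           # loading of achievement on A
  cload <- sqrt(cfg$c2)                       # loading on shared environment C
  u <- cfg$stability                          # loading on stable factor S
  r2 <- pmax(0, 1 - b^2 - cload^2 - u^2)      # age-specific residual variance
  list(b = b, cload = cload, u = u, r = sqrt(r2))
}

#' Generate a synthetic twin cohort
#'
#' Simulates `2 * n_pairs` individuals under the generative model documented in
#' [generator_config()]. Monozygotic co-twins share the genetic factor `A`
#' exactly; dizygotic co-twins correlate 0.5 on it. The polygenic score is
#' `kappa * A` plus independent noise, and each subject's achievement score at
#' age `t` is built so its population correlation with the score equals
#' `gps_validity[t]`. Regenerating with the same seed is bit-identical, and
#' family `f` depends only on `(seed, f)`, never on `n_pairs`.
#'
#' @param config A [generator_config()] object.
#' @return A `data.frame` (one row per individual) with columns
#'   `individual_id`, `family_id`, `zygosity` (`"MZ"`/`"DZ"`), `sex` (0/1),
#'   `age_jitter` (years, shared within a family), `ses`, `gps` (plus
#'   `gps_2`, ... when `extra_gps > 0`), `g_age7`, `propensity` (the latent
#'   stable achievement propensity, kept for diagnostics), and one
#'   `ach_<subject>_<age>` column per subject and age with `NA` marking
#'   missing assessments. The configuration is attached as
#'   `attr(, "config")`.
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  cfg <- config
  n <- cfg$n_pairs
  ages <- cfg$ages
  n_ages <- length(ages)
  subjects <- cfg$subjects
  n_sub <- length(subjects)
  ld <- config_loadings(cfg)
  rho <- cfg$residual_cor
  m_extra <- cfg$extra_gps
  e2 <- 1 - cfg$a2 - cfg$c2

  n_ind <- 2L * n
  zyg <- character(n)
  sex <- integer(n_ind)
  A <- numeric(n_ind); S <- numeric(n_ind)
  Cfam <- numeric(n); ses <- numeric(n); jitter <- numeric(n)
  gps <- numeric(n_ind); g7 <- numeric(n_ind)
  gps_extra <- if (m_extra > 0) matrix(0, n_ind, m_extra) else NULL
  # achievement array: individuals x ages x subjects
  ach <- array(NA_real_, dim = c(n_ind, n_ages, n_sub))
  miss <- matrix(FALSE, n_ind, n_ages)

  ses_noise_sd <- sqrt(max(0, 1 - cfg$ses_load_g^2 - cfg$ses_load_c^2))
  g_noise_sd <- sqrt(max(0, 1 - cfg$g_load_a^2 - cfg$g_load_s^2))
  gps_noise_sd <- sqrt(1 - cfg$kappa^2)

  for (f in seq_len(n)) {
    set.seed(family_seed(cfg$seed, f))
    i1 <- 2L * f - 1L; i2 <- 2L * f
    is_mz <- runif(1) < cfg$prop_mz
    zyg[f] <- if (is_mz) "MZ" else "DZ"
    z <- rnorm(11L)
    A[i1] <- z[1]
    A[i2] <- if (is_mz) z[1] else 0.5 * z[1] + sqrt(0.75) * z[2]
    Cfam[f] <- z[3]
    S[i1] <- z[4]; S[i2] <- z[5]
    nu1 <- z[6]; nu2 <- z[7]
    gps[i1] <- cfg$kappa * A[i1] + gps_noise_sd * nu1
    gps[i2] <- cfg$kappa * A[i2] + gps_noise_sd * nu2
    g7[i1] <- cfg$g_load_a * A[i1] + cfg$g_load_s * S[i1] + g_noise_sd * z[8]
    g7[i2] <- cfg$g_load_a * A[i2] + cfg$g_load_s * S[i2] + g_noise_sd * z[9]
    rho_a <- if (is_mz) 1 else 0.5
    ses[f] <- cfg$ses_load_g * (A[i1] + A[i2]) / sqrt(2 + 2 * rho_a) +
      cfg$ses_load_c * Cfam[f] + ses_noise_sd * z[10]
    jitter[f] <- 0.25 * z[11]
    su <- runif(2L)
    sex[i1] <- as.integer(su[1] < 0.5)
    sex[i2] <- if (is_mz) sex[i1] else as.integer(su[2] < 0.5)

    eps_shared <- matrix(rnorm(2L * n_ages), 2L, n_ages)
    eps_sub <- array(rnorm(2L * n_ages * n_sub), dim = c(2L, n_ages, n_sub))
    for (tw in 1:2) {
      ii <- if (tw == 1L) i1 else i2
      core <- ld$b * A[ii] + ld$cload * Cfam[f] + ld$u * S[ii] +
        cfg$sex_beta * (sex[ii] - 0.5) + cfg$age_beta * jitter[f]
      for (s in seq_len(n_sub)) {
        ach[ii, , s] <- core + ld$r *
          (sqrt(rho) * eps_shared[tw, ] + sqrt(1 - rho) * eps_sub[tw, , s])
      }
    }
    au <- matrix(runif(2L * n_ages), 2L, n_ages)
    miss[i1, ] <- au[1, ] < cfg$attrition
    miss[i2, ] <- au[2, ] < cfg$attrition
    if (m_extra > 0) {
      en <- matrix(rnorm(2L * m_extra), 2L, m_extra)
      for (j in seq_len(m_extra)) {
        kj <- cfg$extra_kappa[j]
        res_sd <- sqrt(max(0, 1 - kj^2 - cfg$extra_shared^2))
        gps_extra[i1, j] <- kj * A[i1] + cfg$extra_shared * nu1 + res_sd * en[1, j]
        gps_extra[i2, j] <- kj * A[i2] + cfg$extra_shared * nu2 + res_sd * en[2, j]
      }
    }
  }

  # apply attrition, then structural missingness for science at age 7
  for (t in seq_len(n_ages)) ach[miss[, t], t, ] <- NA_real_
  if (cfg$science_missing_age7 && "science" %in% subjects && 7 %in% ages) {
    ach[, which(ages == 7), which(subjects == "science")] <- NA_real_
  }

  fam_ids <- sprintf("F%05d", seq_len(n))
  out <- data.frame(
    individual_id = paste0(rep(fam_ids, each = 2L), "_", rep(1:2, n)),
    family_id = rep(fam_ids, each = 2L),
    zygosity = rep(zyg, each = 2L),
    sex = sex,
    age_jitter = rep(jitter, each = 2L),
    ses = rep(ses, each = 2L),
    gps = gps,
    stringsAsFactors = FALSE
  )
  if (m_extra > 0) {
    colnames(gps_extra) <- paste0("gps_", seq_len(m_extra) + 1L)
    out <- cbind(out, as.data.frame(gps_extra))
  }
  out$g_age7 <- g7
  out$propensity <- sqrt(cfg$a2) * A + sqrt(cfg$c2) * Cfam[rep(seq_len(n), each = 2L)] +
    sqrt(max(0, e2)) * S
  for (s in seq_len(n_sub)) {
    for (t in seq_len(n_ages)) {
      out[[paste0("ach_", subjects[s], "_", ages[t])]] <- ach[, t, s]
    }
  }
  attr(out, "config") <- cfg
  out
}

#' Closed-form correlations implied by a generator configuration
#'
#' Returns the population correlation matrix among the polygenic score,
#' achievement at each age (a single subject's score; all subjects are
#' exchangeable), and family SES, as implied by the generative equations.
#' Serves as the oracle against which simulated cohorts are validated. Exact
#' when `sex_beta = age_beta = 0` (the defaults).
#'
#' @param config A [generator_config()] object.
#' @return A symmetric correlation matrix with dimnames
#'   `c("gps", "ach_<age>"..., "ses")`.
#' @export
theoretical_covariance <- function(config) {
  validate_config(config)
  cfg <- config
  ld <- config_loadings(cfg)
  ages <- cfg$ages
  n_ages <- length(ages)
  # E over zygosity of cov(family mean genetic factor, individual A)
  wbar <- cfg$prop_mz * 1 + (1 - cfg$prop_mz) * sqrt(0.75)
  vars <- c("gps", paste0("ach_", ages), "ses")
  k <- length(vars)
  m <- diag(1, k)
  dimnames(m) <- list(vars, vars)
  for (t in seq_len(n_ages)) {
    m["gps", 1 + t] <- m[1 + t, "gps"] <- cfg$gps_validity[t]
    m["ses", 1 + t] <- m[1 + t, "ses"] <-
      cfg$ses_load_g * wbar * ld$b[t] + cfg$ses_load_c * ld$cload
    for (s in seq_len(n_ages)) {
      if (s != t) {
        m[1 + t, 1 + s] <- ld$b[t] * ld$b[s] + ld$cload^2 + ld$u^2
      }
    }
  }
  m["gps", "ses"] <- m["ses", "gps"] <- cfg$ses_load_g * wbar * cfg$kappa
  m
}

#' Write / read a cohort table as CSV
#'
#' Plain-text round trip for [generate_cohort()] output; missing values are
#' encoded as empty fields.
#'
#' @param cohort A cohort `data.frame`.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    gpad_stop(sprintf("cohort file not found: %s", path), "gpad_io_error")
  }
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA")),
    error = function(e) {
      gpad_stop(sprintf("malformed CSV '%s': %s", path, conditionMessage(e)),
                "gpad_parse_error")
    }
  )
  df
}
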