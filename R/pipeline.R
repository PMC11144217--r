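# End-to-end orchestration: simulate/load -> inclusion filter -> standardize
# -> deltas -> slopes -> trajectories -> models -> twin, with tidy CSV
# outputs, a manifest, and a text report. The pipeline is a pure function of
# (input, config): no timestamps, and all randomness flows from one master
# seed.

# Identify achievement columns "ach_<subject>_<age>" and parse them.
.ach_layout <- function(cohort) {
  cols <- grep("^ach_", names(cohort), value = TRUE)
  if (!length(cols)) gpad_stop("no achievement columns (ach_<subject>_<age>) found",
                               "gpad_validation_error")
  parts <- regmatches(cols, regexec("^ach_([A-Za-z][A-Za-z0-9]*)_([0-9]+)$", cols))
  bad <- vapply(parts, length, 0L) != 3L
  if (any(bad)) gpad_stop(paste0("unparseable achievement columns: ",
                                 paste(cols[bad], collapse = ", ")),
                          "gpad_validation_error")
  subjects <- unique(vapply(parts, `[`, "", 2L))
  ages <- sort(unique(as.numeric(vapply(parts, `[`, "", 3L))))
  list(cols = cols, subjects = subjects, ages = ages)
}

#' Longitudinal inclusion filter
#'
#' Retains individuals with at least `min_obs` assessment ages at which a
#' composite can be formed (i.e. at least `min_subjects` subject scores
#' observed), and logs the exclusion counts.
#'
#' @param table Cohort `data.frame` with `ach_<subject>_<age>` columns.
#' @param min_obs Minimum observed ages (default 3).
#' @param min_subjects Minimum subjects per age for that age to count
#'   (default 2).
#' @return List with `table` (filtered), `kept`, `excluded`, `n_input`, and
#'   `obs_per_individual`.
#' @export
apply_inclusion_filter <- function(table, min_obs = 3, min_subjects = 2) {
  lay <- .ach_layout(table)
  n_ages <- length(lay$ages)
  avail <- matrix(0L, nrow(table), n_ages)
  for (t in seq_len(n_ages)) {
    cols_t <- paste0("ach_", lay$subjects, "_", lay$ages[t])
    cols_t <- cols_t[cols_t %in% names(table)]
    avail[, t] <- rowSums(!is.na(table[, cols_t, drop = FALSE]))
  }
  obs <- rowSums(avail >= min_subjects)
  keep <- obs >= min_obs
  list(table = table[keep, , drop = FALSE], kept = sum(keep),
       excluded = sum(!keep), n_input = nrow(table), obs_per_individual = obs)
}

#' Pipeline configuration
#'
#' Collects every stage parameter and the master seed into one object. Either
#' `simulate` (a [generator_config()]) or `input` (a cohort CSV path) must be
#' supplied; `column_map` renames arbitrary cohort exports to the standard
#' column names (`standard = actual`).
#'
#' @param simulate Optional [generator_config()] used to simulate the cohort;
#'   its seed is overridden by `seed`.
#' @param input Optional path to a cohort CSV.
#' @param column_map Optional named character vector renaming input columns.
#' @param out_dir Optional output directory for tidy CSVs, manifest and
#'   report.
#' @param seed Master seed governing simulation, fold assignment and any
#'   bootstrap.
#' @param min_obs,min_subjects Inclusion-filter parameters.
#' @param k_mad MAD outlier threshold for slopes.
#' @param trim Trim proportion for regression-percentage summaries.
#' @param band Age-7 achievement band for decile trajectories.
#' @param delta_threshold,achievement_threshold Group-classification cut-offs.
#' @param method Delta construction: `"difference"` or `"residualized"`.
#' @param cv_k,cv_repeats Repeated cross-validation scheme for multi-score
#'   weighting.
#' @param ace_ci Confidence-interval method for ACE fits (`"profile"`,
#'   `"bootstrap"`, `"none"`).
#' @return Object of class `gpad_run_config`.
#' @export
run_config <- function(simulate = generator_config(extra_gps = 4),
                       input = NULL, column_map = NULL, out_dir = NULL,
                       seed = 1L, min_obs = 3, min_subjects = 2, k_mad = 3,
                       trim = 0.05, band = 0.5, delta_threshold = 1,
                       achievement_threshold = 1,
                       method = c("difference", "residualized"),
                       cv_k = 10, cv_repeats = 3,
                       ace_ci = c("profile", "bootstrap", "none")) {
  method <- match.arg(method)
  ace_ci <- match.arg(ace_ci)
  if (is.null(simulate) && is.null(input)) {
    gpad_stop("run_config: supply either a simulate block or an input path",
              "gpad_config_error")
  }
  structure(list(
    simulate = simulate, input = input, column_map = column_map,
    out_dir = out_dir, seed = as.integer(seed), min_obs = min_obs,
    min_subjects = min_subjects, k_mad = k_mad, trim = trim, band = band,
    delta_threshold = delta_threshold,
    achievement_threshold = achievement_threshold, method = method,
    cv_k = cv_k, cv_repeats = cv_repeats, ace_ci = ace_ci
  ), class = "gpad_run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    gpad_stop(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)), "gpad_pipeline_error")
  })
}

#' Run the full discrepancy-analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation or CSV), the
#' three-of-four-ages inclusion filter, standardization and composite
#' construction on the analysis sample, discrepancy-score construction at the
#' first and final ages, per-individual slope fitting with MAD filtering,
#' group classification and trajectory summaries, the regression analyses
#' (correlation with CI, overall and per-group regression percentages,
#' hierarchical regression with covariates sex / age-at-test / SES, SES
#' moderation, multi-score cross-validated weighting when extra score columns
#' exist, domain comparison, joint two-delta regression), and twin ACE
#' analyses of the main traits. When `out_dir` is set, tidy CSVs, a JSON
#' manifest of seeds and row counts, and a text report are written;
#' identical config and seed give byte-identical outputs.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with every stage's results (`cohort`, `scored`,
#'   `slopes`, `groups`, `group_summary`, `deciles`, `models`, `twin`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "gpad_run_config")) {
    gpad_stop("run_pipeline: config must come from run_config()", "gpad_config_error")
  }
  manifest <- list(package_version = as.character(packageVersion("gpadelta")),
                   seed = config$seed, stages = list())

  # -- acquire cohort ---------------------------------------------------------
  cohort <- .stage("acquire", {
    if (!is.null(config$input)) {
      d <- read_cohort(config$input)
      if (!is.null(config$column_map)) {
        for (std in names(config$column_map)) {
          actual <- config$column_map[[std]]
          if (!actual %in% names(d)) {
            gpad_stop(sprintf("column_map: no column '%s' in input", actual),
                      "gpad_validation_error")
          }
          names(d)[names(d) == actual] <- std
        }
      }
      d
    } else {
      gen <- config$simulate
      gen$seed <- config$seed
      validate_config(gen)
      generate_cohort(gen)
    }
  })
  manifest$stages$acquire <- list(rows = nrow(cohort))
  lay <- .ach_layout(cohort)
  ages <- lay$ages
  age_first <- ages[1]; age_last <- ages[length(ages)]

  # -- inclusion filter -------------------------------------------------------
  filt <- .stage("inclusion_filter",
                 apply_inclusion_filter(cohort, config$min_obs, config$min_subjects))
  d <- filt$table
  manifest$stages$inclusion_filter <-
    list(rows = nrow(d), excluded = filt$excluded)

  # -- standardization & composites (analysis-sample reference) ---------------
  scored <- .stage("standardize", {
    s <- d[c("individual_id", "family_id", "zygosity", "sex", "age_jitter")]
    s$ses_z <- zscore(d$ses)
    s$gps_z <- zscore(d$gps)
    extra_cols <- grep("^gps_[0-9]+$", names(d), value = TRUE)
    for (ec in extra_cols) s[[paste0(ec, "_z")]] <- zscore(d[[ec]])
    if ("g_age7" %in% names(d)) s$g_z <- zscore(d$g_age7)
    for (t in ages) {
      subj_cols <- paste0("ach_", lay$subjects, "_", t)
      subj_cols <- subj_cols[subj_cols %in% names(d)]
      zs <- list()
      for (sc in subj_cols) {
        col <- d[[sc]]
        zs[[sc]] <- if (sum(!is.na(col)) >= 2 && sd(col, na.rm = TRUE) > 0) {
          z <- zscore(col)
          s[[paste0(sc, "_z")]] <- z
          z
        } else NULL
      }
      zs <- Filter(Negate(is.null), zs)
      s[[paste0("ach_", t)]] <- composite(do.call(cbind, zs), config$min_subjects)
    }
    s
  })

  # -- deltas -----------------------------------------------------------------
  scored <- .stage("deltas", {
    a7 <- scored[[paste0("ach_", age_first)]]
    a_last <- scored[[paste0("ach_", age_last)]]
    scored$gpa_delta <- delta(a7, scored$gps_z, config$method)
    scored$gpa_delta_last <- delta(a_last, scored$gps_z, config$method)
    if (!is.null(scored$g_z)) scored$cog_delta <- delta(a7, scored$g_z, config$method)
    e7 <- scored[[paste0("ach_english_", age_first, "_z")]]
    m7 <- scored[[paste0("ach_math_", age_first, "_z")]]
    if (!is.null(e7)) scored$english_delta <- delta(e7, scored$gps_z, config$method)
    if (!is.null(m7)) scored$math_delta <- delta(m7, scored$gps_z, config$method)
    scored
  })
  manifest$stages$deltas <- list(rows = sum(!is.na(scored$gpa_delta)))

  # -- slopes -----------------------------------------------------------------
  comp_mat <- as.matrix(scored[paste0("ach_", ages)])
  colnames(comp_mat) <- ages
  slopes <- .stage("slopes", {
    slope_records(ages, comp_mat, ids = scored$individual_id,
                  min_points = config$min_obs, k_mad = config$k_mad)
  })
  scored$slope <- slopes$slope
  scored$slope_z <- slopes$slope_z
  manifest$stages$slopes <- list(
    rows = sum(!is.na(slopes$slope)),
    outliers_removed = sum(slopes$outlier, na.rm = TRUE),
    retained = sum(!is.na(slopes$slope_z))
  )

  # -- trajectories -----------------------------------------------------------
  groups <- .stage("classify", {
    classify_groups(scored$gpa_delta, scored[[paste0("ach_", age_first)]],
                    config$delta_threshold, config$achievement_threshold,
                    ids = scored$individual_id)
  })
  group_summary <- .stage("group_summary", {
    group_trajectory_summary(groups, comp_mat, scored$gpa_delta,
                             scored$gpa_delta_last, ages = ages,
                             trim = config$trim)
  })
  deciles <- .stage("deciles", {
    tryCatch(
      decile_trajectories(scored$gpa_delta, comp_mat, ages = ages,
                          band = config$band, ids = scored$individual_id),
      gpad_insufficient_data = function(e) NULL
    )
  })
  manifest$stages$trajectories <- list(
    relative_under = sum(groups$relative_group == "underachiever"),
    relative_over = sum(groups$relative_group == "overachiever"),
    absolute_under = sum(groups$absolute_group == "underachiever"),
    absolute_over = sum(groups$absolute_group == "overachiever"),
    decile_eligible = if (is.null(deciles)) 0L else nrow(deciles$assignment)
  )

  # -- models -----------------------------------------------------------------
  models <- .stage("models", {
    out <- list()
    out$delta_slope_cor <- pearson_ci(scored$gpa_delta, scored$slope_z)
    out$overall_regression <- regression_percentage(
      scored$gpa_delta, scored$gpa_delta_last, trim = config$trim)[c("summary", "n_used")]
    out$hierarchical <- hierarchical_regression(
      scored, "slope_z", "gpa_delta",
      covariate_blocks = list("sex", "age_jitter", "ses_z"))
    out$moderation <- moderation_test(scored, "slope_z", "gpa_delta", "ses_z",
                                      covariates = c("sex", "age_jitter"))
    if (!is.null(scored$cog_delta)) {
      out$joint <- joint_delta_regression(scored$slope_z, scored$gpa_delta,
                                          scored$cog_delta)
      out$delta_cor <- pearson_ci(scored$gpa_delta, scored$cog_delta)
    }
    if (!is.null(scored$english_delta) && !is.null(scored$math_delta)) {
      ok <- complete.cases(scored$english_delta, scored$math_delta, scored$slope_z)
      r1 <- cor(scored$english_delta[ok], scored$slope_z[ok])
      r2 <- cor(scored$math_delta[ok], scored$slope_z[ok])
      r12 <- cor(scored$english_delta[ok], scored$math_delta[ok])
      out$domain_comparison <- c(
        list(r_english = r1, r_math = r2, overlap = r12, n = sum(ok)),
        compare_correlations(r1, r2, sum(ok), r12))
    }
    extra_z <- grep("^gps_[0-9]+_z$", names(scored), value = TRUE)
    if (length(extra_z) >= 1) {
      gmat <- as.matrix(scored[c("gps_z", extra_z)])
      target <- scored[[paste0("ach_", age_first)]]
      out$multi_gps <- multi_gps_weights(gmat, target, k = config$cv_k,
                                         repeats = config$cv_repeats,
                                         seed = config$seed + 100L)
      ok <- complete.cases(gmat, target)
      pred <- drop(cbind(1, gmat[ok, ]) %*% c(out$multi_gps$intercept,
                                              out$multi_gps$weights))
      multi_z <- rep(NA_real_, nrow(scored))
      multi_z[ok] <- zscore(pred)
      multi_delta <- delta(target, multi_z, config$method, check = FALSE)
      okc <- complete.cases(multi_delta, scored$gpa_delta, scored$slope_z)
      r_multi <- cor(multi_delta[okc], scored$slope_z[okc])
      r_single <- cor(scored$gpa_delta[okc], scored$slope_z[okc])
      r_ov <- cor(multi_delta[okc], scored$gpa_delta[okc])
      out$multi_vs_single <- c(
        list(r_multi = r_multi, r_single = r_single, n = sum(okc)),
        compare_correlations(r_multi, r_single, sum(okc), r_ov))
    }
    out
  })

  # -- twin -------------------------------------------------------------------
  twin <- .stage("twin", {
    out <- list()
    traits <- c(gpa_delta = "gpa_delta",
                achievement = paste0("ach_", age_first),
                slope = "slope_z")
    if (!is.null(scored$cog_delta)) traits <- c(traits, cog_delta = "cog_delta")
    for (nm in names(traits)) {
      pairs <- twin_pairs(scored, traits[[nm]])
      res <- list(n_pairs_mz = sum(pairs$zygosity == "MZ"),
                  n_pairs_dz = sum(pairs$zygosity == "DZ"))
      fit_ok <- res$n_pairs_mz >= 5 && res$n_pairs_dz >= 5
      if (fit_ok) {
        res$icc_mz <- intraclass_corr(pairs, "MZ")
        res$icc_dz <- intraclass_corr(pairs, "DZ")
        res$ace <- fit_ace(pairs[pairs$zygosity == "MZ", ],
                           pairs[pairs$zygosity == "DZ", ],
                           ci = config$ace_ci, seed = config$seed + 200L)
      }
      out[[nm]] <- res
    }
    out
  })

  result <- list(cohort = cohort, scored = scored, slopes = slopes,
                 groups = groups, group_summary = group_summary,
                 deciles = deciles, models = models, twin = twin,
                 manifest = manifest, config = config)

  if (!is.null(config$out_dir)) .write_outputs(result, config$out_dir)
  invisible(result)
}

# Tidy CSVs + manifest + text report. Deliberately timestamp-free so reruns
# with the same seed are byte-identical.
.write_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
  }
  wr(result$scored, "scored_cohort.csv")
  wr(result$slopes, "slopes.csv")
  wr(result$groups, "groups.csv")
  wr(result$group_summary$trajectory, "group_trajectories.csv")
  wr(result$group_summary$regression, "group_regression.csv")
  if (!is.null(result$deciles)) {
    wr(result$deciles$summary, "decile_trajectories.csv")
    wr(result$deciles$lines, "decile_lines.csv")
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(.format_report(result), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

.format_report <- function(result) {
  m <- result$models
  fmt_ci <- function(x) sprintf("%.3f [%.3f, %.3f]", x$r, x$lower, x$upper)
  lines <- c(
    "Genomically predicted achievement discrepancy: pipeline report",
    "==============================================================",
    sprintf("seed: %d", result$config$seed),
    sprintf("individuals analysed: %d", nrow(result$scored)),
    "",
    "Discrepancy vs achievement slope:",
    sprintf("  r(gpa_delta, slope_z) = %s, p = %.3g, n = %d",
            fmt_ci(m$delta_slope_cor), m$delta_slope_cor$p, m$delta_slope_cor$n),
    sprintf("  overall trimmed-mean regression percentage: %.1f%% (n = %d)",
            m$overall_regression$summary, m$overall_regression$n_used),
    "",
    "Group regression percentages (from means / individual trimmed mean):"
  )
  gr <- result$group_summary$regression
  for (i in seq_len(nrow(gr))) {
    lines <- c(lines, sprintf("  %-24s n=%5d  %6.1f%% / %6.1f%%",
                              gr$group[i], gr$n[i], gr$pct_from_means[i],
                              gr$pct_individual[i]))
  }
  h <- m$hierarchical
  lines <- c(lines, "", "Hierarchical regression of slope_z on gpa_delta:")
  for (i in seq_along(h)) {
    l <- sprintf("  model %d (%s): R2 = %.3f, semi-partial R2 (focal) = %.3f",
                 i, paste(h[[i]]$predictors, collapse = " + "),
                 h[[i]]$r2, h[[i]]$semipartial_r2)
    if (!is.null(h[[i]]$f)) {
      l <- sprintf("%s, dR2 = %.3f, F(%d, %d) = %.2f, p = %.3g",
                   l, h[[i]]$delta_r2, h[[i]]$df1, h[[i]]$df2, h[[i]]$f,
                   h[[i]]$p_f)
    }
    lines <- c(lines, l)
  }
  it <- m$moderation$interaction
  lines <- c(lines, "", sprintf(
    "SES moderation: beta = %.3f [%.3f, %.3f], p = %.3g",
    it$estimate, it$lower, it$upper, it$p))
  if (!is.null(m$joint)) {
    ct <- m$joint$coefficients
    lines <- c(lines, "", sprintf(
      "Joint delta regression: R2 = %.3f; std betas: gpa %.3f, cog %.3f",
      m$joint$r2,
      ct$std_beta[ct$term == "gpa_delta"],
      ct$std_beta[ct$term == "cog_delta"]))
  }
  if (!is.null(m$multi_vs_single)) {
    lines <- c(lines, "", sprintf(
      "Multi-score vs single-score delta: r = %.3f vs %.3f, diff CI [%.3f, %.3f]",
      m$multi_vs_single$r_multi, m$multi_vs_single$r_single,
      m$multi_vs_single$lower, m$multi_vs_single$upper))
  }
  if (!is.null(m$domain_comparison)) {
    lines <- c(lines, sprintf(
      "English vs math delta-slope correlations: %.3f vs %.3f, diff CI [%.3f, %.3f]",
      m$domain_comparison$r_english, m$domain_comparison$r_math,
      m$domain_comparison$lower, m$domain_comparison$upper))
  }
  lines <- c(lines, "", "Twin ACE estimates (a2 / c2 / e2):")
  for (nm in names(result$twin)) {
    tw <- result$twin[[nm]]
    if (!is.null(tw$ace)) {
      lines <- c(lines, sprintf(
        "  %-12s %.3f / %.3f / %.3f  (ICC MZ %.3f, DZ %.3f; %d+%d pairs)",
        nm, tw$ace$a2, tw$ace$c2, tw$ace$e2, tw$icc_mz$r, tw$icc_dz$r,
        tw$n_pairs_mz, tw$n_pairs_dz))
    } else {
      lines <- c(lines, sprintf("  %-12s too few pairs (%d MZ, %d DZ)",
                                nm, tw$n_pairs_mz, tw$n_pairs_dz))
    }
  }
  lines
}
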