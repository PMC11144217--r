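# Univariate twin analysis: intraclass correlations by zygosity and
# maximum-likelihood ACE variance decomposition.
#
# The ACE likelihood is the exchangeable bivariate normal: within-pair
# covariance A + C for MZ pairs, 0.5 A + C for DZ pairs, total variance
# A + C + E. Rotating each pair to its (scaled) sum and difference
# diagonalizes the covariance, so the whole log-likelihood depends on the
# data only through per-zygosity sums of squares — fitting and profiling are
# O(1) in the number of pairs after one pass.

#' Build twin pair records from a cohort table
#'
#' Reshapes an individual-level cohort into one row per family with the trait
#' for each twin. Complete pairs only: families reduced to a single member by
#' upstream filters, and pairs where either twin is missing the trait, are
#' dropped.
#'
#' @param cohort Cohort `data.frame` with `family_id`, `zygosity`, and the
#'   trait column.
#' @param trait Name of the trait column.
#' @return `data.frame` with `family_id`, `zygosity`, `t1`, `t2`.
#' @export
twin_pairs <- function(cohort, trait) {
  if (!trait %in% names(cohort)) {
    gpad_stop(sprintf("twin_pairs: no column '%s'", trait), "gpad_validation_error")
  }
  # complete pairs only: families reduced to one member (e.g. by upstream
  # filters) are dropped; more than two members is a malformed table
  counts <- table(cohort$family_id)
  if (any(counts > 2L)) {
    gpad_stop("twin_pairs: some families have more than two individuals",
              "gpad_validation_error")
  }
  cohort <- cohort[cohort$family_id %in% names(counts)[counts == 2L], ,
                   drop = FALSE]
  if (nrow(cohort) == 0) {
    gpad_stop("twin_pairs: no complete pairs", "gpad_empty_error")
  }
  ord <- order(cohort$family_id)
  d <- cohort[ord, ]
  fams <- unique(d$family_id)
  first <- match(fams, d$family_id)
  t1 <- d[[trait]][first]
  t2 <- d[[trait]][first + 1L]
  zy <- d$zygosity[first]
  if (any(zy != d$zygosity[first + 1L])) {
    gpad_stop("twin_pairs: zygosity differs within a family", "gpad_validation_error")
  }
  ok <- !is.na(t1) & !is.na(t2)
  data.frame(family_id = fams[ok], zygosity = zy[ok], t1 = t1[ok], t2 = t2[ok],
             stringsAsFactors = FALSE)
}

#' Twin intraclass correlation
#'
#' One-way ANOVA intraclass correlation for pairs (equivalent to the
#' double-entry correlation up to degrees of freedom), with a Fisher-z
#' confidence interval on the pair count.
#'
#' @param pairs Output of [twin_pairs()], or any data frame with `t1`, `t2`
#'   (and `zygosity` if `zygosity` is given).
#' @param zygosity Optional `"MZ"`/`"DZ"` filter.
#' @param conf Confidence level.
#' @return List with `r`, `lower`, `upper`, `n_pairs`.
#' @export
intraclass_corr <- function(pairs, zygosity = NULL, conf = 0.95) {
  d <- pairs
  if (!is.null(zygosity)) d <- d[d$zygosity == zygosity, , drop = FALSE]
  n <- nrow(d)
  if (n < 5) gpad_stop("intraclass_corr: need >= 5 complete pairs",
                       "gpad_insufficient_data")
  x1 <- d$t1; x2 <- d$t2
  if (sd(c(x1, x2)) == 0) gpad_stop("intraclass_corr: zero variance",
                                    "gpad_degenerate_error")
  m <- (x1 + x2) / 2
  g <- mean(c(x1, x2))
  msb <- 2 * sum((m - g)^2) / (n - 1)
  msw <- sum((x1 - x2)^2) / (2 * n)
  r <- (msb - msw) / (msb + msw)
  crit <- qnorm(1 - (1 - conf) / 2)
  se <- 1 / sqrt(n - 3)
  rc <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  list(r = r, lower = tanh(atanh(rc) - crit * se),
       upper = tanh(atanh(rc) + crit * se), n_pairs = n)
}

#' Falconer closed-form ACE estimates
#'
#' `a2 = 2 (r_mz - r_dz)`, `c2 = r_mz - a2`, `e2 = 1 - r_mz`, each clipped to
#' `[0, 1]` with a flag when clipping occurred. Used as the sanity oracle and
#' starting point for [fit_ace()].
#'
#' @param r_mz,r_dz MZ and DZ intraclass correlations, each in `(-1, 1)`.
#' @return List with `a2`, `c2`, `e2`, `clipped`.
#' @export
#' @examples
#' falconer(0.8, 0.5)  # a2 = 0.6, c2 = 0.2, e2 = 0.2
falconer <- function(r_mz, r_dz) {
  for (r in c(r_mz, r_dz)) {
    if (!is_number(r) || abs(r) >= 1) {
      gpad_stop("falconer: correlations must lie in (-1, 1)", "gpad_validation_error")
    }
  }
  a2 <- 2 * (r_mz - r_dz)
  c2 <- r_mz - a2
  e2 <- 1 - r_mz
  raw <- c(a2 = a2, c2 = c2, e2 = e2)
  clipped <- any(raw < 0 | raw > 1)
  out <- pmin(pmax(raw, 0), 1)
  list(a2 = out[["a2"]], c2 = out[["c2"]], e2 = out[["e2"]], clipped = clipped)
}

# Sufficient statistics for the exchangeable bivariate normal likelihood:
# per zygosity, the sums of squares of the centered scaled sums and
# differences, after concentrating out the per-zygosity mean.
.twin_suffstats <- function(t1, t2) {
  n <- length(t1)
  mu <- mean(c(t1, t2))
  s <- (t1 + t2 - 2 * mu) / sqrt(2)
  d <- (t1 - t2) / sqrt(2)
  list(n = n, ss_s = sum(s^2), ss_d = sum(d^2))
}

# Negative log-likelihood at raw components (A, C, E) given suff stats.
.ace_nll <- function(par, st_mz, st_dz) {
  A <- par[1]; C <- par[2]; E <- par[3]
  v <- A + C + E
  nll <- 0
  for (g in list(list(st = st_mz, cc = A + C), list(st = st_dz, cc = 0.5 * A + C))) {
    vp <- v + g$cc
    vm <- v - g$cc
    if (vp <= 0 || vm <= 0) return(1e10)
    nll <- nll + 0.5 * (g$st$n * log(2 * pi * vp) + g$st$ss_s / vp +
                          g$st$n * log(2 * pi * vm) + g$st$ss_d / vm)
  }
  nll
}

# Minimize the ACE nll from several starts; returns par and objective.
.ace_fit_raw <- function(st_mz, st_dz, starts) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      nlminb(s, .ace_nll, st_mz = st_mz, st_dz = st_dz,
             lower = c(0, 0, 1e-8), upper = c(10, 10, 10)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) gpad_stop("fit_ace: optimization failed to converge",
                               "gpad_fit_error")
  best
}

# Profile nll with the proportion of one component fixed at p.
# comp: 1=A, 2=C, 3=E. Free parameters: total variance v and the split q of
# the remaining variance between the other two components.
.ace_profile_nll <- function(p, comp, st_mz, st_dz, start_v = 1, start_q = 0.5) {
  obj <- function(par) {
    v <- par[1]; q <- par[2]
    if (v <= 0) return(1e10)
    rest <- (1 - p) * v
    comps <- numeric(3)
    comps[comp] <- p * v
    others <- setdiff(1:3, comp)
    comps[others[1]] <- q * rest
    comps[others[2]] <- (1 - q) * rest
    comps[3] <- max(comps[3], 1e-10)
    .ace_nll(comps, st_mz, st_dz)
  }
  fit <- nlminb(c(start_v, start_q), obj, lower = c(1e-8, 0), upper = c(10, 1))
  fit$objective
}

#' Maximum-likelihood ACE fit for twin pairs
#'
#' Maximizes the exchangeable bivariate-normal log-likelihood with the
#' classical twin structure (MZ within-pair covariance `A + C`, DZ
#' `0.5 A + C`) under non-negativity constraints, starting from the Falconer
#' estimates plus jittered multi-starts. Confidence intervals for the
#' standardized variance proportions come from the profile likelihood
#' (default) or a nonparametric bootstrap over families.
#'
#' @param mz,dz Twin-pair data for each zygosity: data frames with `t1`, `t2`
#'   (e.g. from [twin_pairs()]) or two-column matrices.
#' @param ci `"profile"`, `"bootstrap"` or `"none"`.
#' @param conf Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples when `ci = "bootstrap"`.
#' @param n_starts Number of jittered starting points beyond Falconer.
#' @param seed Seed for jitter and bootstrap.
#' @return List of class `gpad_ace`: `a2`, `c2`, `e2` (proportions summing to
#'   1), `ci` (3 x 2 matrix or `NULL`), `loglik`, `total_var`, `converged`,
#'   `iterations`, `boundary` (flag: any component at 0), `n_mz`, `n_dz`.
#' @export
fit_ace <- function(mz, dz, ci = c("profile", "bootstrap", "none"),
                    conf = 0.95, n_boot = 200, n_starts = 5, seed = 1) {
  ci <- match.arg(ci)
  as_pair <- function(x) {
    if (is.data.frame(x) && all(c("t1", "t2") %in% names(x))) {
      cbind(x$t1, x$t2)
    } else {
      m <- as.matrix(x)
      if (ncol(m) != 2) gpad_stop("fit_ace: pairs must have two trait columns",
                                  "gpad_validation_error")
      m
    }
  }
  pm <- as_pair(mz); pd <- as_pair(dz)
  pm <- pm[complete.cases(pm), , drop = FALSE]
  pd <- pd[complete.cases(pd), , drop = FALSE]
  if (nrow(pm) < 5 || nrow(pd) < 5) {
    gpad_stop("fit_ace: need >= 5 complete pairs per zygosity group",
              "gpad_insufficient_data")
  }
  st_mz <- .twin_suffstats(pm[, 1], pm[, 2])
  st_dz <- .twin_suffstats(pd[, 1], pd[, 2])

  vtot <- var(c(pm[, 1], pm[, 2], pd[, 1], pd[, 2]))
  r_mz <- tryCatch(intraclass_corr(data.frame(t1 = pm[, 1], t2 = pm[, 2]))$r,
                   gpad_error = function(e) 0.5)
  r_dz <- tryCatch(intraclass_corr(data.frame(t1 = pd[, 1], t2 = pd[, 2]))$r,
                   gpad_error = function(e) 0.25)
  falc <- falconer(max(min(r_mz, 0.99), -0.99), max(min(r_dz, 0.99), -0.99))
  start0 <- pmax(c(falc$a2, falc$c2, falc$e2) * vtot, 1e-4)
  set.seed(seed)
  starts <- c(list(start0), lapply(seq_len(n_starts), function(i) {
    pmax(start0 * exp(rnorm(3, 0, 0.3)), 1e-4)
  }))
  best <- .ace_fit_raw(st_mz, st_dz, starts)
  comps <- pmax(best$par, 0)
  v <- sum(comps)
  props <- comps / v
  boundary <- any(props < 1e-6)

  ci_mat <- NULL
  if (ci == "profile") {
    crit <- qchisq(conf, df = 1)
    nll_min <- best$objective
    ci_mat <- matrix(NA_real_, 3, 2,
                     dimnames = list(c("a2", "c2", "e2"), c("lower", "upper")))
    for (comp in 1:3) {
      p_hat <- props[comp]
      dev <- function(p) {
        2 * (.ace_profile_nll(p, comp, st_mz, st_dz, start_v = v,
                              start_q = 0.5) - nll_min) - crit
      }
      # lower bound
      lo <- 0
      if (p_hat > 1e-6 && dev(max(p_hat * 1e-3, 1e-8)) > 0) {
        lo <- uniroot(dev, c(max(p_hat * 1e-3, 1e-8), p_hat), tol = 1e-4)$root
      }
      # upper bound
      hi <- 1
      if (p_hat < 1 - 1e-6 && dev(1 - 1e-8) > 0) {
        hi <- uniroot(dev, c(p_hat, 1 - 1e-8), tol = 1e-4)$root
      }
      ci_mat[comp, ] <- c(lo, hi)
    }
  } else if (ci == "bootstrap") {
    set.seed(seed + 1L)
    boots <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      im <- sample.int(nrow(pm), replace = TRUE)
      id <- sample.int(nrow(pd), replace = TRUE)
      stm <- .twin_suffstats(pm[im, 1], pm[im, 2])
      std <- .twin_suffstats(pd[id, 1], pd[id, 2])
      fb <- tryCatch(.ace_fit_raw(stm, std, list(pmax(comps, 1e-4))),
                     gpad_error = function(e) NULL)
      if (!is.null(fb)) {
        cb <- pmax(fb$par, 0)
        boots[b, ] <- cb / sum(cb)
      }
    }
    alpha <- 1 - conf
    ci_mat <- t(apply(boots, 2, quantile,
                      probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
    dimnames(ci_mat) <- list(c("a2", "c2", "e2"), c("lower", "upper"))
  }

  structure(list(
    a2 = props[1], c2 = props[2], e2 = props[3],
    ci = ci_mat, loglik = -best$objective, total_var = v,
    converged = best$convergence == 0, iterations = best$iterations,
    boundary = boundary, n_mz = st_mz$n, n_dz = st_dz$n
  ), class = "gpad_ace")
}

#' @export
print.gpad_ace <- function(x, ...) {
  cat("ACE maximum-likelihood fit\n")
  cat(sprintf("  pairs: %d MZ, %d DZ   logLik %.2f   converged: %s\n",
              x$n_mz, x$n_dz, x$loglik, x$converged))
  for (nm in c("a2", "c2", "e2")) {
    line <- sprintf("  %s = %.3f", nm, x[[nm]])
    if (!is.null(x$ci)) {
      line <- sprintf("%s  [%.3f, %.3f]", line, x$ci[nm, 1], x$ci[nm, 2])
    }
    cat(line, "\n")
  }
  invisible(x)
}
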