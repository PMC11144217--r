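---
title: "Methods: genomic achievement discrepancies, slopes, and twin models"
author: "gpadelta maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic achievement discrepancies, slopes, and twin models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpadelta)
```

## The problem

A child is *underachieving* when their school performance falls below what
some predictor says they should attain. Classically the predictor is tested
cognitive ability (*g*); genomically, it can be a polygenic score (GPS) — a
standardized weighted sum of trait-associated allele counts, consumed here as
a precomputed column. Subtracting the standardized prediction from
standardized observed achievement,

$$\mathrm{GPA}\Delta_i = z(\mathrm{ach}_{7})_i - z(\mathrm{GPS})_i,$$

turns under/over-achievement into one continuous scale: negative values mean
the child performs below their genomic prediction, positive above. The
package quantifies how these discrepancies, formed at the first school age,
evolve over subsequent ages: per-individual achievement slopes, the
percentage of the initial discrepancy eliminated by the final age, extreme
achiever groups, covariate-adjusted regressions, and twin ACE decompositions
of the discrepancy itself.

Because cohorts carrying this data are access-restricted, everything runs
against a bundled synthetic twin-cohort generator whose population moments
are known in closed form. That duality — simulator vs `theoretical_covariance()`
oracle — is what makes the analysis testable offline.

## The generative model

For family $f$ with twins $i \in \{1, 2\}$:

* $A_1 \sim N(0,1)$; $A_2 = A_1$ for MZ pairs, else
  $A_2 = 0.5 A_1 + \sqrt{0.75}\,\eta$ — the classical twin-design genetic
  correlations of 1 and 0.5.
* $C_f \sim N(0,1)$ shared by the pair; $S_i \sim N(0,1)$ a stable
  individual factor; all residuals independent standard normals.
* Polygenic score: $\mathrm{GPS}_i = \kappa A_i + \sqrt{1-\kappa^2}\,\nu_i$,
  so $\kappa$ is the GPS–genotype correlation.
* Achievement of subject $s$ at age $t$:
  $$X_{i,t,s} = b_t A_i + \sqrt{c^2}\, C_f + u\, S_i +
    r_t\left(\sqrt{\rho}\,\varepsilon_{i,t} +
    \sqrt{1-\rho}\,\varepsilon_{i,t,s}\right),$$
  with $b_t = v_t/\kappa$ solved so that
  $\mathrm{corr}(\mathrm{GPS}, X_{t}) = v_t$, the configured per-age
  validity, exactly; $r_t$ makes each subject score unit-variance.
* Family SES loads on the pair's mean genetic factor and on $C_f$;
  the age-7 ability proxy $g$ loads on $A$ and $S$.
* Missingness is i.i.d. per individual and age with configured
  probabilities; science at age 7 is structurally missing (all `NA`),
  mirroring curricula where science is not assessed at the first key stage.

Feasibility is validated up front: $b_t \le \sqrt{a^2}$ (per-age genetic
variance cannot exceed the stable propensity's) and
$1 - b_t^2 - c^2 - u^2 \ge 0$ (non-negative residual variance; exactly zero
is allowed so the fully deterministic world with
$\kappa = 1, v_t = 1$ — achievement $\equiv$ GPS — remains expressible).

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| `ages` | 7, 9, 12, 16 | the four UK key-stage assessment ages |
| `gps_validity` | 0.28, 0.27, 0.26, 0.43 | the published per-age GPS–achievement correlations this world emulates (age 9 interpolated) |
| `kappa` | 0.6 | must exceed $\max_t v_t/\sqrt{a^2}$; 0.6 leaves headroom while keeping the GPS an imperfect proxy |
| `a2`, `c2` | 0.70, 0.15 | stable-propensity ACE shares typical of school achievement; $e^2 = 0.15$ implied |
| `stability` | 0.5 | not published for the source cohort; calibrated once so cross-age achievement correlations land at 0.60–0.73 and per-individual slopes have realistic spread |
| `ses_load_g`, `ses_load_c` | 0.30, 0.45 | closed form gives corr(SES, age-7 achievement) ≈ 0.302, matching the ≈ 0.30 emulation target |
| `g_load_a`, `g_load_s` | 0.40, 0.65 | gives corr(g, achievement) ≈ 0.50 and corr(GPAΔ, cogΔ) ≈ 0.36–0.38, the "moderately correlated" target |
| `attrition` | 0.30, 0.65, 0.50, 0.25 | reproduces the published per-wave sample sizes relative to the genotyped cohort; implies P(≥ 3 observed ages) ≈ 0.42, matching the published final-sample fraction |
| `residual_cor` | 0.7 | share of each age residual common to subjects, so same-age subject scores correlate beyond the factors, as real marks do |
| `sex_beta`, `age_beta` | 0 | the emulated correlations (−0.03, 0.10) are near zero; nonzero values are configurable but make the closed-form covariance approximate |

These are stated once and not tuned against test outcomes. Reproducibility:
one master seed spawns a per-family substream (`family_seed(seed, f)`), so
the same seed is bit-identical and enlarging `n_pairs` never reshuffles
earlier families.

### What the generator does *not* emulate

Linear-Gaussian factors only: no genotype-level simulation, no LD structure
or score construction, no ancestry heterogeneity, no school/classroom
clustering, no floor/ceiling effects in graded scores, no
missing-not-at-random attrition, and a single genetic factor — so the GPS
exhausts its genetic signal through $A$. A green test therefore certifies
the machinery on this stated world, not the behaviour of any real cohort.

## Numerical and procedural choices

**Standardization reference.** z-scores are computed on the analysis sample
*after* the ≥ 3-of-4-ages inclusion filter, so downstream means are
interpretable relative to the analysed sample. (Whether the source analysis
standardized within the genotyped subsample is unstated; this is the
package's choice.)

**Composites.** Per-age composites are the mean of available standardized
subject scores, missing when fewer than `min_subjects` (default 2) are
observed — which is what lets the structurally missing age-7 science column
pass through — then re-standardized.

**Deltas.** Missing if either component is missing. The difference form is
primary; the residualized form (re-standardized OLS residual) is provided
because the two are close whenever the achievement–GPS correlation is
modest: the exact relation is
$\mathrm{corr}(a - p,\ \mathrm{resid}) = \sqrt{(1+r)/2}$, about 0.80 at
$r = 0.28$ — strong agreement, though not the near-unity sometimes assumed.
The GPS is assumed already residualized for array/batch/ancestry components
upstream.

**Slopes.** Plain per-individual OLS of standardized achievement on age in
raw years (centering cannot change the slope), over whichever ≥ 3 ages are
observed; fewer than 3 observed ages excludes the individual rather than
erroring the run.

**MAD filter.** The raw MAD — no 1.4826 consistency constant — because that
is the printed definition this package follows; the constant is available as
an option. One pass only (no re-estimation after removal), applied to raw
slopes *before* standardization (the alternative order is a documented
switch, and is scale-free anyway since the mask depends only on ranks of
deviations). "Exceeding 3 MAD" is strict: a value at exactly the threshold
is retained. A zero MAD with non-constant data warns and removes nothing.

**Regression percentage.** $(1 - \Delta_{16}/\Delta_7)\cdot 100$ explodes
for near-zero $\Delta_7$; the literal reading handles this only through the
trimmed mean, so the default is `eps = 0` with an optional `eps` exclusion.
The "5% trimmed mean" drops `floor(n × 0.05)` observations from *each* tail
(the convention of common statistical software; 2.5%-per-tail is a
parameter away). Group percentages are reported in two modes side by side —
from group-mean deltas and as the trimmed mean of members' individual
percentages — because the source convention is unstated.

**Groups and deciles.** Relative groups cut at `mean(Δ) ± 1·sd(Δ)`; the
centering check is scale-free because Δ's natural SD is
$\sqrt{2(1-r)} \ne 1$. Absolute groups are the subset additionally beyond
∓1 on the achievement z-scale. Deciles use a stable `(delta, id)` sort;
group sizes differ by at most one, extras going to the lowest deciles. A
constant delta vector yields no extremes rather than everyone-extreme.

**Hierarchical regression.** "Unique variance" is the semi-partial
(increment-to-R²) definition: $R^2(\text{model}) - R^2(\text{model without
focal})$; the nested F compares residual sums of squares against Model 1
with exact degrees of freedom. Complete-case analysis throughout, matching
an analysis that reports varying Ns without imputation. Covariates enter in
the order sex, age-at-test, SES.

**Cross-validation.** Repeated k-fold (default 10 × 3) with folds
stratified by outcome decile to stabilize small-fold variance (plain random
folds available); held-out R² is the squared predicted–observed correlation;
final weights come from the full-sample fit; a constant-target fold triggers
a logged refold with a shifted seed.

**Dependent correlations.** Zou's (2007) asymmetric CI for two overlapping
dependent correlations, using the Pearson–Filon sampling correlation between
the estimates; validated against a percentile bootstrap in the test suite.

**ACE fitting.** Rotating each pair to scaled sum and difference
diagonalizes the exchangeable bivariate-normal covariance, so the
log-likelihood depends on the data only through per-zygosity sums of squares
— fitting and profiling are O(1) after one pass. Components are constrained
non-negative; optimization starts from the Falconer closed form plus five
jittered multi-starts; means are concentrated out per zygosity group.
Profile-likelihood CIs for each standardized component fix its proportion,
re-optimize total variance and the split of the remainder, and invert the
$\chi^2_1$ deviance by root-finding; bounds touching 0 or 1 are reported as
such and flagged as boundary solutions. A nonparametric bootstrap over
families is the alternative.

At 5000 + 5000 pairs the sampling SD of $\hat a^2$ is still ≈ 0.02, so the
package's recovery tests assert accuracy on means over replicates (a bias
check) rather than on single draws; unbiasedness was separately verified at
$n = 2\times10^5$ pairs.

**Twin treatment of the discrepancy.** Each simulated twin carries their own
GPS, so the GPS's unique noise $\nu$ loads the non-shared component of
GPAΔ and the default world's GPAΔ heritability is *low* — unlike the
strikingly high estimate reported on real data, where only one twin per
pair was genotyped and the pair-level score treatment is not detailed. The
package does not resolve that ambiguity; it fits whatever trait column it is
given. That a difference score can be *more* heritable than the trait it is
built from is nonetheless reproducible here: with a near-perfectly heritable
score ($\kappa = 0.9$) weakly loading achievement ($b = 0.2$), the
difference's genetic share is $(b-\kappa)^2 / (2 - 2b\kappa) \approx 0.30$
against the trait's own $b^2 = 0.04$; the test suite exercises exactly this
configuration.

**Pipeline order.** Inclusion filter → standardization → composites → deltas
→ slopes → MAD filter → analyses, recorded in the output manifest with row
counts at every stage. All randomness flows from the one master seed; output
files carry no timestamps, so a rerun with the same configuration is
byte-identical.

## A small demonstration

```{r demo, eval = FALSE}
cfg <- run_config(
  simulate = generator_config(n_pairs = 1000, extra_gps = 4),
  seed = 1, ace_ci = "none"
)
res <- run_pipeline(cfg)
res$models$delta_slope_cor      # negative correlation with Fisher-z CI
res$models$overall_regression   # trimmed-mean percentage regressed
res$group_summary$regression    # per-group percentages, both modes
res$twin$gpa_delta$ace          # ACE decomposition of the discrepancy
```

The central phenomenon — discrepancies at the first age predicting
*opposite-signed* achievement slopes — holds in this world for two
compounding reasons: the configured GPS validity rises with age (real
convergence toward the genomic prediction), and the age-7 measurement error
enters both the discrepancy and the slope with opposite signs (pure
regression to the mean). The package's acceptance tests separate the two by
rerunning the analysis under constant validity, where only the second
mechanism survives and the correlation stays negative — a caveat to carry
into any substantive interpretation.

## Known limitations

* Univariate ACE only: no bivariate/sex-limitation/ADE models, no
  equal-environments sensitivity analysis.
* Per-individual OLS slopes, not mixed-effects growth curves, by design.
* No plotting layer; the tidy CSV outputs are plot-ready.
* The CLI accepts JSON configuration only (no YAML parser among the
  package's dependencies).
* Simulator limitations listed above; in particular, results on the default
  world should never be quoted as estimates for any real cohort.
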