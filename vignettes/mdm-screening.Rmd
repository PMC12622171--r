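---
title: "Urinary microbial-metabolite exceedance screening: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urinary microbial-metabolite exceedance screening: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmscreen)
```

## The screening problem

A subset of children with autism spectrum disorder (ASD) shows strongly
disrupted gut microbial communities, and the bacteria and yeasts involved
excrete metabolites — p-cresol and its sulfate conjugate, indoxyl sulfate,
arabinitol and related compounds — that end up in urine at concentrations
occasionally hundreds of times above those of typically developing (TD)
children. Because humans neither produce these compounds themselves nor
obtain them from diet in meaningful amounts, an extreme urinary level of even
a single such microbially-derived metabolite (MDM) is a plausible marker of
gut dysbiosis.

`mdmscreen` implements the analysis pipeline built around that idea:

1. **Creatinine normalization.** Spot-urine concentrations depend on
   hydration. Each analyte is divided by urinary creatinine, giving µmol of
   analyte per mmol creatinine. Ratio pseudo-markers (e.g. the Phe/Tyr
   ratio) are already dimensionless and pass through unchanged.
2. **TD reference ranges.** For each metabolite the reference interval is
   the *full observed range* — minimum to maximum — of the normalized values
   in the TD group. No percentile trimming is applied: the screening
   question is "is this child above *any* TD child?", so the upper bound is
   the TD maximum itself.
3. **MDM Total Score.** A participant gets one point per metabolite whose
   normalized value lies strictly above the TD maximum (strictly below the
   TD minimum, for markers configured as depleted). The score is a count,
   not a test statistic; no multiplicity correction applies to it.
4. **Classification.** A participant screens positive when their score
   reaches a cut-off, by default 1 — one or more metabolites beyond the
   entire TD range.

## Tautological in-sample specificity, and what deployment changes

When the ranges are built from the same TD group being evaluated, every TD
value lies inside its own group's min–max interval by construction, so every
TD score is 0 and specificity is exactly 100%. The package reproduces this
as a definitional guarantee (it is also the single quantity the acceptance
script recomputes), but labels the evaluation mode prominently, because the
guarantee does **not** transfer to new samples.

For a fresh TD-like participant and a continuous marginal, the probability
of landing above the maximum of an `n`-sample reference is `1/(n+1)` per
metabolite — the classical order-statistic result. With `n = 47` TD
reference children and 24 scored metabolites, a fresh TD child screens
positive with probability roughly `1 - (1 - 1/48)^24 ≈ 0.40`, i.e. deployed
specificity near 60%, not 100%. The bundled analysis scripts demonstrate
exactly this: `analysis/03_scoring.R` freezes the in-sample ranges, applies
them to a second simulated cohort, and observes deployed specificity of
about 62%. This leakage is a property of min–max reference ranges, shrinks
only like `1/n` in the reference size, and is the main statistical caveat of
the method. `score_cohort()` therefore distinguishes `insample` and
`deploy` modes explicitly, and all reports carry the mode label.

## Univariate statistics

The per-metabolite report mirrors the standard two-group screening table:

* **Welch's t-test** (`welch_t()`, via `stats::t.test` with
  `var.equal = FALSE`) on the normalized values, and again after a
  **square-root transform** (`sqrt_transform_then_test()`). Urinary
  concentrations are strongly right-skewed — in the simulated cohorts the
  heavy spike tail makes the raw-scale test visibly underpowered, and the
  sqrt-scale test recovers most of the loss — which is why both p-values are
  emitted.
* **Benjamini–Hochberg q-values** (`bh_fdr()`, via `stats::p.adjust`)
  over the raw-scale p-values, flagged at q < 0.05. The quantitative-assay
  style report can omit q (`include_q = FALSE`) when no correction is
  wanted.
* **AUROC** by the Mann–Whitney rank formula with half-credit ties,
  oriented so values above 0.5 mean ASD is stochastically larger.
* **% difference of group means**, `100 (m_ASD - m_TD)/m_TD`, computed from
  the means rather than copied from any report, and undefined (NA) when the
  reference mean is zero.
* **% of ASD above the TD range** (consistent by construction with the
  scoring indicators) and **% below LOD** pooled over both groups.
* **Pearson correlations** (pairwise-complete) between metabolites;
  Spearman available by flag. The coefficient is a deliberate default — the
  co-elevation structure is approximately multiplicative, and either choice
  only affects the descriptive supplement table.

Report formatting (`format_report()`) rounds percent columns to integers,
AUROC to two decimals and p/q to two significant figures, matching the usual
presentation of such tables.

## Censoring and missingness

Below-LOD cells are first-class: the CSV dialect uses a literal `"<LOD"`
token, the cohort object keeps a logical censoring mask, and
`normalize_by_creatinine()` applies one of three explicit policies —
`half_lod` (default: impute LOD/2 before normalization), `zero`, or
`exclude`. Half-LOD is the common metabolomics convention for summary
statistics; for exceedance scoring the choice is immaterial in the high
direction, because an imputed low value can never clear a TD maximum.
Missing (unmeasured) cells are excluded pairwise from every statistic and
never imputed. Censoring counts are conserved by the imputing policies, a
property the tests assert.

## Fisher discriminant subset search

The multivariate comparison fits a Fisher linear discriminant on selected
features: the weight vector solves `(S_W + ridge·I) w = μ_ASD − μ_TD` with
`S_W` the pooled within-class scatter. Numerical choices:

* features default to sqrt-transformed normalized values, consistent with
  the univariate re-test; `log1p` is available;
* ridge defaults to 0, switching to `1e-6 · trace(S_W)/p` (with a message)
  when the scatter's condition number exceeds `1e10`; a singular scatter
  with ridge 0 is an error that advises regularisation;
* the projection is oriented per fit so the ASD training mean exceeds the
  TD training mean, which prevents sign flips across cross-validation folds;
* **LOOCV AUROC** refits on each leave-one-out fold, scores the held-out
  participant, and computes one AUROC on the pooled held-out scores —
  per-fold AUROC is undefined for single observations, so pooling is the
  only coherent definition; the per-fold orientation rule above is what
  makes pooling safe.

`combination_search()` enumerates all k-subsets of the feature pool in
lexicographic order under an explicit budget (error, stating `C(pool, k)`,
when exceeded), retains subsets above an AUROC floor and sorts by AUROC with
a lexicographic tie-break, so identical inputs always give identical ranked
lists. LOOCV per subset is flag-gated for cost; the bundled driver instead
re-evaluates only the leading in-sample subsets by LOOCV.

## The synthetic-cohort generator

No participant-level data accompany the published study, so the package
ships a generator whose defaults emulate the targeted-assay study arm, and
every downstream stage is tested against its ground truth.

**Baseline.** Each metabolite's creatinine-normalized level in unaffected
children is log-normal (`log_sd = 1` by default), anchored so the TD mean
matches the typical TD level of the corresponding assayed metabolite. Raw
concentrations are baseline × creatinine with creatinine itself log-normal
(median 8 mmol/L, log-sd 0.5 — plausible spot-urine variation in children),
so normalization recovers the baseline exactly and jointly rescaling raw
values and creatinine is a no-op.

**Elevations.** A participant–metabolite elevation event multiplies the
baseline by a log-uniform fold on `(10, 1000)`; the upper decades reproduce
the "100–1000×" extremes while the lower edge keeps moderate elevations in
play. Markers configured as depleted are divided instead. Events for
metabolite `m` fire with marginal probability `p_m`; with probability
`family_coupling` the event is gated by a per-participant, per-family latent
dysbiosis indicator (fired with probability `max_m p_m` within the family,
the largest gate that preserves every marginal exactly). Coupling 0 gives
independent events; coupling 1 makes each family all-or-none.

**Calibration.** The observed fraction of ASD participants above a
*finite* TD maximum mixes two sources: true elevations, which clear the
maximum with probability `h` (estimated by Monte Carlo from the fold
distribution and baseline spread; ≈ 0.92 under the defaults), and
order-statistic leakage `1/(n_td+1)` from non-elevated values.
`calibrate_to_table()` inverts `target = p·h + (1−p)·leakage` per
metabolite; targets below the leakage floor clamp to `p = 0`, and targets
above `h` are rejected as infeasible. The default configuration calibrates
to the targeted-assay exceedance fractions (0–21% per metabolite) at
52 ASD / 47 TD. The family coupling default of 0.7 was chosen once, by
simulating the family-level fractions of ASD participants with any elevated
phenylalanine-, tryptophan-, or yeast-derived marker and matching the
reported 57% / 42% / 16% pattern (0.7 gives ≈ 54% / 45% / 16%, with ≈ 79%
showing any elevated marker); it was fixed before any downstream evaluation
and is not adjusted thereafter.

**Censoring.** Per-metabolite LODs sit at the requested quantile of the
pooled raw marginal (up to 95% for the least detectable markers); cells
below them are censored, flagged, and the realized LOD is recorded on the
generated panel so imputing policies work downstream.

**Reproducibility.** One master seed drives named per-component substreams
(creatinine, ages, each family, each metabolite) through R's default
Mersenne-Twister; a metabolite's draws depend only on the master seed and
its own identifier, so extending the panel does not reshuffle existing
columns. Identical seed and configuration give bit-identical cohorts.

**What the generator does not emulate.** Assay error and batch effects,
metabolite misidentification, age or sex effects on the microbiome,
non-log-normal baseline shapes, and correlation between baselines (only
elevation *events* are correlated). Passing tests therefore demonstrate the
pipeline's internal correctness and calibration under a clean mechanistic
model, not clinical performance on real cohorts.

## Scoring conventions and edge cases

* Exceedance is **strict**: a value exactly at the TD maximum scores 0.
  "Above any TD child" is read as strictly above; ties have probability
  zero for continuous data and the convention only matters for imputed or
  rounded values.
* All default-panel metabolites score in the high direction. Depleted
  markers (such as N-formyl methionine in the untargeted panel) are
  supported via `direction = "low"` in the panel definition, scoring
  strictly below the TD minimum; the generator simulates them as
  multiplicative suppression.
* Two identical constant samples in `welch_t()` return `t = 0, p = 1` with
  a message; constant samples with different means are an error.
* A zero TD mean makes the percent difference undefined (NA), never
  infinite.
* Reference ranges are serializable JSON artifacts stamped with a panel
  hash, so frozen ranges cannot silently be applied under a different panel.

## Problem sizes

The test suite and bundled analyses use cohorts of 52/47 (the study-arm
geometry) down to 12–27 participants for oracle comparisons, 200-seed
Monte Carlo sweeps for calibration and sensitivity-recovery checks, and
~10,800 independent replicates for the order-statistic law; the exhaustive
search driver enumerates all 42,504 five-metabolite subsets and
cross-validates the leading twenty. These sizes were chosen to give
Monte-Carlo standard errors comfortably inside the asserted tolerances.

## Known limitations

* Min–max reference ranges are extremely sensitive to the reference-sample
  size and to any TD outlier; deployed specificity is structurally below
  the in-sample 100% (see above) and a single contaminated TD sample can
  hide true elevations for that metabolite.
* The sensitivity of the score is bounded by the biology it encodes: ASD
  participants without microbial co-elevation are invisible to it by
  design; under the calibrated defaults roughly one in five ASD
  participants carries no elevation at all.
* Welch's test on raw normalized values loses power under sparse extreme
  elevations; the sqrt-scale test partly compensates but neither is a
  substitute for methods that model the spike structure explicitly.
* The generator's calibration reproduces per-metabolite exceedance
  fractions and family-level co-elevation, but leaves the mean MDM Total
  Score to follow from those (≈ 2.1–2.25 under the defaults); reported
  study means of ~3.3 are not separately enforced, and no single
  configuration could satisfy both sets of published summaries at once.
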