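---
title: "Methods: quantifying the nodule size-density trade-off"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the nodule size-density trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduletrade)
```

## The biological question

Fungus-growing termites (Macrotermitinae) feed on fungal nodules — spherical
clusters of asexual spores that their *Termitomyces* cultivar produces on the
fungus garden. Different termite genera differ several-fold in the size of
their farming caste (the minor worker), and different *Termitomyces* clades
produce nodules of very different diameters. Two quantitative patterns
characterise this symbiosis:

1. **A size-number trade-off.** Per gram of fungus garden, cultivars that
   make larger nodules make proportionally fewer of them, so the product of
   average nodule volume `V` (mm³) and nodule density `D` (count g⁻¹) is
   approximately constant across nests. That constant `L = V × D` (mm³ g⁻¹)
   is the *production limit*: the total nodule volume a gram of garden can
   sustain.
2. **Size specificity.** Larger termite genera cultivate clades with larger,
   less numerous nodules, visible as a positive correlation between
   minor-worker head width and nodule diameter and a negative correlation
   with nodule density.

The package implements the full desk analysis for these questions — trait
quantification, trade-off model, group statistics — together with a
synthetic-survey generator so that every stage can be exercised and
calibrated without field data.

## The survey design being emulated

The reference design, returned by `default_survey_config()`, mirrors a field
survey of 43 nests from four genera (*Macrotermes*, *Odontotermes*,
*Ancistrotermes*, *Microtermes*). Per nest, the field protocol measures the
diameters of 50 fungal nodules from the fresh top quarter of one fungus
garden, counts the nodules in 1 g of garden, and averages the head widths of
three minor workers. One cultivar clade is recorded per nest.

Several defaults deserve comment:

* **Per-clade diameter means are placeholders.** The reference analysis
  reports only the *ordering* of clades by diameter (III > IV > VI > VII >
  V > II > I) and, indirectly, that the largest clade's nodule volume is
  roughly 166 times the smallest clade's. The defaults (0.45 mm for clade I
  up to 2.50 mm for clade III) honour both constraints but are configurable
  stand-ins, not published values.
* **Diameter distributions** are normal per clade with `sd = mean × CV/100`,
  truncated at a 0.05 mm floor so volumes stay positive. Configured CVs lie
  in 14–26%, inside the 12.4–31.9% stability band reported for real clades.
  A configuration whose truncation would discard more than 1% of draws is
  rejected outright — such a (mean, sd) pair signals a degenerate design,
  and silently truncating it would distort the distribution.
* **Density noise is multiplicative lognormal**, `D = L/V_true × exp(ε)`,
  `ε ~ N(0, σ²)`: density is a positive, count-like rate whose observed
  dispersion (CV 40.3–92.9% among nests) is far too skewed for additive
  normal noise. The default `σ = 0.5` gives a population density CV of
  `sqrt(exp(σ²) − 1) ≈ 53%`, inside that band; a smaller σ of 0.35 would
  give ≈ 36% and fall short of it. With `σ = 0` every nest sits exactly on
  the isoquant, which is what makes the generator a usable oracle for the
  fitter.
* **Compatibility weights encode size matching.** Each genus can only draw
  clades of commensurate nodule size (e.g. *Microtermes* draws clades I–II,
  *Macrotermes* clades III, IV and VI). This induces the positive
  head-width/diameter association the correlation stage is designed to
  detect; setting all weights equal removes the signal and provides the
  null model used for type-I calibration.
* **Hierarchical seeding.** The global seed initialises a L'Ecuyer-CMRG
  generator and each nest consumes its own sub-stream. Identical seeds give
  bit-identical tables (down to the serialized CSVs), and appending nests to
  the design leaves earlier nests' draws untouched.

What the generator deliberately does *not* emulate: spatial mound structure,
multi-strain gardens, termite harvesting feedback on density, and nest-level
random effects on diameter. The last point matters for interpretation:
because nodule diameters are i.i.d. within a clade, the among-nest CV of
nest *mean* diameters shrinks like `CV/sqrt(50)` (≈ 2–4%), much smaller than
the 12.4–31.9% among-nest CVs of real data, which include garden-level
variation. Passing tests therefore demonstrate the correctness of the
computations, not that real surveys are this well behaved. The pooled
per-nodule CV (available via `clade_summary(..., cv_method = "pooled")`)
recovers the configured clade CV and is the quantity used when checking the
generator's calibration.

## Trait quantification

`nest_traits()` reduces raw measurements to one row per nest. The order of
aggregation is fixed by the model's definition: the nest's volume is the
sphere volume **of the mean diameter**, `V = (4π/3)(d̄/2)³`, not the mean of
per-nodule volumes. The two differ by Jensen's inequality (for diameters 1
and 3 mm the former is 4π/3 ≈ 4.19 mm³, the latter ≈ 7.33 mm³); the model's
`V` is defined on the averaged diameter. Head widths are averaged
arithmetically. Nests with fewer than the expected 50 nodule measurements
are accepted with a warning (field losses happen); `strict_nodule_count =
TRUE` turns the warning into an error.

`clade_summary()` computes, per clade, the mean diameter, the among-nest CVs
of diameter and density, and a Shapiro–Wilk p-value for the per-nest mean
diameters. Choices made here:

* **CV uses the sample (n − 1) standard deviation** — the usual small-sample
  convention; the alternative denominator is not exposed.
* **The CV's analysis unit defaults to per-nest means** ("among nests"), with
  the pooled per-nodule alternative behind `cv_method = "pooled"`; no claim
  is made that either exactly reproduces any published CV.
* **Normality is assessed by Shapiro–Wilk at α = 0.05** on per-nest mean
  diameters, reported as a p-value and never used as a filter. The test is
  skipped (NA) below three nests, and its rejection rate on genuinely normal
  samples is verified in the test suite to sit near the nominal level
  (0.03–0.08 over 500 samples of n = 10).

## The isoquant model

`fit_isoquant()` estimates `L` in `L = V × D`. The model statement does not
name a regression response; the package treats **density as the response**,

\[ D_i = L / V_i + e_i, \]

because density is the single manual count (the noisier measurement) while
each volume derives from 50 averaged diameters. Minimising
`Σ (D_i − L/V_i)²` over the single parameter `L` is linear least squares in
disguise, with closed form

\[ \hat L = \frac{\sum D_i / V_i}{\sum 1 / V_i^2}, \qquad
   \mathrm{se}(\hat L) = \sqrt{\frac{SSE/(n-1)}{\sum 1/V_i^2}}, \]

using n − 1 degrees of freedom (one parameter). The iterative `nls` route is
seeded at the closed form and must agree with it to a relative 10⁻⁶; a
10⁴-point grid search over `[0, 2\hat L]` (`isoquant_grid()`) provides a
third, brute-force route, required to land within one grid step. This
"oracle triangle" runs over 100 random datasets in the test suite. Because
the objective is an exact quadratic in `L`, Gauss–Newton lands on the
optimum in one step; when started exactly there the step-halving line search
can fail to improve and the closed form — already the exact minimiser — is
kept.

Two alternative parameterisations are available behind the `response`
argument: `"volume"` (fit `V = L/D`) and `"geometric"` (the log-scale
orthogonal variant `exp(mean(log V D))`, which treats both variables
symmetrically). Default reported results use density-as-response. The fit is
made on per-nest points; collapsing to per-clade means first is a caller-side
`dplyr::summarise()` away and deliberately not a flag.

### Parameter recovery and the lognormal bias

`recover_production_limit()` simulates replicate surveys, refits each, and
reports bias, RMSE and the coverage of `±2 se`. Two systematic effects are
worth knowing:

* **Lognormal inflation.** Multiplicative noise `exp(ε)` has mean
  `exp(σ²/2) > 1`, so `E[\hat L] ≈ L exp(σ²/2)` — at σ = 0.2 a 2% inflation,
  at σ = 0.5 a 13% one. The recovery report states the expected factor and a
  corrected estimate that divides it out; the corrected bias at σ = 0.2 over
  200 replicates is within ±5%.
* **Interval coverage is design-dependent.** The se formula assumes additive
  homoscedastic density errors. Under multiplicative noise the residual
  scale is proportional to `L/V`, so when true volumes span two orders of
  magnitude (the seven-clade default design) the classical interval
  undercovers — measured coverage ≈ 0.7 rather than 0.95. Where the error
  model holds (nests sharing one true volume) coverage is nominal, and that
  is the condition under which the test suite checks it. For strongly
  heteroscedastic designs the `"geometric"` response is the better-specified
  choice.

## Group statistics

`anova_oneway()` is the classical fixed-effects decomposition computed from
its sums of squares (`F = (SSB/df_B)/(SSW/df_W)`), cross-checked in the test
suite against `stats::aov` to 10⁻¹⁰ on random datasets. `trait_anovas()`
applies it to the three study contrasts: head width across genera, and
diameter and density across clades. The analysis unit is the nest — nests,
not nodules, are the independent replicates; pooling all 2150 nodules into
one ANOVA is possible through `anova_oneway()` directly but is
pseudoreplication and not what the wrapper does. Welch's correction is not
applied (the classical test is what an unqualified "ANOVA" denotes), and the
three tests are reported without multiple-testing correction, as three
separate planned contrasts.

`correlate()` computes the Pearson correlation and OLS line after
log(n + 1)-standardising both variables (natural logarithm; the base is a
convention here, as it leaves r unchanged and only rescales the slope).
`trait_correlations()` applies it to head width vs diameter and head width
vs density. Under the size-matched default design the (+, −) sign pattern
reproduces in ≥95 of 100 seeded replicates; under uniform compatibility
weights the p < 0.05 rate sits at the nominal 5% (checked over 200
replicates with a binomial tolerance band of 2–18 rejections).

## Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages (traits → clade summaries → isoquant →
ANOVAs → correlations), validating the input tables first
(`validate_tables()` reports every violation with its table, row and file
line). The pipeline draws no random numbers: running it twice on the same
inputs writes byte-identical `report.json` files (floats serialized at 12
significant digits), with provenance carrying input hashes, options, seed
and package version.

The simulation-backed checks use these problem sizes, chosen so the whole
suite exercises the study-scale design while individual property checks stay
small: the full 43-nest × 50-nodule design for the acceptance-level checks,
200 replicates for recovery and type-I calibration, 100 for the sign-pattern
and oracle-triangle sweeps, 500 samples for the Shapiro calibration, and
5000 nodules per nest for moment-convergence checks.

## Worked example

```{r example, eval = FALSE}
survey <- simulate_survey(default_survey_config(seed = 1))
report <- run_pipeline(survey$nodules, survey$nests, cv_method = "pooled")
report$isoquant
tidy(report$isoquant)
autoplot(report$isoquant, log_scale = TRUE)
```

## Known limitations

* The generator's i.i.d.-within-clade diameters understate among-nest
  variation relative to real gardens (no nest random effect), as discussed
  above.
* The homoscedastic se of the isoquant fit undercovers under strong volume
  spread with multiplicative noise; use the geometric response or a
  resampling interval when that matters.
* Clade labels are taken as given categorical annotations; the package does
  not address sequence-based identification or phylogenetics.
* Densities are continuous rates by default; `round_density = TRUE` makes
  them integer counts at the cost of exact isoquant conservation in the
  noise-free case.
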