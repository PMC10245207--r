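# noduletrade

Fungus-growing termites (Macrotermitinae) live off the fungal nodules their
*Termitomyces* cultivar produces on the fungus garden. Across termite genera
and fungal clades, two patterns structure this symbiosis: a **size-number
trade-off** — cultivars that make larger nodules make proportionally fewer of
them — and **size specificity** — larger termite genera farm clades with
larger, less numerous nodules.

`noduletrade` is a tidyverse-style R package for the desk analysis of such
surveys. Its core is the one-parameter isoquant model

    L = V × D

where `V = (4π/3)(d̄/2)³` is the average nodule volume (mm³) of a nest,
`D` the nodule density (count per gram of fungus garden), and `L` the
*production limit* — the constant total nodule volume a gram of garden can
sustain (mm³ g⁻¹). With density as the response, least squares over `L` has
the closed form `L̂ = Σ(Dᵢ/Vᵢ) / Σ(1/Vᵢ²)`; the package fits it three ways
(closed form, `nls`, brute-force grid) and requires them to agree. Around the
model it provides:

* `simulate_survey()` / `default_survey_config()` — a seeded synthetic-survey
  generator emulating a 43-nest, 4-genus, 7-clade field design (50 nodule
  diameters and 3 minor-worker head widths per nest), with densities generated
  on the isoquant up to lognormal noise;
* `nest_traits()` / `clade_summary()` — per-nest and per-clade trait
  summaries: mean diameters, sphere volumes, coefficients of variation,
  Shapiro–Wilk normality checks;
* `fit_isoquant()` / `isoquant_grid()` / `recover_production_limit()` — the
  trade-off fit with uncertainty, an independent grid oracle, and a
  parameter-recovery simulation study (bias, RMSE, coverage);
* `anova_oneway()`, `correlate()`, `trait_anovas()`, `trait_correlations()` —
  the group-difference and log(n+1)-standardised association tests;
* `run_pipeline()` / `validate_tables()` — schema-validated end-to-end
  orchestration writing CSVs, a JSON report and a text summary, plus
  `autoplot()` / `tidy()` / `glance()` methods.

All functions take data frames first and return tibbles, so stages chain with
the pipe. A thin command-line wrapper ships in `inst/cli/noduletrade.R`.

## Worked example

```r
library(noduletrade)

survey <- simulate_survey(default_survey_config(seed = 1))
report <- run_pipeline(survey$nodules, survey$nests, cv_method = "pooled")
report
```

```
== Nodule trait-matching analysis ==
43 nests, 7 clades

Per-clade summaries:
 clade n_nests mean_diameter_mm cv_diameter_pct mean_density_per_g cv_density_pct normality_p
     I       8           0.4431           16.67            549.079          48.01     0.82034
    II      12           0.7045           17.25            140.472          57.69     0.67341
   III       2           2.4948           15.11              1.802          35.58          NA
    IV       3           1.9219           22.70              8.425          30.60     0.39275
     V       6           0.9443           24.53             67.832          38.59     0.01671
    VI       7           1.3738           24.45             20.949          74.70     0.56368
   VII      5            1.1245           17.81             44.528          27.38     0.89485

Isoquant production limit:
<isoquant_fit>  L = V x D
  L_hat = 24.8521 mm^3/g  (se 1.8292, t = 13.587, p = 5.73e-17, n = 43)
  SSE = 603072.1136, method = nls, response = density

One-way ANOVAs (nest-level):
           response grouping  f_stat df_between df_within   p_value
 mean_head_width_mm    genus  815.43          3        39 3.299e-35
   mean_diameter_mm    clade 2461.46          6        36 1.671e-45
      density_per_g    clade   16.89          6        36 3.678e-09

Head-width correlations:
            trait       r  slope intercept   p_value  n transform
 mean_diameter_mm  0.8736  1.371   -0.3047 2.099e-14 43     log1p
    density_per_g -0.8173 -7.892    9.8064 2.296e-11 43     log1p
```

Reading this: each clade's nodule diameter is a stabilised trait (CV 15–25%
among nodules) while its density is plastic (CV 27–75% among nests); the
fitted production limit L̂ ≈ 24.9 mm³ g⁻¹ recovers the generating constant
25.067 up to lognormal noise bias; and head width correlates positively with
nodule diameter (r = 0.87) and negatively with density (r = −0.82) — the
size-specificity signature. `autoplot(report$isoquant, log_scale = TRUE)`
draws the volume-density scatter with the fitted hyperbola.

The methods vignette (`vignettes/nodule-tradeoff.Rmd`) documents the model,
the generator's assumptions, and the numerical choices.

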