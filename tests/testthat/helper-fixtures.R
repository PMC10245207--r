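# Small two-genus / three-clade design used where the full 43-nest default
# would be overkill.
small_config <- function(seed = 11L, sigma = 0.3, nodules = 20L, ...) {
  survey_config(
    genera = tibble::tribble(
      ~name,    ~head_width_mean, ~head_width_sd, ~n_nests,
      "BigGen",   1.5,              0.07,           4L,
      "SmallGen", 0.7,              0.04,           5L
    ),
    clades = tibble::tribble(
      ~name, ~diameter_mean, ~diameter_cv,
      "A",   0.5,            15,
      "B",   1.0,            20,
      "C",   2.0,            18
    ),
    compatibility = tibble::tribble(
      ~genus,     ~clade, ~weight,
      "BigGen",   "B",    1,
      "BigGen",   "C",    2,
      "SmallGen", "A",    2,
      "SmallGen", "B",    1
    ),
    production_limit_L = 25,
    density_noise_sigma = sigma,
    nodules_per_nest = nodules,
    workers_per_nest = 3L,
    seed = seed,
    ...
  )
}

# default config with uniform compatibility weights across all genus-clade
# pairs: no size matching, so head-width/trait correlations are null
unmatched_config <- function(seed = 1L, ...) {
  cfg <- default_survey_config(seed = seed)
  cfg$compatibility <- tidyr::expand_grid(
    genus = cfg$genera$name, clade = cfg$clades$name
  ) |> dplyr::mutate(weight = 1)
  validate_survey_config(cfg)
  cfg
}
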