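#' Define a synthetic survey configuration
#'
#' A survey configuration fully parameterises the synthetic-survey generator:
#' which termite genera are sampled (and how large their minor workers are),
#' which *Termitomyces* clades exist (and what nodule diameter each one is
#' stabilised at), which clades each genus may cultivate, and the
#' production-limit constant `L` that ties nodule volume `V` (mm^3) and nodule
#' density `D` (count per gram of fungus garden) together through the isoquant
#' `L = V * D`.
#'
#' @param genera A data frame with columns `name`, `head_width_mean` (mm),
#'   `head_width_sd` (mm) and `n_nests` — one row per termite genus.
#' @param clades A data frame with columns `name`, `diameter_mean` (mm) and
#'   `diameter_cv` (percent, in (0, 100)) — one row per fungal clade.
#' @param compatibility A data frame with columns `genus`, `clade` and
#'   `weight` giving the relative probability that a nest of `genus`
#'   cultivates `clade`. Every genus needs at least one positive weight.
#' @param production_limit_L Constant nodule-volume output per gram of fungus
#'   garden, in mm^3 g^-1. Must be positive.
#' @param density_noise_sigma Standard deviation of the multiplicative
#'   log-scale noise applied to nodule density. `0` generates densities lying
#'   exactly on the isoquant.
#' @param nodules_per_nest Number of nodule diameters measured per nest.
#' @param workers_per_nest Number of minor-worker head widths measured per
#'   nest.
#' @param seed Integer seed driving all randomness. Each nest receives its own
#'   random-number stream split off this seed, so appending nests does not
#'   perturb earlier nests' draws.
#' @param diameter_floor_mm Lower truncation bound for nodule diameters, so
#'   volumes stay positive. Configurations whose normal diameter (or head
#'   width) distributions would place more than 1% of mass below the floor are
#'   rejected as degenerate.
#' @param round_density If `TRUE`, densities are rounded to whole counts per
#'   gram for realism. The default keeps them continuous so that noise-free
#'   surveys satisfy the isoquant exactly.
#'
#' @return An object of class `survey_config`.
#' @seealso [default_survey_config()], [simulate_survey()]
#' @export
#' @examples
#' cfg <- survey_config(
#'   genera = data.frame(name = "Odontotermes", head_width_mean = 1.2,
#'                       head_width_sd = 0.06, n_nests = 5),
#'   clades = data.frame(name = "V", diameter_mean = 1, diameter_cv = 20),
#'   compatibility = data.frame(genus = "Odontotermes", clade = "V", weight = 1),
#'   production_limit_L = 25, seed = 42
#' )
#' cfg
survey_config <- function(genera, clades, compatibility,
                          production_limit_L,
                          density_noise_sigma = 0.5,
                          nodules_per_nest = 50,
                          workers_per_nest = 3,
                          seed = 1L,
                          diameter_floor_mm = 0.05,
                          round_density = FALSE) {
  config <- structure(
    list(
      genera = tibble::as_tibble(genera),
      clades = tibble::as_tibble(clades),
      compatibility = tibble::as_tibble(compatibility),
      production_limit_L = production_limit_L,
      density_noise_sigma = density_noise_sigma,
      nodules_per_nest = as.integer(nodules_per_nest),
      workers_per_nest = as.integer(workers_per_nest),
      seed = as.integer(seed),
      diameter_floor_mm = diameter_floor_mm,
      round_density = isTRUE(round_density)
    ),
    class = "survey_config"
  )
  validate_survey_config(config)
  config
}

#' Validate a survey configuration
#'
#' Checks all structural invariants of a [survey_config()]: positive means,
#' CVs in (0, 100), at least one compatible clade with positive weight per
#' genus, and a truncation guard rejecting diameter or head-width
#' distributions that would discard more than 1% of their draws at the
#' truncation floor (a signal of a degenerate mean/sd pair).
#'
#' @param config A `survey_config` object.
#' @return `config`, invisibly, if valid; otherwise an error.
#' @export
validate_survey_config <- function(config) {
  g <- config$genera
  cl <- config$clades
  cp <- config$compatibility

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(sprintf("%s is missing column(s): %s", what,
                    paste(miss, collapse = ", ")))
    }
  }
  need(g, c("name", "head_width_mean", "head_width_sd", "n_nests"), "`genera`")
  need(cl, c("name", "diameter_mean", "diameter_cv"), "`clades`")
  need(cp, c("genus", "clade", "weight"), "`compatibility`")

  if (nrow(g) == 0) abort("`genera` must contain at least one genus.")
  if (nrow(cl) == 0) abort("`clades` must contain at least one clade.")
  if (anyDuplicated(g$name)) abort("genus names must be unique.")
  if (anyDuplicated(cl$name)) abort("clade names must be unique.")
  if (any(g$head_width_mean <= 0)) abort("head_width_mean must be > 0.")
  if (any(g$head_width_sd < 0)) abort("head_width_sd must be >= 0.")
  if (any(g$head_width_sd >= g$head_width_mean)) {
    abort("head_width_sd must be smaller than head_width_mean.")
  }
  if (any(g$n_nests < 1)) abort("every genus needs n_nests >= 1.")
  if (any(cl$diameter_mean <= 0)) abort("diameter_mean must be > 0.")
  if (any(cl$diameter_cv <= 0 | cl$diameter_cv >= 100)) {
    abort("diameter_cv must lie strictly between 0 and 100 percent.")
  }
  if (config$production_limit_L <= 0) abort("production_limit_L must be > 0.")
  if (config$density_noise_sigma < 0) abort("density_noise_sigma must be >= 0.")
  if (config$nodules_per_nest < 1) abort("nodules_per_nest must be >= 1.")
  if (config$workers_per_nest < 1) abort("workers_per_nest must be >= 1.")

  bad_clade <- setdiff(cp$clade, cl$name)
  if (length(bad_clade)) {
    abort(sprintf("compatibility references unknown clade(s): %s",
                  paste(bad_clade, collapse = ", ")))
  }
  bad_genus <- setdiff(cp$genus, g$name)
  if (length(bad_genus)) {
    abort(sprintf("compatibility references unknown genus/genera: %s",
                  paste(bad_genus, collapse = ", ")))
  }
  if (any(cp$weight < 0)) abort("compatibility weights must be nonnegative.")
  for (gn in g$name) {
    w <- cp$weight[cp$genus == gn]
    if (!length(w) || all(w == 0)) {
      abort(sprintf("genus %s has no compatible clade with positive weight.", gn))
    }
  }

  # truncation guard: >1% sub-floor mass signals a degenerate (mean, sd) pair
  d_sd <- cl$diameter_mean * cl$diameter_cv / 100
  p_trunc <- pnorm(config$diameter_floor_mm, cl$diameter_mean, d_sd)
  if (any(p_trunc > 0.01)) {
    abort(sprintf(
      "diameter distribution of clade(s) %s places >1%% of mass below the %.2f mm floor.",
      paste(cl$name[p_trunc > 0.01], collapse = ", "), config$diameter_floor_mm))
  }
  p_hw <- pnorm(0, g$head_width_mean, g$head_width_sd)
  if (any(p_hw > 0.01)) {
    abort(sprintf(
      "head-width distribution of genus/genera %s places >1%% of mass below zero.",
      paste(g$name[p_hw > 0.01], collapse = ", ")))
  }
  invisible(config)
}

#' @export
print.survey_config <- function(x, ...) {
  cat("<survey_config>\n")
  cat(sprintf("  genera: %s (%d nests total)\n",
              paste(x$genera$name, collapse = ", "), sum(x$genera$n_nests)))
  cat(sprintf("  clades: %s\n", paste(x$clades$name, collapse = ", ")))
  cat(sprintf("  production limit L: %.3f mm^3/g, density noise sigma: %.2f\n",
              x$production_limit_L, x$density_noise_sigma))
  cat(sprintf("  %d nodules and %d workers per nest, seed %d\n",
              x$nodules_per_nest, x$workers_per_nest, x$seed))
  invisible(x)
}

#' Default survey configuration
#'
#' Returns the configuration the package treats as its reference study design:
#' 43 nests split across the four termite genera *Macrotermes*,
#' *Odontotermes*, *Ancistrotermes* and *Microtermes* (ordered by decreasing
#' minor-worker head width), seven *Termitomyces* clades I–VII with
#' clade-specific nodule diameters, 50 nodule diameters and 3 head widths per
#' nest, and a shared production limit of 25.067 mm^3 per gram of fungus
#' garden.
#'
#' The per-clade diameter means are plausible placeholders, not published
#' values: they honour the reported clade ordering by diameter
#' (III > IV > VI > VII > V > II > I) and give clade III roughly 170 times the
#' nodule volume of clade I, but the exact numbers are configurable stand-ins.
#' Each genus is compatible only with clades of commensurate nodule size,
#' which induces the positive head-width/diameter association the analysis is
#' designed to detect.
#'
#' @param seed Integer seed, stored in the configuration.
#' @return A [survey_config()] object.
#' @export
#' @examples
#' cfg <- default_survey_config()
#' sum(cfg$genera$n_nests) # 43
default_survey_config <- function(seed = 1L) {
  genera <- tibble::tribble(
    ~name,            ~head_width_mean, ~head_width_sd, ~n_nests,
    "Macrotermes",    1.60,             0.08,           8L,
    "Odontotermes",   1.15,             0.06,           15L,
    "Ancistrotermes", 0.90,             0.05,           8L,
    "Microtermes",    0.70,             0.04,           12L
  )
  clades <- tibble::tribble(
    ~name, ~diameter_mean, ~diameter_cv,
    "I",   0.45,           16,
    "II",  0.70,           18,
    "III", 2.50,           15,
    "IV",  1.90,           26,
    "V",   0.95,           22,
    "VI",  1.40,           24,
    "VII", 1.10,           20
  )
  compatibility <- tibble::tribble(
    ~genus,           ~clade, ~weight,
    "Macrotermes",    "VI",   1,
    "Macrotermes",    "IV",   2,
    "Macrotermes",    "III",  1,
    "Odontotermes",   "II",   0.5,
    "Odontotermes",   "V",    1,
    "Odontotermes",   "VII",  2,
    "Odontotermes",   "VI",   1,
    "Ancistrotermes", "I",    1,
    "Ancistrotermes", "II",   2,
    "Ancistrotermes", "V",    1,
    "Microtermes",    "I",    2,
    "Microtermes",    "II",   1
  )
  survey_config(
    genera = genera,
    clades = clades,
    compatibility = compatibility,
    production_limit_L = 25.067,
    density_noise_sigma = 0.5,
    nodules_per_nest = 50L,
    workers_per_nest = 3L,
    seed = seed
  )
}

# draw n normal variates, resampling any at or below the floor
rnorm_above <- function(n, mean, sd, floor) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= floor)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= floor)
  }
  x
}

#' Simulate a synthetic nodule survey
#'
#' Generates one survey with the statistical structure the downstream analysis
#' assumes. For every nest: a cultivar clade is drawn from the genus's
#' compatibility weights; `nodules_per_nest` nodule diameters are drawn
#' i.i.d. normal with the clade's mean and `sd = mean * cv / 100`, truncated
#' at a small positive floor; `workers_per_nest` minor-worker head widths are
#' drawn i.i.d. normal for the genus, truncated positive; and the nodule
#' density is set on the isoquant, `D = L / V_true * exp(eps)` with
#' `eps ~ Normal(0, density_noise_sigma^2)`, where `V_true` is the sphere
#' volume of the clade's true mean diameter. With `density_noise_sigma = 0`
#' every nest satisfies `V_true * D = L` exactly.
#'
#' Randomness is hierarchical: the global seed initialises a L'Ecuyer-CMRG
#' stream and each nest consumes its own sub-stream, so identical seeds give
#' bit-identical tables and appending nests leaves earlier nests unchanged.
#'
#' @param config A [survey_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return An object of class `synthetic_survey`: a list with `nodules`
#'   (tibble: `nest_id`, `genus`, `clade`, `diameter_mm`), `nests` (tibble:
#'   `nest_id`, `genus`, `clade`, `density_per_g`, `head_width_<k>_mm`), and
#'   `truth` (the configuration used).
#' @export
#' @examples
#' survey <- simulate_survey(default_survey_config(seed = 7))
#' nrow(survey$nodules) # 43 nests x 50 nodules = 2150
simulate_survey <- function(config, seed = NULL) {
  validate_survey_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)

  withr::local_seed(config$seed, .rng_kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", envir = globalenv())

  plan <- config$genera |>
    dplyr::rowwise() |>
    dplyr::reframe(genus = .data$name, idx = seq_len(.data$n_nests)) |>
    dplyr::mutate(nest_id = sprintf("%s_%02d", .data$genus, .data$idx))

  nests <- vector("list", nrow(plan))
  nodules <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    assign(".Random.seed", stream, envir = globalenv())
    g <- config$genera[config$genera$name == plan$genus[i], ]
    compat <- config$compatibility[
      config$compatibility$genus == g$name & config$compatibility$weight > 0, ]
    clade <- if (nrow(compat) == 1) compat$clade else {
      compat$clade[sample.int(nrow(compat), 1, prob = compat$weight)]
    }
    cl <- config$clades[config$clades$name == clade, ]

    d_sd <- cl$diameter_mean * cl$diameter_cv / 100
    diam <- rnorm_above(config$nodules_per_nest, cl$diameter_mean, d_sd,
                        config$diameter_floor_mm)
    hw <- rnorm_above(config$workers_per_nest, g$head_width_mean,
                      g$head_width_sd, 0)
    eps <- rnorm(1, 0, config$density_noise_sigma)

    v_true <- sphere_volume(cl$diameter_mean)
    dens <- config$production_limit_L / v_true * exp(eps)
    if (config$round_density) dens <- round(dens)

    nest_row <- tibble::tibble(
      nest_id = plan$nest_id[i], genus = g$name, clade = clade,
      density_per_g = dens
    )
    hw_cols <- setNames(as.list(hw),
                        sprintf("head_width_%d_mm", seq_along(hw)))
    nests[[i]] <- dplyr::bind_cols(nest_row, tibble::as_tibble(hw_cols))
    nodules[[i]] <- tibble::tibble(
      nest_id = plan$nest_id[i], genus = g$name, clade = clade,
      diameter_mm = diam
    )
    stream <- parallel::nextRNGStream(stream)
  }

  structure(
    list(
      nodules = dplyr::bind_rows(nodules),
      nests = dplyr::bind_rows(nests),
      truth = config
    ),
    class = "synthetic_survey"
  )
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat("<synthetic_survey>\n")
  cat(sprintf("  %d nests, %d nodule measurements, %d genera, %d clades realised\n",
              nrow(x$nests), nrow(x$nodules),
              dplyr::n_distinct(x$nests$genus), dplyr::n_distinct(x$nests$clade)))
  cat(sprintf("  generating production limit L = %.3f mm^3/g (sigma = %.2f, seed %d)\n",
              x$truth$production_limit_L, x$truth$density_noise_sigma,
              x$truth$seed))
  invisible(x)
}

#' Write a synthetic survey to CSV files
#'
#' Writes `nodules.csv` (`nest_id`, `genus`, `clade`, `diameter_mm`) and
#' `nests.csv` (`nest_id`, `genus`, `clade`, `density_per_g`,
#' `head_width_<k>_mm`) into `dir`, UTF-8 with a header row and `.` decimal
#' separator — the schemas the rest of the pipeline reads.
#'
#' @param survey A `synthetic_survey`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector with the two file paths.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "synthetic_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(nodules = file.path(dir, "nodules.csv"),
             nests = file.path(dir, "nests.csv"))
  readr::write_csv(survey$nodules, paths[["nodules"]])
  readr::write_csv(survey$nests, paths[["nests"]])
  invisible(paths)
}

#' Read nodule measurements from CSV
#'
#' @param path Path to a `nodules.csv` file with columns `nest_id`, `genus`,
#'   `clade`, `diameter_mm`.
#' @return A tibble.
#' @export
read_nodules <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    nest_id = readr::col_character(),
    genus = readr::col_character(),
    clade = readr::col_character(),
    diameter_mm = readr::col_double()
  ))
}

#' Read per-nest records from CSV
#'
#' @param path Path to a `nests.csv` file with columns `nest_id`, `genus`,
#'   `clade`, `density_per_g` and one `head_width_<k>_mm` column per measured
#'   minor worker.
#' @return A tibble.
#' @export
read_nests <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    nest_id = readr::col_character(),
    genus = readr::col_character(),
    clade = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Serialise a survey configuration to YAML
#'
#' @param config A [survey_config()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_survey_config <- function(config, path) {
  validate_survey_config(config)
  x <- list(
    genera = purrr::transpose(as.list(config$genera)),
    clades = purrr::transpose(as.list(config$clades)),
    compatibility = purrr::transpose(as.list(config$compatibility)),
    production_limit_L = config$production_limit_L,
    density_noise_sigma = config$density_noise_sigma,
    nodules_per_nest = config$nodules_per_nest,
    workers_per_nest = config$workers_per_nest,
    seed = config$seed,
    diameter_floor_mm = config$diameter_floor_mm,
    round_density = config$round_density
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a survey configuration from YAML
#'
#' @param path File written by [write_survey_config()].
#' @return A [survey_config()].
#' @export
read_survey_config <- function(path) {
  x <- yaml::read_yaml(path)
  survey_config(
    genera = dplyr::bind_rows(lapply(x$genera, tibble::as_tibble)),
    clades = dplyr::bind_rows(lapply(x$clades, tibble::as_tibble)),
    compatibility = dplyr::bind_rows(lapply(x$compatibility, tibble::as_tibble)),
    production_limit_L = x$production_limit_L,
    density_noise_sigma = x$density_noise_sigma,
    nodules_per_nest = x$nodules_per_nest,
    workers_per_nest = x$workers_per_nest,
    seed = x$seed,
    diameter_floor_mm = x$diameter_floor_mm,
    round_density = x$round_density
  )
}
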