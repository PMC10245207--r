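#' Volume of an ideal sphere
#'
#' Converts a diameter to the volume of an ideal sphere,
#' `(4*pi/3) * (d/2)^3` — the geometric model used to turn a nest's average
#' nodule diameter into an average nodule volume.
#'
#' @param diameter Numeric vector of diameters (mm), all nonnegative.
#' @return Volumes in mm^3.
#' @export
#' @examples
#' sphere_volume(1) # pi/6
#' sphere_volume(2) # 4*pi/3
sphere_volume <- function(diameter) {
  if (!is.numeric(diameter)) abort("`diameter` must be numeric.")
  if (any(diameter < 0, na.rm = TRUE)) abort("`diameter` must be nonnegative.")
  (pi / 6) * diameter^3
}

#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)`, using the sample (n - 1) standard deviation. The
#' CV is unitless and invariant to positive rescaling, which makes it the
#' natural yardstick for comparing trait stability across clades measured on
#' different scales: a trait with low CV across nests is stabilised, one with
#' high CV is plastic.
#'
#' @param x Numeric vector with at least two values and nonzero mean.
#' @return The CV as a percentage.
#' @export
#' @examples
#' cv_percent(c(2, 4, 6, 8)) # 51.64
cv_percent <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("CV needs at least two values.")
  m <- mean(x)
  if (m == 0) abort("CV is undefined for zero mean.")
  100 * sd(x) / m
}

#' Per-nest trait summaries
#'
#' Reduces raw measurements to one row per nest: the arithmetic mean nodule
#' diameter, the sphere volume **of that mean diameter** (not the mean of
#' per-nodule volumes — the two differ by Jensen's inequality and the model
#' is defined on the former), the nodule density, and the mean minor-worker
#' head width.
#'
#' @param nodules Data frame of per-nodule measurements (`nest_id`,
#'   `diameter_mm`; `genus`/`clade` are carried through if present on
#'   `nests`).
#' @param nests Data frame of per-nest records (`nest_id`, `genus`, `clade`,
#'   `density_per_g`, `head_width_<k>_mm` columns).
#' @param expected_nodules Expected measurement count per nest (warn when a
#'   nest deviates; `NULL` disables the check).
#' @param strict_nodule_count If `TRUE`, a deviating nodule count is an error
#'   rather than a warning.
#' @return A tibble with columns `nest_id`, `genus`, `clade`, `n_nodules`,
#'   `mean_diameter_mm`, `volume_mm3`, `density_per_g`, `mean_head_width_mm`.
#' @export
#' @examples
#' nodules <- tibble::tibble(nest_id = "a", diameter_mm = c(1, 3))
#' nests <- tibble::tibble(nest_id = "a", genus = "g", clade = "I",
#'                         density_per_g = 10, head_width_1_mm = 1,
#'                         head_width_2_mm = 2, head_width_3_mm = 3)
#' nest_traits(nodules, nests, expected_nodules = NULL)
nest_traits <- function(nodules, nests, expected_nodules = 50,
                        strict_nodule_count = FALSE) {
  nodules <- tibble::as_tibble(nodules)
  nests <- tibble::as_tibble(nests)
  for (col in c("nest_id", "diameter_mm")) {
    if (!col %in% names(nodules)) {
      abort(sprintf("`nodules` is missing column %s.", col))
    }
  }
  for (col in c("nest_id", "density_per_g")) {
    if (!col %in% names(nests)) {
      abort(sprintf("`nests` is missing column %s.", col))
    }
  }
  hw_cols <- grep("^head_width_\\d+_mm$", names(nests), value = TRUE)
  if (!length(hw_cols)) {
    abort("`nests` has no head_width_<k>_mm columns.")
  }
  if (any(nodules$diameter_mm <= 0, na.rm = TRUE)) {
    abort("all nodule diameters must be positive.")
  }
  if (any(nests$density_per_g < 0, na.rm = TRUE)) {
    abort("nodule density must be nonnegative.")
  }

  orphan_nod <- setdiff(nodules$nest_id, nests$nest_id)
  orphan_nest <- setdiff(nests$nest_id, nodules$nest_id)
  if (length(orphan_nod) || length(orphan_nest)) {
    abort(sprintf(
      "nest_id mismatch between tables: %s",
      paste(union(orphan_nod, orphan_nest), collapse = ", ")))
  }

  per_nest <- nodules |>
    dplyr::group_by(.data$nest_id) |>
    dplyr::summarise(
      n_nodules = dplyr::n(),
      mean_diameter_mm = mean(.data$diameter_mm),
      .groups = "drop"
    )

  if (!is.null(expected_nodules)) {
    off <- per_nest$nest_id[per_nest$n_nodules != expected_nodules]
    if (length(off)) {
      msg <- sprintf("%d nest(s) do not have exactly %d nodule measurements: %s",
                     length(off), expected_nodules,
                     paste(head(off, 5), collapse = ", "))
      if (strict_nodule_count) abort(msg) else warn(msg)
    }
  }

  keep <- intersect(c("nest_id", "genus", "clade", "density_per_g"), names(nests))
  nests |>
    dplyr::mutate(
      mean_head_width_mm = rowMeans(dplyr::pick(dplyr::all_of(hw_cols)))
    ) |>
    dplyr::select(dplyr::all_of(keep), "mean_head_width_mm") |>
    dplyr::inner_join(per_nest, by = "nest_id") |>
    dplyr::mutate(volume_mm3 = sphere_volume(.data$mean_diameter_mm)) |>
    dplyr::select(dplyr::any_of(c("nest_id", "genus", "clade", "n_nodules",
                                  "mean_diameter_mm", "volume_mm3",
                                  "density_per_g", "mean_head_width_mm")))
}

#' Per-clade trait summaries
#'
#' Summarises nest-level traits by fungal clade: number of nests, mean nodule
#' diameter, the among-nest CVs of diameter and density, and a Shapiro–Wilk
#' normality p-value for the per-nest mean diameters (reported as evidence,
#' never used as a filter). A low diameter CV paired with a high density CV is
#' the signature of a clade whose nodule size is stabilised while its nodule
#' number is plastic.
#'
#' @param traits Output of [nest_traits()].
#' @param nodules Optional per-nodule table; required when
#'   `cv_method = "pooled"`.
#' @param cv_method `"nest_means"` (default) computes the diameter CV across
#'   per-nest mean diameters — nests are the independent replicates.
#'   `"pooled"` computes it across all individual nodule diameters in the
#'   clade, which estimates the clade's underlying nodule-to-nodule CV
#'   rather than the nest-to-nest CV of means.
#' @return A tibble with one row per clade: `clade`, `n_nests`,
#'   `mean_diameter_mm`, `cv_diameter_pct`, `mean_density_per_g`,
#'   `cv_density_pct`, `normality_p`. CVs are `NA` for singleton clades and
#'   `normality_p` is `NA` below three nests.
#' @export
clade_summary <- function(traits, nodules = NULL,
                          cv_method = c("nest_means", "pooled")) {
  cv_method <- match.arg(cv_method)
  traits <- tibble::as_tibble(traits)
  if (!"clade" %in% names(traits)) abort("`traits` must have a `clade` column.")
  if (cv_method == "pooled" && is.null(nodules)) {
    abort("`cv_method = \"pooled\"` needs the per-nodule table.")
  }

  safe_cv <- function(x) if (length(x) < 2) NA_real_ else cv_percent(x)
  safe_shapiro <- function(x) {
    if (length(x) < 3) return(NA_real_)
    tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
  }

  out <- traits |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(
      n_nests = dplyr::n(),
      # summarise() lets later expressions see earlier results, so the
      # aggregates that consume the full per-nest vectors come first
      cv_diameter_pct = safe_cv(.data$mean_diameter_mm),
      cv_density_pct = safe_cv(.data$density_per_g),
      normality_p = safe_shapiro(.data$mean_diameter_mm),
      mean_diameter_mm = mean(.data$mean_diameter_mm),
      mean_density_per_g = mean(.data$density_per_g),
      .groups = "drop"
    ) |>
    dplyr::select("clade", "n_nests", "mean_diameter_mm", "cv_diameter_pct",
                  "mean_density_per_g", "cv_density_pct", "normality_p")

  if (cv_method == "pooled") {
    pooled <- tibble::as_tibble(nodules) |>
      dplyr::group_by(.data$clade) |>
      dplyr::summarise(cv_diameter_pct = safe_cv(.data$diameter_mm),
                       .groups = "drop")
    out <- out |>
      dplyr::select(-"cv_diameter_pct") |>
      dplyr::left_join(pooled, by = "clade") |>
      dplyr::relocate("cv_diameter_pct", .after = "mean_diameter_mm")
  }
  out
}
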