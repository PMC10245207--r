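#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA computed from its sums of squares:
#' `F = (SSB / (k - 1)) / (SSW / (N - k))` with the between-group sum of
#' squares `SSB = sum_g n_g (m_g - m)^2` and within-group sum of squares
#' `SSW = sum_i (x_i - m_{g(i)})^2`. The p-value comes from the F distribution
#' with `k - 1` and `N - k` degrees of freedom.
#'
#' @param data A data frame.
#' @param value Column of numeric observations.
#' @param group Column of group labels.
#' @return A one-row tibble: `f_stat`, `df_between`, `df_within`, `p_value`,
#'   and `group_means` (a list-column holding the named vector of group
#'   means).
#' @export
#' @examples
#' d <- tibble::tibble(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' anova_oneway(d, y, g) # F = 13.5 on 1 and 4 df
anova_oneway <- function(data, value, group) {
  data <- tibble::as_tibble(data)
  y <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  if (length(y) != length(g)) abort("value and group must have equal length.")
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  k <- length(unique(g))
  n_total <- length(y)
  if (k < 2) abort("one-way ANOVA needs at least two groups.")
  if (n_total - k < 1) {
    abort("no within-group degrees of freedom: every group is a singleton.")
  }

  grand <- mean(y)
  means <- c(tapply(y, g, mean)) # drop the 1-d array shape, keep names
  sizes <- c(tapply(y, g, length))
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  df_b <- k - 1L
  df_w <- n_total - k
  f <- (ssb / df_b) / (ssw / df_w)
  tibble::tibble(
    f_stat = f,
    df_between = df_b,
    df_within = df_w,
    p_value = pf(f, df_b, df_w, lower.tail = FALSE),
    group_means = list(means[sort(names(means))])
  )
}

#' log(n + 1) standardisation
#'
#' Elementwise natural logarithm of `value + 1`, the standardisation applied
#' to both variables before correlation analysis. Strictly monotone, maps 0
#' to 0, and tames the right skew of count-like traits such as nodule density.
#'
#' @param values Numeric vector, all nonnegative.
#' @return The transformed vector.
#' @export
#' @examples
#' log1p_standardize(c(0, exp(1) - 1)) # 0, 1
log1p_standardize <- function(values) {
  if (!is.numeric(values)) abort("`values` must be numeric.")
  if (any(values < 0, na.rm = TRUE)) {
    abort("log(n + 1) standardisation needs nonnegative values.")
  }
  log1p(values)
}

#' Simple linear correlation
#'
#' Pearson correlation with OLS slope and intercept, optionally after
#' log(n + 1)-standardising both variables. The two-sided p-value uses the t
#' distribution with `n - 2` degrees of freedom.
#'
#' @param data A data frame.
#' @param x,y Columns to correlate.
#' @param transform `"log1p"` (default; both variables must be nonnegative)
#'   or `"none"`.
#' @return A one-row tibble: `r`, `slope`, `intercept`, `p_value`, `n`,
#'   `transform`.
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:5, y = c(2, 4, 6, 8, 10))
#' correlate(d, x, y, transform = "none")$r # 1
correlate <- function(data, x, y, transform = c("log1p", "none")) {
  transform <- match.arg(transform)
  data <- tibble::as_tibble(data)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) != length(yv)) abort("x and y must have equal length.")
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("correlation needs at least three complete pairs.")
  if (transform == "log1p") {
    xv <- log1p_standardize(xv)
    yv <- log1p_standardize(yv)
  }
  if (var(xv) == 0 || var(yv) == 0) {
    abort("correlation is undefined for a constant vector.")
  }
  ct <- cor.test(xv, yv, method = "pearson")
  ols <- lm(yv ~ xv)
  tibble::tibble(
    r = unname(ct$estimate),
    slope = unname(coef(ols)[2]),
    intercept = unname(coef(ols)[1]),
    p_value = ct$p.value,
    n = length(xv),
    transform = transform
  )
}

#' The study's three one-way ANOVAs
#'
#' Runs the group-difference tests on nest-level traits: minor-worker head
#' width across termite genera, and mean nodule diameter and nodule density
#' across fungal clades. Nests are the analysis units — each nest contributes
#' one value per trait — since nests, not individual nodules, are the
#' independent replicates. (Pooling all nodules is possible via
#' [anova_oneway()] directly but is pseudoreplicated.) No multiple-testing
#' correction is applied; the three tests are reported separately.
#'
#' @param traits Output of [nest_traits()].
#' @return A tibble with one row per test: `response`, `grouping`, `f_stat`,
#'   `df_between`, `df_within`, `p_value`, `group_means` (list-column).
#' @export
trait_anovas <- function(traits) {
  traits <- tibble::as_tibble(traits)
  specs <- tibble::tribble(
    ~response,            ~grouping,
    "mean_head_width_mm", "genus",
    "mean_diameter_mm",   "clade",
    "density_per_g",      "clade"
  )
  purrr::pmap(specs, function(response, grouping) {
    anova_oneway(traits, !!rlang::sym(response), !!rlang::sym(grouping)) |>
      dplyr::mutate(response = response, grouping = grouping,
                    .before = 1)
  }) |> dplyr::bind_rows()
}

#' Head-width vs cultivar-trait correlations
#'
#' Correlates minor-worker head width with the two cultivar traits — mean
#' nodule diameter and nodule density — across nests, after log(n + 1)
#' standardisation by default. Size matching predicts a positive diameter
#' correlation and a negative density correlation.
#'
#' @param traits Output of [nest_traits()].
#' @param transform Passed to [correlate()].
#' @return A tibble with one row per trait: `trait`, `r`, `slope`,
#'   `intercept`, `p_value`, `n`, `transform`.
#' @export
trait_correlations <- function(traits, transform = "log1p") {
  traits <- tibble::as_tibble(traits)
  purrr::map(c("mean_diameter_mm", "density_per_g"), function(trait) {
    correlate(traits, mean_head_width_mm, !!rlang::sym(trait),
              transform = transform) |>
      dplyr::mutate(trait = trait, .before = 1)
  }) |> dplyr::bind_rows()
}
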