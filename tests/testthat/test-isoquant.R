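iso_data <- function(v, d) tibble::tibble(volume_mm3 = v, density_per_g = d)

test_that("fit_isoquant reproduces hand-worked fixtures", {
  # exact isoquant data: L = 10, zero residual
  f <- fit_isoquant(iso_data(c(1, 2), c(10, 5)))
  expect_equal(f$L_hat, 10)
  expect_equal(f$sse, 0, tolerance = 1e-12)

  # weighted least squares by hand: (12/1 + 5/2) / (1 + 1/4) = 11.6
  f2 <- fit_isoquant(iso_data(c(1, 2), c(12, 5)))
  expect_equal(f2$L_hat, 11.6, tolerance = 1e-9)

  # equal volumes reduce to the sample mean of densities
  f3 <- fit_isoquant(iso_data(c(1, 1), c(8, 12)))
  expect_equal(f3$L_hat, 10)
})

test_that("se, t and p follow the stated formulas", {
  withr::with_seed(8, {
    v <- runif(12, 0.5, 8)
    d <- 25 / v * exp(rnorm(12, 0, 0.3))
  })
  f <- fit_isoquant(iso_data(v, d))
  sse <- sum((d - f$L_hat / v)^2)
  se <- sqrt(sse / (length(v) - 1) / sum(1 / v^2))
  expect_equal(f$sse, sse)
  expect_equal(f$se_L, se)
  expect_equal(f$t_stat, f$L_hat / f$se_L)
  expect_equal(f$p_value, 2 * pt(-abs(f$t_stat), length(v) - 1))

  # and agree with the reference nls summary on the same data
  ref <- summary(nls(d ~ L / v, start = list(L = 20)))
  expect_equal(f$L_hat, unname(coef(ref)[1, "Estimate"]), tolerance = 1e-8)
  expect_equal(f$se_L, unname(coef(ref)[1, "Std. Error"]), tolerance = 1e-8)
})

test_that("oracle triangle: nls, closed form and grid agree on random data", {
  withr::with_seed(314, {
    for (i in 1:100) {
      n <- sample(5:40, 1)
      v <- runif(n, 0.05, 10)
      d <- runif(n, 0, 600)
      nls_fit <- fit_isoquant(iso_data(v, d), method = "nls")
      cf_fit <- fit_isoquant(iso_data(v, d), method = "closed_form")
      grid_fit <- isoquant_grid(v, d)
      expect_equal(nls_fit$L_hat, cf_fit$L_hat, tolerance = 1e-6)
      expect_lte(abs(grid_fit$L_hat - cf_fit$L_hat), grid_fit$step)
      # SSE is convex in L: monotone away from the grid optimum on both sides
      i_min <- which.min(grid_fit$sse_grid)
      expect_true(all(diff(grid_fit$sse_grid[i_min:length(grid_fit$sse_grid)]) >= 0))
      expect_true(all(diff(grid_fit$sse_grid[1:i_min]) <= 0))
    }
  })
})

test_that("L_hat is scale equivariant in densities and in volumes", {
  withr::with_seed(99, {
    v <- runif(15, 0.2, 6)
    d <- runif(15, 1, 300)
  })
  base <- fit_isoquant(iso_data(v, d))$L_hat
  for (k in c(0.25, 3, 17)) {
    expect_equal(fit_isoquant(iso_data(v, k * d))$L_hat, k * base)
    expect_equal(fit_isoquant(iso_data(k * v, d))$L_hat, k * base)
  }
})

test_that("degenerate and invalid inputs are handled", {
  f <- fit_isoquant(iso_data(c(1, 2), c(0, 0)))
  expect_equal(f$L_hat, 0)
  expect_true(f$degenerate)
  expect_true(is.na(f$se_L))

  expect_error(fit_isoquant(iso_data(c(1, -2), c(3, 4))), "positive")
  expect_error(fit_isoquant(iso_data(1, 3)), "at least two")
  expect_error(isoquant_grid(c(1, 2), c(3, 4), grid = numeric()), "empty")
})

test_that("alternative responses give sensible fits", {
  v <- c(1, 2, 4)
  d <- 25 / v
  for (resp in c("density", "volume", "geometric")) {
    f <- fit_isoquant(iso_data(v, d), response = resp)
    expect_equal(f$L_hat, 25, tolerance = 1e-9)
  }
})

test_that("noise-free surveys return the generating L exactly", {
  cfg <- small_config(seed = 12, sigma = 0, nodules = 200L)
  s <- simulate_survey(cfg)
  tr <- nest_traits(s$nodules, s$nests, expected_nodules = 200)
  # fit against the true per-clade volumes: residuals are exactly zero
  v_true <- sphere_volume(
    cfg$clades$diameter_mean[match(tr$clade, cfg$clades$name)]
  )
  f <- fit_isoquant(tibble::tibble(volume_mm3 = v_true,
                                   density_per_g = tr$density_per_g))
  expect_equal(f$L_hat, cfg$production_limit_L, tolerance = 1e-12)
  expect_equal(f$sse, 0, tolerance = 1e-18)
})

test_that("recovery study is exact without noise and calibrated with it", {
  cfg0 <- small_config(seed = 2, sigma = 0, nodules = 500L)
  rec0 <- recover_production_limit(cfg0, n_replicates = 3)
  # only residual source is the finite-sample volume estimate from 500
  # diameters; bias and RMSE are negligible at this n
  expect_lt(abs(rec0$bias_pct), 0.5)
  expect_lt(rec0$rmse / rec0$true_L, 0.02)

  # coverage of the +/- 2 se interval is nominal where the se's error model
  # holds: a common true volume across nests, so density noise is
  # homoscedastic (with volumes spanning orders of magnitude the
  # multiplicative noise makes the classical se undercover; see the vignette)
  cfg1 <- survey_config(
    genera = tibble::tibble(name = "Gen", head_width_mean = 1,
                            head_width_sd = 0.05, n_nests = 10L),
    clades = tibble::tibble(name = "A", diameter_mean = 1, diameter_cv = 15),
    compatibility = tibble::tibble(genus = "Gen", clade = "A", weight = 1),
    production_limit_L = 25, density_noise_sigma = 0.2,
    nodules_per_nest = 50L, seed = 6L
  )
  rec <- recover_production_limit(cfg1, n_replicates = 200)
  expect_gte(rec$coverage_2se, 0.90)
  expect_lte(rec$coverage_2se, 0.99)
  # measured inflation tracks the lognormal factor exp(sigma^2/2)
  expect_lt(abs(rec$bias_corrected_pct), abs(rec$bias_pct) + 2)
  expect_lt(abs(rec$bias_corrected_pct), 5)
})

test_that("tidy and glance expose the fit in broom form", {
  f <- fit_isoquant(iso_data(c(1, 2, 3), c(26, 12, 9)))
  td <- tidy(f)
  expect_equal(names(td),
               c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$estimate, f$L_hat)
  gl <- glance(f)
  expect_equal(gl$n, 3L)
  expect_equal(gl$sse, f$sse)
})
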