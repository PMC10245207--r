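test_that("sphere_volume matches the closed form and its cube-law scaling", {
  expect_equal(sphere_volume(0), 0)
  expect_equal(sphere_volume(1), pi / 6)
  expect_equal(sphere_volume(2), 4 * pi / 3)
  expect_error(sphere_volume(-1), "nonnegative")

  d <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(sphere_volume(d)) > 0))
  r <- 1.7
  expect_equal(sphere_volume(r * d), r^3 * sphere_volume(d))
})

test_that("cv_percent uses the n-1 denominator and is scale invariant", {
  expect_equal(cv_percent(c(5, 5, 5, 5)), 0)
  # sample variance of 2,4,6,8 is 20/3
  expect_equal(cv_percent(c(2, 4, 6, 8)), 100 * sqrt(20 / 3) / 5)
  expect_error(cv_percent(7), "at least two")
  expect_error(cv_percent(c(-1, 1)), "zero mean")

  withr::with_seed(42, {
    for (i in 1:10) {
      x <- rlnorm(20)
      k <- runif(1, 0.1, 50)
      expect_equal(cv_percent(k * x), cv_percent(x))
    }
  })
})

test_that("nest_traits aggregates in the contract's order: volume of the mean diameter", {
  nests <- tibble::tibble(
    nest_id = "a", genus = "g", clade = "I", density_per_g = 10,
    head_width_1_mm = 1, head_width_2_mm = 2, head_width_3_mm = 3
  )
  nodules <- tibble::tibble(nest_id = "a", diameter_mm = c(1, 1, 1))
  tr <- nest_traits(nodules, nests, expected_nodules = NULL)
  expect_equal(tr$mean_diameter_mm, 1)
  expect_equal(tr$volume_mm3, pi / 6)
  expect_equal(tr$mean_head_width_mm, 2)

  # Jensen-gap disambiguation: diameters 1 and 3 give the volume of d = 2,
  # not the mean of the two per-nodule volumes
  nodules2 <- tibble::tibble(nest_id = "a", diameter_mm = c(1, 3))
  tr2 <- nest_traits(nodules2, nests, expected_nodules = NULL)
  expect_equal(tr2$volume_mm3, 4 * pi / 3)
  expect_gt(mean(sphere_volume(c(1, 3))), tr2$volume_mm3)
})

test_that("nest_traits matches an independent recomputation on a seeded survey", {
  s <- simulate_survey(small_config(seed = 9))
  tr <- nest_traits(s$nodules, s$nests,
                    expected_nodules = s$truth$nodules_per_nest)
  # two-line oracle: base-R aggregate of diameters + direct formulas
  by_nest <- tapply(s$nodules$diameter_mm, s$nodules$nest_id, mean)
  expect_equal(tr$mean_diameter_mm, as.numeric(by_nest[tr$nest_id]))
  expect_equal(tr$volume_mm3,
               (4 * pi / 3) * (as.numeric(by_nest[tr$nest_id]) / 2)^3)
  hw <- (s$nests$head_width_1_mm + s$nests$head_width_2_mm +
           s$nests$head_width_3_mm) / 3
  expect_equal(tr$mean_head_width_mm, hw[match(tr$nest_id, s$nests$nest_id)])
})

test_that("nest_traits enforces the schema and nest_id agreement", {
  nests <- tibble::tibble(
    nest_id = "a", genus = "g", clade = "I", density_per_g = 10,
    head_width_1_mm = 1
  )
  expect_error(nest_traits(tibble::tibble(nest_id = "b", diameter_mm = 1),
                           nests, expected_nodules = NULL),
               "mismatch")
  expect_error(nest_traits(tibble::tibble(nest_id = character(),
                                          diameter_mm = numeric()),
                           nests, expected_nodules = NULL),
               "mismatch")
  expect_error(nest_traits(tibble::tibble(nest_id = "a", diameter_mm = -1),
                           nests, expected_nodules = NULL),
               "positive")
})

test_that("nodule-count policy: warn by default, error under strict", {
  nests <- tibble::tibble(
    nest_id = "a", genus = "g", clade = "I", density_per_g = 10,
    head_width_1_mm = 1
  )
  nodules <- tibble::tibble(nest_id = "a", diameter_mm = c(1, 2))
  expect_warning(nest_traits(nodules, nests, expected_nodules = 50),
                 "50 nodule")
  expect_error(nest_traits(nodules, nests, expected_nodules = 50,
                           strict_nodule_count = TRUE),
               "50 nodule")
  expect_silent(nest_traits(nodules, nests, expected_nodules = 2))
})

test_that("clade_summary handles identical traits and small clades", {
  traits <- tibble::tibble(
    nest_id = c("a", "b", "c", "d", "e"),
    clade = c("X", "X", "X", "Y", "Y"),
    mean_diameter_mm = c(1, 1, 1, 2, 2.2),
    density_per_g = c(5, 5, 5, 3, 3.3)
  )
  cs <- clade_summary(traits)
  x <- cs[cs$clade == "X", ]
  expect_equal(x$cv_diameter_pct, 0)
  expect_equal(x$cv_density_pct, 0)
  # Shapiro is undefined on constant samples: flagged NA, CVs still reported
  expect_true(is.na(x$normality_p))
  y <- cs[cs$clade == "Y", ]
  expect_equal(y$n_nests, 2L)
  expect_true(is.na(y$normality_p))
  expect_false(is.na(y$cv_diameter_pct))
  expect_false(is.na(y$cv_density_pct))
})

test_that("pooled clade CVs recover the generating clade CVs at large n", {
  cfg <- small_config(seed = 31, nodules = 5000L)
  s <- simulate_survey(cfg)
  tr <- nest_traits(s$nodules, s$nests, expected_nodules = 5000)
  cs <- clade_summary(tr, nodules = s$nodules, cv_method = "pooled")
  target <- cfg$clades$diameter_cv[match(cs$clade, cfg$clades$name)]
  expect_true(all(abs(cs$cv_diameter_pct - target) / target < 0.02))
  # among-nest CV of nest means is much smaller than the pooled nodule CV
  cs_nest <- clade_summary(tr)
  expect_true(all(cs_nest$cv_diameter_pct < cs$cv_diameter_pct,
                  na.rm = TRUE))
})

test_that("Shapiro-Wilk rejection rate on normal samples is near alpha", {
  withr::with_seed(202, {
    p <- replicate(500, shapiro.test(rnorm(10))$p.value)
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})
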