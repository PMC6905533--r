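test_that("effective diversity matches closed forms and the entropy oracle", {
  expect_equal(shannon_effective_diversity(rep(25, 4)), 4)
  expect_equal(shannon_effective_diversity(100), 1)
  expect_equal(shannon_effective_diversity(c(2, 1, 1)), 2^1.5)
  # zero-area crops contribute nothing
  expect_equal(shannon_effective_diversity(c(2, 1, 1, 0, 0)), 2^1.5)
  expect_error(shannon_effective_diversity(c(0, 0)), "all areas are zero")
  expect_error(shannon_effective_diversity(c(-1, 2)), "non-negative")

  # cross-check against vegan's Shannon index on random mixes
  set.seed(11)
  for (i in 1:10) {
    a <- stats::runif(sample(3:12, 1), 0.1, 100)
    expect_equal(shannon_effective_diversity(a),
                 exp(vegan::diversity(a, index = "shannon")))
  }
})

test_that("diversity is scale invariant and maximal at equal proportions", {
  set.seed(21)
  for (i in 1:20) {
    a <- stats::runif(8, 1, 50)
    expect_equal(shannon_effective_diversity(a * stats::runif(1, 0.01, 100)),
                 shannon_effective_diversity(a))
    # any unequal perturbation of an equal mix lowers D below n
    expect_lt(shannon_effective_diversity(a), 8)
  }
  expect_equal(shannon_effective_diversity(rep(3.7, 8)), 8)
})

test_that("pooled entropy is at least the area-weighted mean of district entropies", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    mixes <- lapply(seq_len(k), function(j) stats::runif(7, 0, 20))
    pooled <- Reduce(`+`, mixes)
    H <- function(a) { p <- a[a > 0] / sum(a); -sum(p * log(p)) }
    w <- vapply(mixes, sum, numeric(1)); w <- w / sum(w)
    expect_gte(H(pooled) + 1e-12, sum(w * vapply(mixes, H, numeric(1))))
  }
})

test_that("subsampled diversity agrees with exhaustive enumeration", {
  areas <- c(10, 10, 10, 70)
  # x = n: only one subset, mean equals raw D exactly
  full <- subsample_diversity_curve(areas, sizes = 4, reps = 50, seed = 1)
  expect_equal(full$mean_D, shannon_effective_diversity(areas))
  expect_equal(full$n_rep, 1L)
  # x = 1: every subset is a monoculture
  one <- subsample_diversity_curve(areas, sizes = 1, reps = 10, seed = 1)
  expect_equal(one$mean_D, 1)

  # Monte Carlo vs enumeration oracle over all 6 pairs (frozen: 1.7287846325)
  expect_equal(oracle_subsample_mean(areas, 2), 1.7287846325, tolerance = 1e-9)
  mc <- subsample_diversity_curve(areas, sizes = 2, reps = 2000, seed = 42)
  se <- mc$sd_D / sqrt(mc$n_rep)
  expect_lt(abs(mc$mean_D - 1.7287846325), 3 * se)
  # and at x = 3 (frozen: 2.2359537670)
  mc3 <- subsample_diversity_curve(areas, sizes = 3, reps = 2000, seed = 43)
  expect_lt(abs(mc3$mean_D - 2.2359537670), 3 * mc3$sd_D / sqrt(mc3$n_rep))

  expect_error(subsample_diversity_curve(areas, sizes = 5), "sizes must lie")
})

test_that("subsampling is reproducible for a fixed seed and mean is non-decreasing in x", {
  set.seed(5)
  areas <- stats::runif(12, 1, 100)
  c1 <- subsample_diversity_curve(areas, reps = 50, seed = 7)
  c2 <- subsample_diversity_curve(areas, reps = 50, seed = 7)
  expect_identical(c1, c2)
  hi <- subsample_diversity_curve(areas, reps = 400, seed = 8)
  # allow tiny Monte Carlo wiggle between adjacent sizes
  expect_true(all(diff(hi$mean_D) > -0.05))
})

test_that("the adjustment curve recovers known parameters on noiseless data", {
  x <- 2:24
  curve <- tibble::tibble(x = x, mean_D = 20 - 18 * exp(-0.1 * x))
  fit <- fit_adjustment_curve(curve)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_equal(fit$a, 20, tolerance = 1e-6)
  expect_equal(fit$b, -18, tolerance = 1e-6)
  expect_equal(fit$c, 0.1, tolerance = 1e-6)

  # constant curve: a ~ k, b ~ 0
  const <- fit_adjustment_curve(tibble::tibble(x = 2:10, mean_D = 7))
  expect_equal(const$a + const$b * exp(-const$c * 6), 7, tolerance = 1e-6)
  expect_equal(const$b, 0, tolerance = 1e-4)

  # exactly linear curve (all-equal mix) has no saturation: flagged
  lin <- fit_adjustment_curve(tibble::tibble(x = 2:24, mean_D = 2:24))
  expect_true(!lin$converged || lin$degenerate)

  expect_error(fit_adjustment_curve(tibble::tibble(x = 1:3, mean_D = 1:3)),
               "at least 4 distinct")
})

test_that("adjusted diversity is consistent with the raw value and saturates", {
  set.seed(61)
  for (i in 1:5) {
    areas <- stats::rlnorm(15, 0, 1)
    rec <- adjusted_diversity(areas, target_n = 83)
    expect_true(rec$fit_ok)
    # fitted curve evaluated at the observed crop count reproduces raw D
    at_n <- rec$fit_a + rec$fit_b * exp(-rec$fit_c * rec$n_crops)
    expect_equal(at_n, rec$D_raw, tolerance = 0.05 * rec$D_raw)
    # the adjustment extrapolates upward but below the asymptote
    expect_gte(rec$D_adjusted, rec$D_raw - 1e-8)
    expect_lte(rec$D_adjusted, rec$fit_a + 1e-8)
  }

  # dominance-heavy mix: the accumulation curve saturates almost
  # immediately, so the adjustment barely exceeds the raw value
  dom <- c(950, stats::runif(9, 1, 10))
  rec <- adjusted_diversity(dom, target_n = 83)
  expect_true(rec$fit_ok)
  expect_lt(rec$D_adjusted - rec$D_raw, 0.5)
})

test_that("beta diversity partitions match hand calculations", {
  # identical proportions in every district: beta exactly 1
  prop <- c(0.4, 0.3, 0.15, 0.1, 0.03, 0.02)
  totals <- c(100, 250, 30, 900, 500)
  D_each <- vapply(totals, function(t) shannon_effective_diversity(t * prop),
                   numeric(1))
  pooled <- Reduce(`+`, lapply(totals, function(t) t * prop))
  b <- beta_diversity(D_each, pooled)
  expect_equal(b$beta, 1)

  # k monoculture districts of distinct crops, equal areas: beta = k
  b2 <- beta_diversity(rep(1, 4), pooled_areas = rep(100, 4))
  expect_equal(b2$beta, 4)
  expect_equal(b2$gamma, 4)
  expect_equal(b2$alpha_mean, 1)

  # two districts, each a different monoculture
  b3 <- beta_diversity(c(1, 1), pooled_areas = c(100, 100))
  expect_equal(b3$beta, 2)

  expect_error(beta_diversity(numeric(0), c(1, 2)), "no district")
})

test_that("diversity trends classify slope direction and significance", {
  years <- 1956:1975
  tr <- diversity_trend(years, 5 + 0.1 * (years - 1956))
  expect_equal(tr$slope, 0.1, tolerance = 1e-10)
  expect_equal(tr$classification, "increase")

  flat <- diversity_trend(years, rep(4.2, 20))
  expect_equal(flat$slope, 0)
  expect_equal(flat$classification, "NS")

  # time reversal negates the slope
  set.seed(71)
  D <- 5 + 0.05 * (years - 1956) + stats::rnorm(20, 0, 0.2)
  fwd <- diversity_trend(years, D)
  rev <- diversity_trend(years, rev(D))
  expect_equal(rev$slope, -fwd$slope, tolerance = 1e-10)

  expect_error(diversity_trend(2000:2001, c(1, 2)), "at least 3 years")
})

test_that("diversity_table and beta_series agree with per-group computation", {
  p <- random_panel(81, n_districts = 4, n_crops = 6, n_years = 3)
  dt <- diversity_table(p)
  one <- p[p$region_id == "D02" & p$year == 2001, ]
  expect_equal(dt$D_raw[dt$region_id == "D02" & dt$year == 2001],
               oracle_D(one$area_ha))
  expect_equal(dt$n_crops[dt$region_id == "D02" & dt$year == 2001],
               sum(one$area_ha > 0))

  bs <- beta_series(p, dt)
  expect_equal(nrow(bs), 3)  # one row per year with district data
  yr <- 2002
  pool <- p[p$year == yr, ] |> dplyr::count(crop, wt = area_ha, name = "area")
  expect_equal(bs$beta[bs$year == yr],
               oracle_D(pool$area) / mean(dt$D[dt$year == yr]))
})
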