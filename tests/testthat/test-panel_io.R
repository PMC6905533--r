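test_that("read_panel round-trips a well-formed CSV and rejects bad rows", {
  p <- make_panel("D01", 2000:2002, c("rice", "wheat", "rice"),
                  c(100, 50, 120), production = c(200, 60, 250))
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  p2 <- read_panel(f)
  expect_equal(as.data.frame(p2), as.data.frame(p))

  bad <- tibble::tibble(region_id = "D01", level = "district", year = 2000L,
                        crop = "rice", area_ha = -5, production_t = NA_real_)
  readr::write_csv(bad, f)
  expect_error(read_panel(f), "negative area.*row.*1")

  dup <- dplyr::bind_rows(bad, bad)
  dup$area_ha <- 5
  readr::write_csv(dup, f)
  expect_error(read_panel(f), "duplicated.*row.*2")

  readr::write_csv(bad[, -5], f)
  expect_error(read_panel(f), "missing required column")
})

test_that("combine_sources averages overlaps and passes through singletons", {
  a <- make_panel("D01", 2000, c("rice", "wheat"), c(100, 40))
  b <- make_panel("D01", 2000, c("rice", "maize"), c(120, 70))
  out <- combine_sources(a, b)
  expect_equal(out$area_ha[out$crop == "rice"], 110)   # mean of 100, 120
  expect_equal(out$area_ha[out$crop == "wheat"], 40)   # a only
  expect_equal(out$area_ha[out$crop == "maize"], 70)   # b only
  expect_setequal(out$source, c("both", "a", "b"))

  # symmetric on overlapping keys, identity when inputs agree
  rev <- combine_sources(b, a)
  expect_equal(rev$area_ha[rev$crop == "rice"], 110)
  same <- combine_sources(a, a)
  expect_equal(same$area_ha, a$area_ha)

  st <- make_panel("S1", 2000, "rice", 10, level = "state")
  expect_error(combine_sources(a, st), "different aggregation levels")
})

test_that("harmonize_regions merges split districts and conserves area", {
  h <- region_hierarchy(
    membership = c(X1 = "S1", X2 = "S1", Y = "S2"),
    merge_map = c(X1 = "X", X2 = "X", Y = "Y")
  )
  p <- make_panel(c("X1", "X2", "Y"), 2000, "rice", c(40, 60, 30))
  out <- harmonize_regions(p, h)
  expect_equal(out$area_ha[out$region_id == "X"], 100)
  expect_equal(sum(out$area_ha), sum(p$area_ha))

  # already on base ids: unchanged
  out2 <- harmonize_regions(out, h)
  expect_equal(as.data.frame(out2), as.data.frame(out))

  p_un <- make_panel("Z9", 2000, "rice", 10)
  expect_error(harmonize_regions(p_un, h), "missing from merge_map.*Z9")
})

test_that("harmonization and aggregation conserve per year-crop totals on random panels", {
  for (seed in 1:5) {
    p <- random_panel(seed, n_districts = 8, n_crops = 4, n_years = 3)
    districts <- unique(p$region_id)
    h <- region_hierarchy(
      membership = c(stats::setNames(rep_len(c("S1", "S2", "S3"),
                                             length(districts)), districts),
                     B1 = "S1"),
      merge_map = stats::setNames(
        c("B1", "B1", districts[-(1:2)]), districts)  # first two merge
    )
    before <- dplyr::count(p, year, crop, wt = area_ha, name = "total")
    hm <- harmonize_regions(p, h)
    after <- dplyr::count(hm, year, crop, wt = area_ha, name = "total")
    expect_equal(after$total, before$total, tolerance = 1e-12)

    st <- aggregate_to_level(hm, h, target = "state")
    expect_equal(sum(st$area_ha), sum(p$area_ha), tolerance = 1e-12)
    co <- aggregate_to_level(hm, h, target = "country")
    expect_equal(sum(co$area_ha), sum(p$area_ha), tolerance = 1e-12)
    # country aggregate equals aggregating the per-state panel member-wise
    expect_equal(sort(co$area_ha),
                 sort(dplyr::count(st, year, crop, wt = area_ha)$n),
                 tolerance = 1e-12)
  }
})

test_that("gap imputation fills interior gaps linearly, only above the threshold", {
  # 12 observed values, one interior gap: 100 (1980), NA (1981), 200 (1982)
  years <- 1975:1987
  area <- c(90, 95, 100, 105, 110, 100, NA, 200, 150, 140, 130, 120, 110)
  p <- make_panel("D01", years, "rice", area)
  out <- impute_gaps(p)
  expect_equal(out$area_ha[out$year == 1981], 150)
  expect_true(out$imputed[out$year == 1981])
  # observed values are never altered
  expect_equal(out$area_ha[out$year != 1981], area[years != 1981])

  # same gap but too few observations: stays missing
  p4 <- make_panel("D01", 1979:1983, "rice", c(90, 100, NA, 200, 210))
  out4 <- impute_gaps(p4)
  expect_true(is.na(out4$area_ha[out4$year == 1981]))

  # two-year gap interpolates both years
  area2 <- c(80, 85, 90, 95, 100, 105, 100, NA, NA, 250, 240, 230, 220)
  p2 <- make_panel("D02", 1975:1987, "wheat", area2)
  out2 <- impute_gaps(p2)
  expect_equal(out2$area_ha[out2$year %in% 1982:1983], c(150, 200))

  # leading/trailing gaps are never extrapolated
  area3 <- c(NA, 85, 90, 95, 100, 105, 100, 110, 120, 250, 240, 230, NA)
  out3 <- impute_gaps(make_panel("D03", 1975:1987, "rice", area3))
  expect_true(is.na(out3$area_ha[out3$year == 1975]))
  expect_true(is.na(out3$area_ha[out3$year == 1987]))
})

test_that("imputed values always lie within their flanking observations", {
  set.seed(99)
  for (i in 1:20) {
    n <- 15
    vals <- stats::runif(n, 0, 500)
    gaps <- sample(2:(n - 1), 3)
    vals[gaps] <- NA
    p <- make_panel("D01", seq(1990, length.out = n), "rice", vals)
    out <- impute_gaps(p, min_values = 10)
    for (g in gaps) {
      yr <- 1990 + g - 1
      v <- out$area_ha[out$year == yr]
      obs_years <- which(!is.na(vals))
      lo <- max(obs_years[obs_years < g]); hi <- min(obs_years[obs_years > g])
      expect_gte(v, min(vals[lo], vals[hi]))
      expect_lte(v, max(vals[lo], vals[hi]))
    }
  }
})

test_that("yields divide aggregate production by aggregate area", {
  p <- make_panel("D01", 2000, "rice", 1000, production = 3600)
  expect_equal(compute_yield(p)$yield_kg_ha, 3600)

  # aggregate first, divide second
  two <- make_panel(c("D01", "D02"), 2000, "rice", c(500, 1500),
                    production = c(1000, 1000))
  h <- toy_hierarchy(c("D01", "D02"), states = "S1")
  agg <- aggregate_to_level(two, h, target = "state")
  expect_equal(compute_yield(agg)$yield_kg_ha, 1000)  # not mean(2000, 666.7)

  zero <- make_panel("D01", 2000, "rice", 100, production = 0)
  expect_equal(compute_yield(zero)$yield_kg_ha, 0)

  undef <- make_panel("D01", 2000, "rice", 0, production = 10)
  expect_warning(y <- compute_yield(undef), "zero area")
  expect_equal(nrow(y), 0)
})

test_that("hierarchy round-trips through CSV and enforces idempotence", {
  h <- region_hierarchy(
    membership = c(X1 = "S1", X2 = "S1", Y = "S2"),
    merge_map = c(X1 = "X", X2 = "X", Y = "Y")
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_hierarchy(h, f)
  h2 <- read_hierarchy(f)
  expect_equal(sort(names(h2$membership)), sort(names(h$membership)))
  expect_equal(h2$merge_map[names(h$merge_map)], h$merge_map)

  expect_error(
    region_hierarchy(c(A = "S1", B = "S1"), merge_map = c(A = "B", B = "C", C = "A")),
    "not idempotent"
  )
})
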