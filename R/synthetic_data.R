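#' Synthetic district panels with intensification and diversification dynamics
#'
#' The generator emulates the statistical structure the analysis assumes:
#' a multi-decade district-by-year-by-crop panel in which one group of
#' districts intensifies and specializes in high-yielding cereals (regime
#' "A", the Green-Revolution signature: diversity falls, cereal yield and
#' area share rise) while another shifts area away from two declining
#' low-yield cereals into many small oilseed and horticultural crops
#' (regime "B": diversity rises). Every quantity is reproducible from the
#' configured seed.
#'
#' @name synthetic_data
NULL

#' Default crop list with role tags
#'
#' 24 crops spanning the five roles the generator distinguishes:
#' intensifying cereals, declining cereals, oilseeds, horticulture, other.
#' @return A tibble with columns `crop` and `role`.
#' @export
default_crop_roles <- function() {
  tibble::tibble(
    crop = c("wheat", "rice",
             "sorghum", "millet",
             "rapeseed", "soybean", "groundnut", "sesame", "linseed", "castor",
             "potato", "onion", "banana", "chillies", "okra", "brinjal",
             "maize", "barley", "chickpea", "pigeonpea", "sugarcane", "cotton",
             "jute", "tobacco"),
    role = c(rep("intensifying_cereal", 2), rep("declining_cereal", 2),
             rep("oilseed", 6), rep("horticulture", 6), rep("other", 8))
  )
}

#' Scenario configuration for the synthetic panel generator
#'
#' Defaults describe a panel structured like the historical Indian district
#' compilations but small enough for minutes-scale runs: 60 base districts
#' in 10 states, 24 crops, years 1956-2008, half the districts in each
#' regime, with 2% of interior cells blanked and one district split event.
#'
#' @param n_districts,n_states Number of base districts and states.
#' @param years Inclusive year range of the panel.
#' @param crops Crop/role table as from [default_crop_roles()].
#' @param frac_scenario_a Fraction of districts in the intensifying regime.
#' @param concentration Dirichlet concentration scaling of the baseline crop
#'   mix: larger values make district compositions closer to the regime's
#'   mean mix.
#' @param specialization_strength Log-share drift (per year, per unit of
#'   district yield-gain multiplier) toward intensifying cereals in regime-A
#'   districts.
#' @param diversification_strength Fraction per year (scaled by the
#'   district's yield-gain multiplier, capped at 1 in total) by which a
#'   regime-B district's log-ratio mix moves from its initial composition
#'   toward its diverse oilseed/horticulture target mix.
#' @param base_yield,yield_trend_a,yield_trend_b Named per-role baseline
#'   yields (t/ha) and yield trends (t/ha/year) in regime A and B districts.
#' @param yield_noise_sd SD of multiplicative lognormal noise on production.
#' @param share_noise_sd SD of yearly Gaussian noise on log crop shares.
#' @param area_growth Relative growth of every district's total crop area
#'   per year (linear path).
#' @param missingness Fraction of interior area cells blanked by
#'   [inject_missing()] when the scenario is realized end to end.
#' @param split_events List of split events, each
#'   `list(district =, year =, shares =)`; children receive the parent's
#'   area in those proportions from the split year on. The default splits
#'   one district in 1980.
#' @param seed Master seed for all randomness.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_districts = 60L, n_states = 10L,
                            years = c(1956L, 2008L),
                            crops = default_crop_roles(),
                            frac_scenario_a = 0.5,
                            concentration = 1,
                            specialization_strength = 0.03,
                            diversification_strength = 0.025,
                            base_yield = c(intensifying_cereal = 0.9,
                                           declining_cereal = 0.5,
                                           oilseed = 0.7, horticulture = 1.2,
                                           other = 0.8),
                            yield_trend_a = c(intensifying_cereal = 0.040,
                                              declining_cereal = 0.004,
                                              oilseed = 0.008,
                                              horticulture = 0.010,
                                              other = 0.008),
                            yield_trend_b = c(intensifying_cereal = 0.008,
                                              declining_cereal = 0.003,
                                              oilseed = 0.010,
                                              horticulture = 0.012,
                                              other = 0.008),
                            yield_noise_sd = 0.05,
                            share_noise_sd = 0.02,
                            area_growth = 0.005,
                            missingness = 0.02,
                            split_events = NULL,
                            seed = 1L) {
  roles <- c("intensifying_cereal", "declining_cereal", "oilseed",
             "horticulture", "other")
  if (!all(crops$role %in% roles)) {
    stop("unknown crop role(s): ",
         paste(setdiff(unique(crops$role), roles), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(crops$crop)) stop("duplicated crop names", call. = FALSE)
  for (nm in c("base_yield", "yield_trend_a", "yield_trend_b")) {
    v <- get(nm)
    if (!all(roles %in% names(v))) {
      stop(nm, " must name every role", call. = FALSE)
    }
  }
  if (is.null(split_events)) {
    split_events <- list(list(district = "D001", year = 1980L,
                              shares = c(0.4, 0.6)))
  }
  structure(list(
    n_districts = as.integer(n_districts), n_states = as.integer(n_states),
    years = as.integer(years), crops = crops,
    frac_scenario_a = frac_scenario_a, concentration = concentration,
    specialization_strength = specialization_strength,
    diversification_strength = diversification_strength,
    base_yield = base_yield, yield_trend_a = yield_trend_a,
    yield_trend_b = yield_trend_b,
    yield_noise_sd = yield_noise_sd, share_noise_sd = share_noise_sd,
    area_growth = area_growth, missingness = missingness,
    split_events = split_events, seed = as.integer(seed)
  ), class = "scenario_config")
}

# Dirichlet weights of the initial mix, per role. Regime A starts with
# sizable high-yield cereal area; regime B is dominated by the two
# declining cereals. Small weights make district mixes sparse and
# idiosyncratic, which is what keeps beta diversity well above 1.
regime_role_weights <- function(regime) {
  if (regime == "A") {
    c(intensifying_cereal = 2.5, declining_cereal = 0.5, oilseed = 0.08,
      horticulture = 0.08, other = 0.25)
  } else {
    c(intensifying_cereal = 0.4, declining_cereal = 3.5, oilseed = 0.12,
      horticulture = 0.12, other = 0.3)
  }
}

# Dirichlet weights of the mix a regime-B district moves toward. Kept
# sparse so each district adopts its own handful of oilseed/horticulture
# crops: the district's own diversity rises only moderately while the
# pooled national mix spreads over many crops, which is what drives beta
# diversity up over time.
diversification_target_weights <- function() {
  c(intensifying_cereal = 0.1, declining_cereal = 0.1, oilseed = 0.45,
    horticulture = 0.45, other = 0.22)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha  # degenerate guard for tiny alpha
  g / sum(g)
}

#' Generate a synthetic district crop panel
#'
#' Each district draws an initial crop mix from a Dirichlet distribution
#' around its regime's mean mix, then drifts in log-share space: regime-A
#' districts shift share toward the intensifying cereals at a rate
#' proportional to their randomly drawn yield-gain multiplier, regime-B
#' districts shift share from the declining cereals to oilseed and
#' horticultural crops. Shares are renormalized yearly, so they always sum
#' to one before scaling by the district's (deterministically growing) total
#' crop area. Production is area times a linearly trending yield with
#' multiplicative lognormal noise. With all response strengths and noise
#' set to zero, shares are constant and yields exactly linear.
#'
#' @param config A [scenario_config()].
#' @return A list: `panel` (a clean district `crop_panel`), `hierarchy`
#'   (district-to-state `region_hierarchy` on base boundaries), `truth`
#'   (per-district tibble of regime, drift rates and yield-gain
#'   multipliers).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n_d <- config$n_districts
  crops <- config$crops$crop
  roles <- config$crops$role
  n_c <- length(crops)
  years <- seq(config$years[1], config$years[2])
  t_rel <- years - years[1]

  districts <- sprintf("D%03d", seq_len(n_d))
  states <- sprintf("S%02d", rep_len(seq_len(config$n_states), n_d))
  n_a <- round(config$frac_scenario_a * n_d)
  regime <- c(rep("A", n_a), rep("B", n_d - n_a))

  gain <- stats::runif(n_d, 0.3, 1.7)        # district yield-gain multiplier
  total0 <- stats::runif(n_d, 2e5, 8e5)      # district total crop area (ha)

  out <- vector("list", n_d)
  truth <- vector("list", n_d)
  for (d in seq_len(n_d)) {
    w <- regime_role_weights(regime[d])[roles]
    p0 <- rdirichlet1(config$concentration * unname(w))

    trend_role <- if (regime[d] == "A") config$yield_trend_a else config$yield_trend_b
    y_trend <- unname(trend_role[roles]) * gain[d]
    y_base <- unname(config$base_yield[roles])

    if (regime[d] == "A") {
      # specialization: multiplicative log-share drift into the
      # intensifying cereals, faster where yields grow faster
      drift <- numeric(n_c)
      drift[roles == "intensifying_cereal"] <-
        config$specialization_strength * gain[d]
      logw <- outer(log(p0), rep(1, length(years))) + outer(drift, t_rel)
    } else {
      # diversification: log-ratio interpolation from the initial mix
      # toward a district-specific diverse target mix, so crops that start
      # from near-zero area can still be adopted
      p1 <- rdirichlet1(config$concentration *
                          unname(diversification_target_weights()[roles]))
      lambda <- pmin(1, config$diversification_strength * gain[d] * t_rel)
      logw <- outer(log(p0), 1 - lambda) + outer(log(p1), lambda)
    }
    if (config$share_noise_sd > 0) {
      logw <- logw + matrix(stats::rnorm(n_c * length(years), 0,
                                         config$share_noise_sd),
                            n_c, length(years))
    }
    shares <- apply(exp(logw), 2, function(v) v / sum(v))
    totals <- total0[d] * (1 + config$area_growth * t_rel)
    area <- sweep(shares, 2, totals, "*")
    yield <- pmax(outer(y_base, rep(1, length(years))) + outer(y_trend, t_rel),
                  0.05)
    prod <- area * yield
    if (config$yield_noise_sd > 0) {
      prod <- prod * exp(matrix(stats::rnorm(n_c * length(years), 0,
                                             config$yield_noise_sd),
                                n_c, length(years)))
    }
    out[[d]] <- tibble::tibble(
      region_id = districts[d], level = "district",
      year = rep(years, each = n_c), crop = rep(crops, length(years)),
      area_ha = as.vector(area), production_t = as.vector(prod)
    )
    reg_d <- regime[d]
    truth[[d]] <- tibble::tibble(
      region_id = districts[d], state_id = states[d], regime = reg_d,
      yield_gain = gain[d], total_area_t0 = total0[d],
      cereal_drift = if (reg_d == "A") config$specialization_strength * gain[d] else 0,
      diversification_drift = if (reg_d == "B") config$diversification_strength * gain[d] else 0
    )
  }
  hierarchy <- region_hierarchy(stats::setNames(states, districts),
                                base_year = 1966L)
  list(panel = crop_panel(dplyr::bind_rows(out), hierarchy = hierarchy),
       hierarchy = hierarchy,
       truth = dplyr::bind_rows(truth))
}

#' Blank interior cells of a panel at random
#'
#' Sets `area_ha` (and `production_t`) to missing for a random fraction of
#' cells, never touching the first or last year of a (region, crop) series
#' so gap imputation remains an interior-interpolation problem. The blanked
#' records are kept in the `truth` attribute for recovery scoring.
#'
#' @param panel A `crop_panel`.
#' @param rate Fraction of eligible (interior) cells to blank, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The panel with blanks; `attr(, "truth")` holds the original
#'   values of the blanked records.
#' @export
inject_missing <- function(panel, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(panel)
  set.seed(seed)
  x <- panel |>
    dplyr::group_by(.data$region_id, .data$crop) |>
    dplyr::mutate(.interior = .data$year > min(.data$year) &
                    .data$year < max(.data$year)) |>
    dplyr::ungroup()
  eligible <- which(x$.interior & !is.na(x$area_ha))
  blank <- eligible[stats::runif(length(eligible)) < rate]
  truth <- x[blank, c("region_id", "year", "crop", "area_ha", "production_t")]
  x$area_ha[blank] <- NA_real_
  x$production_t[blank] <- NA_real_
  x$.interior <- NULL
  x <- panel_restore(x)
  attr(x, "truth") <- truth
  x
}

#' Apply district split events to a panel
#'
#' From each event's split year on, the parent district's records are
#' replaced by child districts (`<parent>a`, `<parent>b`, ...) whose areas
#' and productions partition the parent's in the configured shares. The
#' returned hierarchy maps children back to their parent (the base
#' district) and keeps them in the parent's state, so
#' [harmonize_regions()] reconstructs the unsplit panel.
#'
#' @param panel A district-level `crop_panel`.
#' @param events List of `list(district =, year =, shares =)` events;
#'   shares must sum to 1.
#' @param hierarchy The base `region_hierarchy` for `panel`.
#' @return A list: `panel` (with splits applied), `hierarchy` (covering the
#'   child districts).
#' @export
apply_split_events <- function(panel, events, hierarchy) {
  membership <- hierarchy$membership
  merge_map <- hierarchy$merge_map
  for (ev in events) {
    if (abs(sum(ev$shares) - 1) > 1e-8) {
      stop("split shares for ", ev$district, " do not sum to 1", call. = FALSE)
    }
    span <- range(panel$year)
    if (ev$year < span[1] || ev$year > span[2]) {
      stop("split year ", ev$year, " outside panel span", call. = FALSE)
    }
    idx <- panel$region_id == ev$district & panel$year >= ev$year
    if (!any(idx)) next
    parent_rows <- panel[idx, ]
    kids <- paste0(ev$district, letters[seq_along(ev$shares)])
    child_rows <- purrr::map2_dfr(kids, ev$shares, function(kid, s) {
      r <- parent_rows
      r$region_id <- kid
      r$area_ha <- r$area_ha * s
      r$production_t <- r$production_t * s
      r
    })
    panel <- dplyr::bind_rows(panel[!idx, ], child_rows)
    membership <- c(membership,
                    stats::setNames(rep(membership[[ev$district]],
                                        length(kids)), kids))
    merge_map <- c(merge_map, stats::setNames(rep(ev$district, length(kids)),
                                              kids))
  }
  hierarchy <- region_hierarchy(membership, merge_map,
                                base_year = hierarchy$base_year)
  list(panel = crop_panel(panel), hierarchy = hierarchy)
}

#' Realize a full synthetic scenario
#'
#' Convenience wrapper: [generate_panel()], then [apply_split_events()] and
#' [inject_missing()] per the configuration, producing the "observed" panel
#' an ingest stage would face alongside the clean panel and ground truth.
#'
#' @param config A [scenario_config()].
#' @return A list: `observed` (panel with splits and missingness),
#'   `clean` (the unperturbed panel), `hierarchy`, `truth`.
#' @export
generate_scenario <- function(config) {
  g <- generate_panel(config)
  sp <- apply_split_events(g$panel, config$split_events, g$hierarchy)
  obs <- inject_missing(sp$panel, config$missingness, seed = config$seed + 1L)
  list(observed = obs, clean = g$panel, hierarchy = sp$hierarchy,
       truth = g$truth)
}
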