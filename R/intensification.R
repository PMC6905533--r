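#' Relative intensity and the diversity-change regression ladder
#'
#' Intensification is measured by a district's area-weighted cereal yield
#' relative to the maximum such yield over all districts and analysis
#' periods (RI, in (0, 1]). Change in diversity between the initial and
#' final periods is then modelled as a function of change in RI, the initial
#' area share of the cereal set, and their interaction, with the final model
#' chosen by AIC.
#'
#' @name intensification
NULL

#' Default crop sets used to compute relative intensity
#' @export
RI_CROP_SETS <- list(
  wheat = "wheat",
  cereals = c("rice", "wheat", "sorghum", "millet")
)

#' Relative intensity per district and period
#'
#' For each district and each analysis window, computes the area-weighted
#' mean yield of the crop set from window period means as total production
#' over total area (never a mean of per-crop yields), then divides by
#' `y_max`, the maximum of that quantity over all districts and all supplied
#' windows jointly. The district/period attaining the maximum has RI = 1.
#'
#' @param panel A district-level `crop_panel` with production.
#' @param crop_set Character vector of crops defining the intensification
#'   index (e.g. `RI_CROP_SETS$wheat`).
#' @param windows A list of inclusive year windows, e.g.
#'   `list(t0 = c(1956, 1960), tend = c(2004, 2008))`.
#' @param min_years Minimum contributing years (of area data for the crop
#'   set) a district needs in a window to be retained there.
#' @param per_window_ymax Normalize by each window's own maximum instead of
#'   the joint maximum (off by default).
#' @return A tibble: `region_id`, `window`, `weighted_yield` (t/ha), `RI`.
#'   Districts with zero crop-set area in a window are excluded with a
#'   warning.
#' @export
relative_intensity <- function(panel, crop_set, windows, min_years = 3L,
                               per_window_ymax = FALSE) {
  if (is.null(names(windows)) || any(names(windows) == "")) {
    names(windows) <- paste0("w", seq_along(windows))
  }
  per_window <- purrr::imap_dfr(windows, function(w, nm) {
    x <- panel |>
      dplyr::filter(.data$crop %in% crop_set,
                    .data$year >= w[1], .data$year <= w[2],
                    !is.na(.data$area_ha), !is.na(.data$production_t))
    x |>
      dplyr::group_by(.data$region_id, .data$year) |>
      dplyr::summarise(area = sum(.data$area_ha),
                       production = sum(.data$production_t),
                       .groups = "drop") |>
      dplyr::group_by(.data$region_id) |>
      dplyr::summarise(area = mean(.data$area), production = mean(.data$production),
                       n_years = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(window = nm)
  })
  kept <- per_window |>
    dplyr::filter(.data$n_years >= min_years)
  zero <- kept$area <= 0
  if (any(zero)) {
    warning(sum(zero), " district/window(s) with zero crop-set area ",
            "excluded from RI", call. = FALSE)
    kept <- kept[!zero, ]
  }
  if (nrow(kept) == 0) stop("no district/window has crop-set data", call. = FALSE)
  kept$weighted_yield <- kept$production / kept$area
  if (per_window_ymax) {
    kept <- kept |>
      dplyr::group_by(.data$window) |>
      dplyr::mutate(RI = .data$weighted_yield / max(.data$weighted_yield)) |>
      dplyr::ungroup()
  } else {
    kept$RI <- kept$weighted_yield / max(kept$weighted_yield)
  }
  kept[, c("region_id", "window", "n_years", "weighted_yield", "RI")]
}

#' District-level delta table linking intensification to diversity change
#'
#' One row per retained district with: RI at both periods and its change;
#' the initial share of district crop area in the RI crop set and its
#' change; and mean diversity at both periods and its change. Districts
#' missing either window (for RI or for diversity) are dropped, with the
#' count reported in the `dropped` attribute.
#'
#' @param panel A district-level `crop_panel` with production.
#' @param diversity A [diversity_table()] for the same panel; the `D` column
#'   is averaged over each window.
#' @param crop_set Crops defining the intensity index and the area share.
#' @param t0_window,tend_window Inclusive year windows for the initial and
#'   final periods.
#' @inheritParams relative_intensity
#' @return A tibble: `region_id`, `RI_t0`, `RI_tend`, `delta_RI`,
#'   `area_share_t0`, `area_share_tend`, `delta_area_share`, `D_t0`,
#'   `D_tend`, `delta_D`.
#' @export
build_delta_table <- function(panel, diversity, crop_set,
                              t0_window = c(1956, 1960),
                              tend_window = c(2004, 2008),
                              min_years = 3L, per_window_ymax = FALSE) {
  ri <- relative_intensity(panel, crop_set,
                           windows = list(t0 = t0_window, tend = tend_window),
                           min_years = min_years,
                           per_window_ymax = per_window_ymax)
  ri_wide <- tidyr::pivot_wider(ri[, c("region_id", "window", "RI")],
                                names_from = "window", values_from = "RI",
                                names_prefix = "RI_")

  share_in <- function(w) {
    pm <- period_mean_areas(panel, w)
    pm |>
      dplyr::group_by(.data$region_id) |>
      dplyr::summarise(share = sum(.data$mean_area[.data$crop %in% crop_set]) /
                         sum(.data$mean_area), .groups = "drop")
  }
  s0 <- share_in(t0_window); s1 <- share_in(tend_window)
  d_in <- function(w) {
    diversity |>
      dplyr::filter(.data$year >= w[1], .data$year <= w[2], !is.na(.data$D)) |>
      dplyr::group_by(.data$region_id) |>
      dplyr::summarise(D = mean(.data$D), .groups = "drop")
  }
  d0 <- d_in(t0_window); d1 <- d_in(tend_window)

  out <- ri_wide |>
    dplyr::inner_join(dplyr::rename(s0, area_share_t0 = "share"), by = "region_id") |>
    dplyr::inner_join(dplyr::rename(s1, area_share_tend = "share"), by = "region_id") |>
    dplyr::inner_join(dplyr::rename(d0, D_t0 = "D"), by = "region_id") |>
    dplyr::inner_join(dplyr::rename(d1, D_tend = "D"), by = "region_id") |>
    dplyr::filter(!is.na(.data$RI_t0), !is.na(.data$RI_tend)) |>
    dplyr::mutate(
      delta_RI = .data$RI_tend - .data$RI_t0,
      delta_area_share = .data$area_share_tend - .data$area_share_t0,
      delta_D = .data$D_tend - .data$D_t0
    )
  if (nrow(out) == 0) stop("no district has both windows complete", call. = FALSE)
  all_regions <- unique(panel$region_id)
  attr(out, "dropped") <- setdiff(all_regions, out$region_id)
  out[, c("region_id", "RI_t0", "RI_tend", "delta_RI",
          "area_share_t0", "area_share_tend", "delta_area_share",
          "D_t0", "D_tend", "delta_D")]
}

# one OLS fit summarised into the ModelFit shape
fit_one_model <- function(data, response, terms) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  f <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(f, data = data)
  rank_deficient <- fit$rank < length(stats::coef(fit)) ||
    any(is.na(stats::coef(fit)))
  sm <- summary(fit)
  co <- sm$coefficients
  list(
    formula = paste(response, "~", rhs),
    terms = terms,
    coefficients = tibble::tibble(
      term = rownames(co),
      estimate = co[, "Estimate"],
      std_error = co[, "Std. Error"],
      p_value = co[, "Pr(>|t|)"]
    ),
    r_squared = sm$r.squared,
    aic = stats::AIC(fit),
    df_residual = fit$df.residual,
    n = stats::nobs(fit),
    rank_deficient = rank_deficient,
    lm = fit
  )
}

#' Default term ladders for the diversity-change models
#'
#' Three nested candidate models: the change term alone; plus the initial
#' area share (districts where the crop set is rare cannot respond much);
#' plus their interaction.
#'
#' @param change Name of the change covariate (`"delta_RI"` or
#'   `"delta_area_share"`).
#' @return A list of character vectors of model terms.
#' @export
default_ladder <- function(change = "delta_RI") {
  list(
    change,
    c(change, "area_share_t0"),
    c(change, "area_share_t0", paste0(change, ":area_share_t0"))
  )
}

#' Fit a ladder of nested OLS models and select by AIC
#'
#' Fits each candidate term set by ordinary least squares and selects the
#' model with minimum AIC among the non-rank-deficient fits; the full
#' comparison table is returned alongside.
#'
#' @param table A [build_delta_table()] result (>= 10 rows).
#' @param response `"delta_D"` or `"delta_area_share"`.
#' @param ladder List of character vectors of terms; default
#'   [default_ladder()] on `delta_RI` (or on `delta_area_share` when that is
#'   a covariate of `delta_D`, supply it explicitly).
#' @return A list of class `model_ladder`: `fits` (list of per-model
#'   summaries), `comparison` (tibble of formula, R^2, AIC, df, n),
#'   `selected` (index of the AIC-best model), `best` (its summary).
#' @export
fit_model_ladder <- function(table, response = "delta_D", ladder = NULL) {
  if (nrow(table) < 10) stop("need at least 10 districts to fit", call. = FALSE)
  if (is.null(ladder)) ladder <- default_ladder("delta_RI")
  fits <- lapply(ladder, function(terms) fit_one_model(table, response, terms))
  comparison <- purrr::map_dfr(seq_along(fits), function(i) {
    f <- fits[[i]]
    tibble::tibble(model = i, formula = f$formula, r_squared = f$r_squared,
                   aic = f$aic, df_residual = f$df_residual, n = f$n,
                   rank_deficient = f$rank_deficient)
  })
  eligible <- which(!comparison$rank_deficient)
  if (length(eligible) == 0) stop("all candidate models are rank deficient",
                                  call. = FALSE)
  selected <- eligible[which.min(comparison$aic[eligible])]
  structure(list(fits = fits, comparison = comparison, selected = selected,
                 best = fits[[selected]]),
            class = "model_ladder")
}

#' @export
print.model_ladder <- function(x, ...) {
  cat("<model_ladder>\n")
  print(x$comparison)
  cat("selected:", x$comparison$formula[x$selected], "\n")
  invisible(x)
}

#' Diversity change against the initial sorghum/millet area share
#'
#' In regions that grew mostly sorghum and millet before intensification,
#' diversification rather than cereal intensity drives diversity change, so
#' a single-predictor model of `delta_D` on the initial share of district
#' area planted to those crops is fitted instead.
#'
#' @param table A [build_delta_table()] result whose `area_share_t0` was
#'   computed for the sorghum/millet crop set.
#' @return A single model summary (as one element of
#'   [fit_model_ladder()]'s `fits`), with a `rank_deficient` flag when the
#'   share does not vary across districts.
#' @export
sorghum_millet_baseline <- function(table) {
  if (nrow(table) < 10) stop("need at least 10 districts to fit", call. = FALSE)
  fit <- fit_one_model(table, "delta_D", "area_share_t0")
  if (stats::var(table$area_share_t0) == 0) fit$rank_deficient <- TRUE
  fit
}
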