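#' Crop panels: read, validate, combine, harmonize, impute, aggregate
#'
#' A crop panel is a tidy tibble with one row per (region_id, year, crop)
#' holding crop area in hectares and, optionally, production in tonnes.
#' All pipeline stages consume and produce this shape.
#'
#' @name panel_io
NULL

PANEL_LEVELS <- c("district", "state", "country")

#' Construct and validate a crop panel
#'
#' @param x A data frame with columns `region_id`, `level`, `year`, `crop`,
#'   `area_ha` and optionally `production_t`. Empty/NA `area_ha` means the
#'   value was not reported.
#' @param hierarchy Optional [region_hierarchy()] used to check that every
#'   district resolves to a state.
#' @return A tibble of class `crop_panel`, sorted by region, crop, year.
#' @details Validation enforces the panel contract: unique
#'   (region_id, year, crop) keys, non-negative areas and productions where
#'   present, and a known aggregation level. Offending rows are reported by
#'   their position in `x`.
#' @export
crop_panel <- function(x, hierarchy = NULL) {
  required <- c("region_id", "level", "year", "crop", "area_ha")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!"production_t" %in% names(x)) x$production_t <- NA_real_
  x$region_id <- as.character(x$region_id)
  x$level <- as.character(x$level)
  x$year <- as.integer(x$year)
  x$crop <- as.character(x$crop)
  x$area_ha <- as.numeric(x$area_ha)
  x$production_t <- as.numeric(x$production_t)

  bad_level <- which(!x$level %in% PANEL_LEVELS)
  if (length(bad_level) > 0) {
    stop("unknown level in row(s): ",
         paste(utils::head(bad_level, 5), collapse = ", "), call. = FALSE)
  }
  neg <- which(x$area_ha < 0 | x$production_t < 0)
  if (length(neg) > 0) {
    stop("negative area or production in row(s): ",
         paste(utils::head(neg, 10), collapse = ", "), call. = FALSE)
  }
  key <- paste(x$region_id, x$year, x$crop, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicated (region_id, year, crop) key in row(s): ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }
  if (!is.null(hierarchy)) {
    dist <- unique(x$region_id[x$level == "district"])
    unknown <- setdiff(dist, names(hierarchy$membership))
    if (length(unknown) > 0) {
      stop("district(s) not in hierarchy membership: ",
           paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
    }
  }
  x <- dplyr::arrange(x, .data$region_id, .data$crop, .data$year)
  class(x) <- c("crop_panel", class(x))
  x
}

#' @export
print.crop_panel <- function(x, ...) {
  cat(sprintf("<crop_panel> %d records | %d regions (%s) | years %d-%d | %d crops\n",
              nrow(x), dplyr::n_distinct(x$region_id),
              paste(unique(x$level), collapse = "/"),
              min(x$year), max(x$year), dplyr::n_distinct(x$crop)))
  NextMethod()
}

panel_restore <- function(x) {
  # dplyr verbs strip the subclass; reattach without re-validating
  if (!inherits(x, "crop_panel")) class(x) <- c("crop_panel", class(x))
  x
}

#' Region hierarchy: district-to-state membership and a split/merge map
#'
#' @param membership Named character vector (or 2-column data frame
#'   `district_id`, `state_id`) mapping districts to their state.
#' @param merge_map Named character vector mapping every observed district id
#'   to its base-year district id. Base ids must map to themselves; ids
#'   absent from the map are assumed to already be base ids.
#' @param base_year Calendar year whose boundaries define the base districts.
#' @return An object of class `region_hierarchy`.
#' @export
region_hierarchy <- function(membership, merge_map = NULL, base_year = 1966L) {
  if (is.data.frame(membership)) {
    membership <- stats::setNames(as.character(membership$state_id),
                                  as.character(membership$district_id))
  }
  if (is.null(merge_map)) {
    merge_map <- stats::setNames(names(membership), names(membership))
  }
  # close the map: every target (base) id maps to itself
  bases <- setdiff(unname(merge_map), names(merge_map))
  merge_map <- c(merge_map, stats::setNames(bases, bases))
  not_idem <- names(merge_map)[merge_map[merge_map[names(merge_map)]] !=
                                 merge_map[names(merge_map)]]
  if (length(not_idem) > 0) {
    stop("merge_map is not idempotent for: ",
         paste(utils::head(not_idem, 10), collapse = ", "), call. = FALSE)
  }
  structure(list(membership = membership, merge_map = merge_map,
                 base_year = as.integer(base_year)),
            class = "region_hierarchy")
}

#' @export
print.region_hierarchy <- function(x, ...) {
  cat(sprintf("<region_hierarchy> %d districts, %d states, base year %d\n",
              length(x$membership), length(unique(x$membership)), x$base_year))
  invisible(x)
}

#' Read a crop panel from CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `region_id,level,year,crop,area_ha,production_t`; an empty field means the
#' value was not reported. Rows failing validation abort the read with
#' row-numbered diagnostics.
#'
#' @param path Path to a CSV file.
#' @param level If given, keep only rows at this aggregation level and error
#'   if none remain.
#' @inheritParams crop_panel
#' @return A `crop_panel`.
#' @export
read_panel <- function(path, level = NULL, hierarchy = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  required <- c("region_id", "level", "year", "crop", "area_ha")
  if (!all(required %in% header)) {
    stop("panel is missing required column(s): ",
         paste(setdiff(required, header), collapse = ", "), call. = FALSE)
  }
  x <- readr::read_csv(path, col_types = readr::cols(
    region_id = readr::col_character(),
    level = readr::col_character(),
    year = readr::col_integer(),
    crop = readr::col_character(),
    area_ha = readr::col_double(),
    production_t = readr::col_double()
  ), progress = FALSE)
  if (!is.null(level)) {
    level <- match.arg(level, PANEL_LEVELS)
    x <- x[x$level == level, , drop = FALSE]
    if (nrow(x) == 0) stop("no rows at level '", level, "' in ", path, call. = FALSE)
  }
  crop_panel(x, hierarchy = hierarchy)
}

#' Write a crop panel to CSV
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(p, f))` reproduces `p`
#' record for record.
#'
#' @param panel A `crop_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  cols <- c("region_id", "level", "year", "crop", "area_ha", "production_t")
  readr::write_csv(panel[, cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a region hierarchy from CSV
#'
#' Expects columns `district_id,state_id,base_district_id`; a missing
#' `base_district_id` means the district is its own base unit.
#'
#' @param path Path to a CSV file.
#' @param base_year Base-boundary year recorded on the hierarchy.
#' @return A `region_hierarchy`.
#' @export
read_hierarchy <- function(path, base_year = 1966L) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  need <- c("district_id", "state_id")
  if (!all(need %in% names(x))) {
    stop("hierarchy file must have columns district_id,state_id[,base_district_id]",
         call. = FALSE)
  }
  base <- if ("base_district_id" %in% names(x)) x$base_district_id else x$district_id
  base <- ifelse(is.na(base) | base == "", x$district_id, base)
  region_hierarchy(
    membership = stats::setNames(x$state_id, x$district_id),
    merge_map = stats::setNames(base, x$district_id),
    base_year = base_year
  )
}

#' Write a region hierarchy to CSV
#' @param hierarchy A `region_hierarchy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, path) {
  d <- names(hierarchy$membership)
  readr::write_csv(tibble::tibble(
    district_id = d,
    state_id = unname(hierarchy$membership[d]),
    base_district_id = unname(hierarchy$merge_map[d])
  ), path, progress = FALSE)
  invisible(path)
}

#' Average two panels covering the same level
#'
#' Where both sources report a (region, year, crop) value the result is their
#' arithmetic mean; keys present in exactly one source are carried through
#' unchanged. Area and production are combined independently, so a value
#' reported by only one source is kept even when the other field overlaps.
#'
#' @param a,b Two `crop_panel`s at the same level with harmonized region ids.
#' @return A `crop_panel` with an extra `source` column marking each record
#'   `"a"`, `"b"` or `"both"`.
#' @export
combine_sources <- function(a, b) {
  if (!setequal(unique(a$level), unique(b$level))) {
    stop("panels are at different aggregation levels", call. = FALSE)
  }
  keys <- c("region_id", "level", "year", "crop")
  m <- dplyr::full_join(
    a[, c(keys, "area_ha", "production_t")],
    b[, c(keys, "area_ha", "production_t")],
    by = keys, suffix = c(".a", ".b")
  )
  mean2 <- function(x, y) {
    dplyr::case_when(
      is.na(x) ~ y,
      is.na(y) ~ x,
      TRUE ~ (x + y) / 2
    )
  }
  m$area_ha <- mean2(m$area_ha.a, m$area_ha.b)
  m$production_t <- mean2(m$production_t.a, m$production_t.b)
  in_a <- !is.na(m$area_ha.a) | !is.na(m$production_t.a)
  in_b <- !is.na(m$area_ha.b) | !is.na(m$production_t.b)
  m$source <- dplyr::case_when(in_a & in_b ~ "both", in_a ~ "a", TRUE ~ "b")
  out <- crop_panel(m[, c(keys, "area_ha", "production_t")])
  out$source <- m$source[order(m$region_id, m$crop, m$year)]
  panel_restore(out)
}

#' Merge split districts back to base-year boundaries
#'
#' Maps every district through the hierarchy's split/merge map and sums area
#' and production within (base district, year, crop), so a time series spans
#' boundary changes consistently. Total area per (year, crop) is conserved
#' exactly.
#'
#' @param panel A district-level `crop_panel`.
#' @param hierarchy A `region_hierarchy` whose `merge_map` covers every
#'   district in `panel`.
#' @return A `crop_panel` on base-district ids.
#' @export
harmonize_regions <- function(panel, hierarchy) {
  ids <- unique(panel$region_id[panel$level == "district"])
  unmapped <- setdiff(ids, names(hierarchy$merge_map))
  if (length(unmapped) > 0) {
    stop("district id(s) missing from merge_map: ",
         paste(utils::head(unmapped, 10), collapse = ", "), call. = FALSE)
  }
  panel$region_id <- ifelse(panel$level == "district",
                            unname(hierarchy$merge_map[panel$region_id]),
                            panel$region_id)
  out <- panel |>
    dplyr::group_by(.data$region_id, .data$level, .data$year, .data$crop) |>
    dplyr::summarise(
      area_ha = sum_or_na(.data$area_ha),
      production_t = sum_or_na(.data$production_t),
      .groups = "drop"
    )
  crop_panel(out)
}

# sum treating all-NA as missing, partial NA as absent contributors
sum_or_na <- function(x) {
  if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
}

#' Impute interior gaps by temporal interpolation
#'
#' For each (region, crop) area series with at least `min_values` reported
#' years, interior missing years are filled by linear interpolation between
#' the nearest flanking observations; for instance a crop reported at 100 ha
#' in 1980 and 200 ha in 1982 but not in 1981 is imputed at 150 ha. Years
#' before the first or after the last observation are never extrapolated.
#' Series below the threshold pass through untouched.
#'
#' @param panel A `crop_panel`. Rows for missing years must be present with
#'   `NA` area (use [tidyr::complete()] or the panel as generated).
#' @param min_values Minimum reported observations a series needs before any
#'   of its gaps are filled (default 10).
#' @param impute_production Also interpolate `production_t` by the same rule
#'   (off by default; the rule is defined for area).
#' @return A `crop_panel` with an added logical `imputed` column.
#' @export
impute_gaps <- function(panel, min_values = 10L, impute_production = FALSE) {
  fill_series <- function(year, value) {
    obs <- !is.na(value)
    if (sum(obs) < min_values || all(obs)) return(value)
    interior <- !obs & year > min(year[obs]) & year < max(year[obs])
    if (!any(interior)) return(value)
    value[interior] <- stats::approx(year[obs], value[obs],
                                     xout = year[interior], method = "linear")$y
    value
  }
  out <- panel |>
    dplyr::group_by(.data$region_id, .data$crop) |>
    dplyr::arrange(.data$year, .by_group = TRUE) |>
    dplyr::mutate(
      .area_new = fill_series(.data$year, .data$area_ha),
      imputed = is.na(.data$area_ha) & !is.na(.data$.area_new),
      area_ha = .data$.area_new,
      production_t = if (impute_production) {
        fill_series(.data$year, .data$production_t)
      } else .data$production_t
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".area_new")
  panel_restore(out)
}

#' Aggregate a district panel to state or country level
#'
#' Sums area and production within the target region for each (year, crop).
#' Missing district values are treated as absent from the sum; the number of
#' districts contributing to each aggregate is recorded.
#'
#' @param panel A district-level `crop_panel`.
#' @param hierarchy A `region_hierarchy` providing district-to-state
#'   membership (only needed for `target = "state"`).
#' @param target `"state"` or `"country"`.
#' @param country_id Region id used for the country aggregate.
#' @return A `crop_panel` at the target level with an `n_districts` column.
#' @export
aggregate_to_level <- function(panel, hierarchy = NULL,
                               target = c("state", "country"),
                               country_id = "IND") {
  target <- match.arg(target)
  if (any(panel$level != "district")) {
    stop("aggregate_to_level expects a district-level panel", call. = FALSE)
  }
  if (target == "state") {
    if (is.null(hierarchy)) stop("state aggregation needs a hierarchy", call. = FALSE)
    unknown <- setdiff(unique(panel$region_id), names(hierarchy$membership))
    if (length(unknown) > 0) {
      stop("district(s) without state membership: ",
           paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
    }
    panel$target_region <- unname(hierarchy$membership[panel$region_id])
  } else {
    panel$target_region <- country_id
  }
  out <- panel |>
    dplyr::group_by(region_id = .data$target_region, .data$year, .data$crop) |>
    dplyr::summarise(
      area_ha = sum_or_na(.data$area_ha),
      production_t = sum_or_na(.data$production_t),
      n_districts = sum(!is.na(.data$area_ha)),
      .groups = "drop"
    ) |>
    dplyr::mutate(level = target)
  crop_panel(out)
}

#' Compute yields at the panel's aggregation level
#'
#' Yield is total production divided by total area at the level of the panel
#' (aggregate first, divide second): district yields are never averaged.
#' Records with zero area but positive production are undefined and dropped
#' with a warning.
#'
#' @param panel A `crop_panel` with production.
#' @return A tibble of `region_id`, `level`, `year`, `crop`, `yield_kg_ha`.
#' @export
compute_yield <- function(panel) {
  x <- panel[!is.na(panel$area_ha) & !is.na(panel$production_t), ]
  undef <- x$area_ha == 0 & x$production_t > 0
  if (any(undef)) {
    warning(sum(undef), " record(s) with zero area but positive production ",
            "excluded from yield", call. = FALSE)
    x <- x[!undef, ]
  }
  x <- x[x$area_ha > 0 | x$production_t == 0, ]
  tibble::tibble(
    region_id = x$region_id, level = x$level, year = x$year, crop = x$crop,
    yield_kg_ha = ifelse(x$area_ha == 0, 0, 1000 * x$production_t / x$area_ha)
  )
}
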