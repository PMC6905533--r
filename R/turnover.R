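#' Crop-to-crop area transition matrices between period means
#'
#' Transitions between an initial and a final period are built per district
#' under the conservative assumption that area a crop retained did not move:
#' a crop growing from 800 to 1000 ha keeps 800 ha on the diagonal. Lost
#' area is reallocated to expanding crops, and district matrices are summed
#' to the national matrix.
#'
#' @name turnover
NULL

#' Period-mean crop areas
#'
#' Per (region, crop), the mean area over the non-missing years inside an
#' inclusive year window — the 5-year averages anchoring each end of the
#' analysis. Crops with no data in the window are absent from the output.
#'
#' @param panel A `crop_panel`.
#' @param window Length-2 integer vector `c(start_year, end_year)`.
#' @return A tibble: `region_id`, `crop`, `start_year`, `end_year`,
#'   `mean_area`, `n_years` (contributing years).
#' @export
period_mean_areas <- function(panel, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  x <- panel |>
    dplyr::filter(.data$year >= window[1], .data$year <= window[2],
                  !is.na(.data$area_ha)) |>
    dplyr::group_by(.data$region_id, .data$crop) |>
    dplyr::summarise(mean_area = mean(.data$area_ha), n_years = dplyr::n(),
                     .groups = "drop")
  if (nrow(x) == 0) {
    stop("no area data inside window ", window[1], "-", window[2], call. = FALSE)
  }
  x$start_year <- as.integer(window[1])
  x$end_year <- as.integer(window[2])
  x[, c("region_id", "crop", "start_year", "end_year", "mean_area", "n_years")]
}

#' Period-mean production (same rule as areas)
#' @inheritParams period_mean_areas
#' @return A tibble: `region_id`, `crop`, `start_year`, `end_year`,
#'   `mean_production`, `n_years`.
#' @export
period_mean_production <- function(panel, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  panel |>
    dplyr::filter(.data$year >= window[1], .data$year <= window[2],
                  !is.na(.data$production_t)) |>
    dplyr::group_by(.data$region_id, .data$crop) |>
    dplyr::summarise(mean_production = mean(.data$production_t),
                     n_years = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(start_year = as.integer(window[1]),
                  end_year = as.integer(window[2]))
}

# Allocate one district's transitions. Returns a (k+1) x (k+1) matrix whose
# last row is area sourced from outside cropland ("__new__") and last column
# area leaving cropland ("__exit__").
district_transitions <- function(t0, tend, crops,
                                 allocation = c("proportional", "uniform")) {
  allocation <- match.arg(allocation)
  k <- length(crops)
  m <- matrix(0, k + 1, k + 1,
              dimnames = list(c(crops, "__new__"), c(crops, "__exit__")))
  diag(m)[seq_len(k)] <- pmin(t0, tend)
  loss <- pmax(t0 - tend, 0)
  gain <- pmax(tend - t0, 0)
  L <- sum(loss); G <- sum(gain)
  transfer <- min(L, G)
  if (transfer > 0) {
    w_out <- loss / L
    w_in <- if (allocation == "proportional") gain / G else (gain > 0) / sum(gain > 0)
    m[seq_len(k), seq_len(k)] <- m[seq_len(k), seq_len(k)] +
      transfer * outer(w_out, w_in)
  }
  if (G > L) {
    # net expansion: the unmatched part of each gain comes from new land
    m["__new__", seq_len(k)] <- gain * (1 - transfer / G)
  } else if (L > G) {
    # net contraction: the unmatched part of each loss exits cropland
    m[seq_len(k), "__exit__"] <- loss * (1 - transfer / L)
  }
  m
}

#' Build the national crop transition matrix
#'
#' Per district, the diagonal holds `min(area_t0, area_tend)` for each crop;
#' each declining crop's loss is spread over expanding crops (by default in
#' proportion to their gains), net district expansion is sourced from a
#' `__new__` row and net contraction sinks to an `__exit__` column, so area
#' is conserved exactly. District matrices are summed to the national
#' matrix. The proportional variant divides every entry by the national
#' total initial-period area.
#'
#' @param t0,tend [period_mean_areas()] tables covering the same districts
#'   and crop list.
#' @param mode `"absolute"` (hectares) or `"proportional"` (fraction of the
#'   total initial-period crop area).
#' @param allocation How a declining crop's lost area is split among
#'   expanding crops: `"proportional"` to their gains (maximum-entropy
#'   default) or `"uniform"`.
#' @return A list of class `transition_matrix`: `flows` (matrix with
#'   `__new__` row and `__exit__` column margins), `crops`, `mode`,
#'   `window_t0`, `window_tend`.
#' @export
transition_matrix <- function(t0, tend, mode = c("absolute", "proportional"),
                              allocation = c("proportional", "uniform")) {
  mode <- match.arg(mode)
  allocation <- match.arg(allocation)
  if (!setequal(unique(t0$crop), unique(tend$crop))) {
    stop("t0 and tend cover different crop lists; align them first ",
         "(see align_period_means)", call. = FALSE)
  }
  if (!setequal(unique(t0$region_id), unique(tend$region_id))) {
    stop("t0 and tend cover different districts", call. = FALSE)
  }
  crops <- sort(unique(t0$crop))
  regions <- sort(unique(t0$region_id))
  a0 <- tidyr::pivot_wider(t0[, c("region_id", "crop", "mean_area")],
                           names_from = "crop", values_from = "mean_area",
                           values_fill = 0)
  a1 <- tidyr::pivot_wider(tend[, c("region_id", "crop", "mean_area")],
                           names_from = "crop", values_from = "mean_area",
                           values_fill = 0)
  a0 <- a0[match(regions, a0$region_id), ]
  a1 <- a1[match(regions, a1$region_id), ]
  total <- matrix(0, length(crops) + 1, length(crops) + 1,
                  dimnames = list(c(crops, "__new__"), c(crops, "__exit__")))
  for (i in seq_along(regions)) {
    v0 <- vapply(crops, function(cr) {
      if (cr %in% names(a0)) a0[[cr]][i] else 0
    }, numeric(1))
    v1 <- vapply(crops, function(cr) {
      if (cr %in% names(a1)) a1[[cr]][i] else 0
    }, numeric(1))
    v0[is.na(v0)] <- 0; v1[is.na(v1)] <- 0
    total <- total + district_transitions(v0, v1, crops, allocation)
  }
  if (mode == "proportional") total <- total / sum(t0$mean_area)
  structure(list(
    flows = total, crops = crops, mode = mode, allocation = allocation,
    window_t0 = c(t0$start_year[1], t0$end_year[1]),
    window_tend = c(tend$start_year[1], tend$end_year[1])
  ), class = "transition_matrix")
}

#' Zero-fill two period-mean tables onto their common crop x district grid
#'
#' Crops or districts present in only one period are given mean area 0 in
#' the other, so the two tables satisfy [transition_matrix()]'s contract.
#'
#' @param t0,tend [period_mean_areas()] tables.
#' @return A list with aligned `t0` and `tend`.
#' @export
align_period_means <- function(t0, tend) {
  crops <- union(unique(t0$crop), unique(tend$crop))
  regions <- union(unique(t0$region_id), unique(tend$region_id))
  grid <- tidyr::expand_grid(region_id = regions, crop = crops)
  fill <- function(x) {
    out <- dplyr::left_join(grid, x[, c("region_id", "crop", "mean_area")],
                            by = c("region_id", "crop"))
    out$mean_area[is.na(out$mean_area)] <- 0
    out$start_year <- x$start_year[1]
    out$end_year <- x$end_year[1]
    out$n_years <- NA_integer_
    out
  }
  list(t0 = fill(t0), tend = fill(tend))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d crops, %s mode, %d-%d to %d-%d\n",
              length(x$crops), x$mode, x$window_t0[1], x$window_t0[2],
              x$window_tend[1], x$window_tend[2]))
  invisible(x)
}

#' Write a transition matrix as a labeled square CSV
#' @param tm A `transition_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(tm, path) {
  df <- as.data.frame(tm$flows)
  df <- cbind(from = rownames(tm$flows), df)
  readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}
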