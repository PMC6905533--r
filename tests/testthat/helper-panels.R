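# small in-code fixtures used across test files

# quick panel from vectors recycled to common length
make_panel <- function(region, year, crop, area, production = NA_real_,
                       level = "district") {
  n <- max(length(region), length(year), length(crop), length(area))
  crop_panel(tibble::tibble(
    region_id = rep_len(region, n), level = rep_len(level, n),
    year = rep_len(year, n), crop = rep_len(crop, n),
    area_ha = rep_len(area, n), production_t = rep_len(production, n)
  ))
}

# random district panel with positive areas and production
random_panel <- function(seed, n_districts = 6, n_crops = 5, n_years = 4,
                         start_year = 2000) {
  set.seed(seed)
  grid <- expand.grid(
    region_id = sprintf("D%02d", seq_len(n_districts)),
    year = seq(start_year, length.out = n_years),
    crop = paste0("crop", seq_len(n_crops)),
    stringsAsFactors = FALSE
  )
  grid$level <- "district"
  grid$area_ha <- stats::runif(nrow(grid), 10, 1000)
  grid$production_t <- grid$area_ha * stats::runif(nrow(grid), 0.5, 3)
  crop_panel(grid)
}

# independent entropy-based diversity oracle (kept deliberately naive)
oracle_D <- function(areas) {
  areas <- areas[!is.na(areas) & areas > 0]
  p <- areas / sum(areas)
  exp(-sum(p * log(p)))
}

# exhaustive mean subsampled diversity over all size-x crop subsets
oracle_subsample_mean <- function(areas, x) {
  mean(apply(utils::combn(length(areas), x), 2, function(ix) oracle_D(areas[ix])))
}

# tiny hierarchy: districts split evenly over two states, identity merge map
toy_hierarchy <- function(districts, states = c("S1", "S2")) {
  region_hierarchy(stats::setNames(rep_len(states, length(districts)),
                                   districts))
}
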