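#' Effective number of crop species and alpha/beta/gamma partitioning
#'
#' Diversity is measured as the exponential of Shannon entropy computed on
#' crop-area proportions: the number of equally abundant crops that would
#' give the same entropy as the observed mix. Because reported crop counts
#' differ across datasets and years, sub-national diversity values can be
#' adjusted to a common crop count by fitting a saturating exponential to
#' subsampled diversity values.
#'
#' @name diversity
NULL

#' Effective number of species from crop areas
#'
#' Computes `D = exp(H)` where `H = -sum(p_i * log(p_i))` and `p_i` are the
#' area proportions over crops with strictly positive area. Zero-area crops
#' contribute nothing; `D` ranges from 1 (monoculture) to the number of
#' crops (all areas equal).
#'
#' @param areas Numeric vector of non-negative crop areas (ha). `NA`s are
#'   dropped.
#' @return The effective number of species (dimensionless, >= 1).
#' @examples
#' shannon_effective_diversity(c(25, 25, 25, 25)) # 4 equally abundant crops
#' shannon_effective_diversity(c(2, 1, 1))        # 2^1.5
#' @export
shannon_effective_diversity <- function(areas) {
  areas <- areas[!is.na(areas)]
  if (any(areas < 0)) stop("areas must be non-negative", call. = FALSE)
  areas <- areas[areas > 0]
  if (length(areas) == 0) stop("all areas are zero or missing", call. = FALSE)
  p <- areas / sum(areas)
  exp(-sum(p * log(p)))
}

#' Diversity of crop subsets, by subset size
#'
#' Builds the diversity-versus-crop-count curve that the crop-count
#' adjustment is fitted to. Two subset rules are available:
#'
#' * `method = "random"`: for each size `x`, draws `reps` uniform subsets of
#'   `x` crops without replacement, renormalizes the area proportions within
#'   each subset, computes the effective number of species, and returns the
#'   replicate mean (optionally every replicate). When `x` equals the number
#'   of crops the single exhaustive subset is used, so the mean equals the
#'   raw diversity. Note that this curve is close to proportional in `x`
#'   for almost any composition (a random subset inherits the full mix's
#'   evenness), so it carries little information about saturation.
#' * `method = "rank"`: for each size `x`, takes the `x` crops with the
#'   largest areas (the crops a reporting list of length `x` would contain),
#'   renormalizes, and computes D. This deterministic accumulation curve
#'   saturates at the raw diversity and is what the adjustment fit uses by
#'   default.
#'
#' @param areas Per-crop areas (ha); crops with zero or missing area are
#'   excluded first.
#' @param sizes Integer subset sizes, each in `[1, n_crops]`. Default: every
#'   size from 2 to `n_crops`.
#' @param reps Random subsets per size (default 200; ignored for `"rank"`).
#' @param seed Integer seed making the draws reproducible.
#' @param method Subset rule, `"random"` or `"rank"` (see above).
#' @param keep_replicates Return one row per replicate instead of the mean.
#' @return A tibble with columns `x`, `mean_D`, `sd_D`, `n_rep` (or `x`,
#'   `rep`, `D` when `keep_replicates = TRUE`).
#' @export
subsample_diversity_curve <- function(areas, sizes = NULL, reps = 200L,
                                      seed = NULL,
                                      method = c("random", "rank"),
                                      keep_replicates = FALSE) {
  method <- match.arg(method)
  areas <- areas[!is.na(areas) & areas > 0]
  n <- length(areas)
  if (n == 0) stop("no crops with positive area", call. = FALSE)
  if (is.null(sizes)) sizes <- seq(2L, n)
  sizes <- as.integer(sizes)
  if (any(sizes < 1 | sizes > n)) {
    stop("subset sizes must lie in [1, ", n, "]", call. = FALSE)
  }
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ranked <- sort(areas, decreasing = TRUE)
  one_size <- function(x) {
    if (method == "rank") {
      return(shannon_effective_diversity(ranked[seq_len(x)]))
    }
    if (x == n) {
      # only one subset exists; no sampling needed
      return(shannon_effective_diversity(areas))
    }
    vapply(seq_len(reps), function(i) {
      shannon_effective_diversity(areas[sample.int(n, x)])
    }, numeric(1))
  }
  draws <- lapply(sizes, one_size)
  if (keep_replicates) {
    return(tibble::tibble(
      x = rep(sizes, lengths(draws)),
      rep = unlist(lapply(lengths(draws), seq_len)),
      D = unlist(draws)
    ))
  }
  tibble::tibble(
    x = sizes,
    mean_D = vapply(draws, mean, numeric(1)),
    sd_D = vapply(draws, function(d) if (length(d) > 1) stats::sd(d) else 0,
                  numeric(1)),
    n_rep = lengths(draws)
  )
}

#' Fit the saturating-exponential crop-count adjustment curve
#'
#' Fits `D = a + b * exp(-c * x)` to a table of subset size `x` versus mean
#' diversity by nonlinear least squares, with `c` constrained positive.
#' Initial values follow saturating-curve heuristics (`a0` = largest observed
#' D, `b0` = D at the smallest x minus `a0`, `c0 = 0.1`) with up to
#' `restarts` jittered restarts on failure. A fit is flagged degenerate when
#' `c` collapses to its lower bound, which happens for curves with no
#' saturation (for example the exactly linear curve produced by an all-equal
#' mix).
#'
#' @param curve A data frame with columns `x` and `mean_D` (at least 4
#'   distinct `x` values).
#' @param restarts Maximum jittered restarts after a failed fit.
#' @return A list of class `adjustment_fit` with elements `a`, `b`, `c`,
#'   `converged`, `degenerate`, `rss`, `fitted` (function of x), `n`.
#' @export
fit_adjustment_curve <- function(curve, restarts = 5L) {
  x <- curve$x
  y <- if ("mean_D" %in% names(curve)) curve$mean_D else curve$D
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 4) {
    stop("need at least 4 distinct x values to fit the adjustment curve",
         call. = FALSE)
  }
  c_min <- 1e-6
  a0 <- max(y)
  b0 <- y[which.min(x)] - a0
  if (b0 == 0) b0 <- -1e-3
  starts <- list(c(a = a0, b = b0, c = 0.1))
  for (i in seq_len(restarts)) {
    starts[[i + 1L]] <- c(
      a = a0 * stats::runif(1, 0.8, 1.2),
      b = b0 * stats::runif(1, 0.5, 2),
      c = stats::runif(1, 0.01, 0.5)
    )
  }
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a + b * exp(-c * x),
        start = as.list(st),
        lower = c(a = -Inf, b = -Inf, c = c_min),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          converged = FALSE, degenerate = TRUE,
                          rss = NA_real_, fitted = NULL, n = length(x)),
                     class = "adjustment_fit"))
  }
  cf <- stats::coef(fit)
  # a usable fit must actually saturate within (a few times) the observed
  # range of x and have a plausible asymptote; otherwise evaluating it at a
  # larger crop count is pure extrapolation (the all-equal linear curve is
  # the canonical offender: it is fitted arbitrarily well by c -> 0 with a
  # huge asymptote)
  degenerate <- cf[["c"]] <= c_min * 10 ||
    cf[["c"]] * diff(range(x)) < 0.2 ||
    cf[["a"]] < 0 || cf[["a"]] > 3 * max(y)
  structure(list(
    a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
    converged = TRUE, degenerate = degenerate,
    rss = sum(stats::resid(fit)^2),
    fitted = function(x) cf[["a"]] + cf[["b"]] * exp(-cf[["c"]] * x),
    n = length(x)
  ), class = "adjustment_fit")
}

#' @export
print.adjustment_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<adjustment_fit> failed to converge\n")
  } else {
    cat(sprintf("<adjustment_fit> D = %.4g + %.4g * exp(-%.4g x)%s (RSS %.3g, n %d)\n",
                x$a, x$b, x$c, if (x$degenerate) " [degenerate]" else "",
                x$rss, x$n))
  }
  invisible(x)
}

#' Crop-count-adjusted diversity for one crop-area mix
#'
#' Estimates what the effective number of species would have been had a
#' common, larger number of crops been reported: builds the
#' diversity-versus-crop-count curve for the observed mix, fits the
#' saturating exponential `D = a + b * exp(-c * x)`, and evaluates it at
#' `target_n` crops (default 83, the largest crop count observed in the
#' country-level series). The curve uses rank accumulation by default — a
#' reporting list of `x` crops contains the `x` most widespread ones — since
#' the uniform-random subset curve is nearly linear in `x` and leaves the
#' saturation parameters unidentified (see
#' [subsample_diversity_curve()]). When the fit fails or is degenerate the
#' adjusted value is `NA` and callers fall back to the raw value.
#'
#' @inheritParams subsample_diversity_curve
#' @param target_n Crop count at which the fitted curve is evaluated.
#' @return A one-row tibble: `n_crops`, `D_raw`, `D_adjusted`, `fit_a`,
#'   `fit_b`, `fit_c`, `fit_ok`.
#' @export
adjusted_diversity <- function(areas, target_n = 83L, sizes = NULL,
                               reps = 200L, seed = NULL,
                               method = c("rank", "random")) {
  method <- match.arg(method)
  areas <- areas[!is.na(areas) & areas > 0]
  n <- length(areas)
  d_raw <- shannon_effective_diversity(areas)
  if (n < 5) {
    # too few crops for a 3-parameter curve; report raw only
    return(tibble::tibble(n_crops = n, D_raw = d_raw, D_adjusted = NA_real_,
                          fit_a = NA_real_, fit_b = NA_real_, fit_c = NA_real_,
                          fit_ok = FALSE))
  }
  curve <- subsample_diversity_curve(areas, sizes = sizes, reps = reps,
                                     seed = seed, method = method)
  fit <- fit_adjustment_curve(curve)
  ok <- fit$converged && !fit$degenerate
  tibble::tibble(
    n_crops = n,
    D_raw = d_raw,
    D_adjusted = if (ok) fit$a + fit$b * exp(-fit$c * target_n) else NA_real_,
    fit_a = fit$a, fit_b = fit$b, fit_c = fit$c,
    fit_ok = ok
  )
}

#' Per region-year diversity table for a panel
#'
#' Computes observed crop count and raw diversity for every (region, year),
#' and optionally the crop-count-adjusted value. The adjustment is meant for
#' sub-national series reported on restricted crop lists; country-level
#' series covering the full crop list are conventionally reported raw.
#'
#' @param panel A `crop_panel`.
#' @param adjust Compute the adjusted value as well (slower).
#' @inheritParams adjusted_diversity
#' @return A tibble with one row per (region_id, level, year): `n_crops`,
#'   `D_raw`, and when `adjust = TRUE` the `D_adjusted` and fit columns, plus
#'   `D` (the adjusted value where available, raw otherwise).
#' @export
diversity_table <- function(panel, adjust = FALSE, target_n = 83L,
                            reps = 200L, seed = NULL,
                            method = c("rank", "random")) {
  method <- match.arg(method)
  groups <- panel |>
    dplyr::filter(!is.na(.data$area_ha), .data$area_ha > 0) |>
    dplyr::group_by(.data$region_id, .data$level, .data$year)
  if (!adjust) {
    out <- groups |>
      dplyr::summarise(
        n_crops = dplyr::n(),
        D_raw = shannon_effective_diversity(.data$area_ha),
        .groups = "drop"
      )
    out$D <- out$D_raw
    return(out)
  }
  keys <- dplyr::group_keys(groups)
  # one deterministic stream per group, derived from the master seed
  recs <- purrr::map2(dplyr::group_split(groups), seq_len(nrow(keys)),
    function(g, i) {
      adjusted_diversity(g$area_ha, target_n = target_n, reps = reps,
                         seed = if (is.null(seed)) NULL else seed + i,
                         method = method)
    })
  out <- dplyr::bind_cols(keys, dplyr::bind_rows(recs))
  out$D <- ifelse(is.na(out$D_adjusted), out$D_raw, out$D_adjusted)
  out
}

#' Multiplicative beta diversity for one year
#'
#' Gamma is the effective number of species of the pooled (country-level)
#' areas, alpha the unweighted mean of the district diversity values, and
#' beta their ratio `gamma / alpha`: 1 when every district has identical
#' crop proportions, and up to the number of districts when each grows a
#' different crop.
#'
#' @param district_D Numeric vector of per-district diversity values for one
#'   year (raw or adjusted — use one consistently).
#' @param pooled_areas Per-crop areas summed over the same districts.
#' @param weights Optional positive district weights for a weighted alpha
#'   mean (default unweighted).
#' @return A one-row tibble: `gamma`, `alpha_mean`, `beta`.
#' @export
beta_diversity <- function(district_D, pooled_areas, weights = NULL) {
  district_D <- district_D[!is.na(district_D)]
  if (length(district_D) == 0) stop("no district diversity values", call. = FALSE)
  alpha <- if (is.null(weights)) {
    mean(district_D)
  } else {
    stats::weighted.mean(district_D, weights)
  }
  gamma <- shannon_effective_diversity(pooled_areas)
  tibble::tibble(gamma = gamma, alpha_mean = alpha, beta = gamma / alpha)
}

#' Yearly beta-diversity series for a district panel
#'
#' @param panel A district-level `crop_panel`.
#' @param diversity Optional precomputed [diversity_table()] for `panel`
#'   (raw is used unless it carries adjusted values in `D`).
#' @return A tibble with one row per year: `year`, `gamma`, `alpha_mean`,
#'   `beta`, `n_districts`.
#' @export
beta_series <- function(panel, diversity = NULL) {
  if (is.null(diversity)) diversity <- diversity_table(panel)
  pooled <- panel |>
    dplyr::filter(!is.na(.data$area_ha)) |>
    dplyr::group_by(.data$year, .data$crop) |>
    dplyr::summarise(area_ha = sum(.data$area_ha), .groups = "drop")
  years <- sort(intersect(unique(diversity$year), unique(pooled$year)))
  purrr::map_dfr(years, function(yr) {
    b <- beta_diversity(diversity$D[diversity$year == yr],
                        pooled$area_ha[pooled$year == yr])
    b$year <- yr
    b$n_districts <- sum(diversity$year == yr)
    b[, c("year", "gamma", "alpha_mean", "beta", "n_districts")]
  })
}

#' Temporal trend in diversity for one region
#'
#' Ordinary least-squares regression of diversity on calendar year. The
#' slope measures change in effective species per year; regions whose slope
#' is not distinguishable from zero at `alpha_level` are classified `"NS"`.
#'
#' @param years,D Paired numeric vectors (at least 3 years).
#' @param alpha_level Two-sided significance threshold (default 0.05).
#' @return A one-row tibble: `slope`, `se`, `p_value`, `classification`.
#' @export
diversity_trend <- function(years, D, alpha_level = 0.05) {
  ok <- !is.na(years) & !is.na(D)
  years <- years[ok]; D <- D[ok]
  if (length(years) < 3) stop("need at least 3 years for a trend", call. = FALSE)
  fit <- stats::lm(D ~ years)
  # summary() warns on exact linear series; the NaN p-value is handled below
  sm <- suppressWarnings(summary(fit))$coefficients
  if (nrow(sm) < 2 || is.na(sm["years", "Std. Error"])) {
    # constant or degenerate series
    slope <- unname(stats::coef(fit)["years"])
    if (is.na(slope)) slope <- 0
    return(tibble::tibble(slope = slope, se = NA_real_, p_value = 1,
                          classification = "NS"))
  }
  slope <- sm["years", "Estimate"]
  p <- sm["years", "Pr(>|t|)"]
  if (is.nan(p)) p <- 1  # zero residual variance on a flat line
  cls <- if (p >= alpha_level) "NS" else if (slope > 0) "increase" else "decrease"
  tibble::tibble(slope = slope, se = sm["years", "Std. Error"],
                 p_value = p, classification = cls)
}
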