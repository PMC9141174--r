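#' Season of a calendar month
#'
#' Fixed month-to-season table of the study design: spring = March-May,
#' summer = June-August, autumn = September and November, winter = February
#' and December. January and October fall outside the analysed periods and
#' map to `NA`.
#'
#' @param month Integer month 1-12, or a `Date` (vectorised).
#' @return Character vector of season labels (`"spring"`, `"summer"`,
#'   `"autumn"`, `"winter"`) or `NA`.
#' @export
season_of <- function(month) {
  if (inherits(month, "Date")) month <- as.integer(format(month, "%m"))
  tab <- c(NA, "winter", "spring", "spring", "spring", "summer", "summer",
           "summer", "autumn", NA, "autumn", "winter")
  if (any(!month %in% 1:12, na.rm = TRUE)) stop("months must be in 1..12")
  tab[month]
}

# Separable Gaussian smoothing with edge renormalisation (kernel rows are
# rescaled so the smoother preserves a constant field exactly).
gaussian_smooth <- function(m, sd_cells) {
  smooth_1d <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / sd_cells)^2)
    k / rowSums(k)
  }
  kr <- smooth_1d(nrow(m))
  kc <- smooth_1d(ncol(m))
  kr %*% m %*% t(kc)
}

#' Generate a spatially autocorrelated AOD field
#'
#' Gaussian-kernel smoothing of white noise plus a deterministic planar
#' gradient, rescaled and clamped into `value_range`. The gradient emulates
#' the coastal-high / inland-low structure of real aerosol fields; the
#' smoothing length controls the spatial autocorrelation (global Moran's I).
#'
#' @param spec A [grid_spec()].
#' @param smoothness Gaussian kernel standard deviation in cells (> 0).
#' @param gradient Peak-to-trough amplitude of a planar ramp (AOD units).
#' @param gradient_direction Direction of increase, degrees clockwise from
#'   "east along columns" (0 = increases left to right).
#' @param noise_sd Standard deviation of the smoothed noise component
#'   (AOD units, after smoothing).
#' @param base Field mean level (default: midpoint of `value_range`).
#' @param value_range Admissible AOD interval, must lie within `[0, 1.95]`.
#' @param seed Integer seed; identical seeds give identical fields.
#' @return Numeric matrix of AOD at 550 nm.
#' @export
generate_aod_field <- function(spec, smoothness = 8, gradient = 0.4,
                               gradient_direction = 0, noise_sd = 0.15,
                               base = mean(value_range),
                               value_range = c(0.02, 1.5), seed = 1L) {
  if (value_range[1] < 0 || value_range[2] > 1.95 ||
      value_range[1] >= value_range[2])
    stop("`value_range` must be an interval within [0, 1.95]")
  if (smoothness <= 0) stop("`smoothness` must be > 0")
  nr <- spec$n_rows; nc <- spec$n_cols
  noise <- 0
  if (noise_sd > 0) {
    z <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
    sm <- gaussian_smooth(z, smoothness)
    sm <- (sm - mean(sm)) / max(stats::sd(sm), .Machine$double.eps)
    noise <- noise_sd * sm
  }
  theta <- gradient_direction * pi / 180
  cc <- (col(matrix(0, nr, nc)) - (nc + 1) / 2) / max(nc - 1, 1)
  rr <- ((nr + 1) / 2 - row(matrix(0, nr, nc))) / max(nr - 1, 1)
  ramp <- gradient * (cos(theta) * cc + sin(theta) * rr)
  field <- base + noise + ramp
  pmin(pmax(field, value_range[1]), value_range[2])
}

# Evaluate one of the six regression families at x.
family_eval <- function(family, x, a0, a1, a2 = 0, a3 = 0) {
  switch(family,
    linear = a0 + a1 * x,
    logarithmic = a0 + a1 * log(x),
    exponential = a0 * exp(a1 * x),
    power = a0 * x^a1,
    quadratic = a0 + a1 * x + a2 * x^2,
    cubic = a0 + a1 * x + a2 * x^2 + a3 * x^3,
    stop(sprintf("unknown model family '%s'", family))
  )
}

MODEL_FAMILIES <- c("linear", "logarithmic", "exponential", "power",
                    "quadratic", "cubic")

#' Generate a ground-truth PM2.5 grid from an AOD field
#'
#' Applies one of the six AOD-PM2.5 regression families as the generating
#' law, with multiplicative lognormal noise of a given coefficient of
#' variation (mean-one multiplier, so the noise is unbiased on the original
#' scale). Concentrations are floored at zero.
#'
#' @param aod Numeric AOD matrix.
#' @param family One of `"linear"`, `"logarithmic"`, `"exponential"`,
#'   `"power"`, `"quadratic"`, `"cubic"`.
#' @param a0,a1,a2,a3 Generating coefficients.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = deterministic).
#' @param seed Integer seed.
#' @return Numeric PM2.5 matrix (ug/m3), `NA` where `aod` is `NA`.
#' @export
generate_pm25_truth <- function(aod, family, a0, a1, a2 = 0, a3 = 0,
                                noise_cv = 0.1, seed = 1L) {
  if (!family %in% MODEL_FAMILIES)
    stop("`family` must be one of: ", paste(MODEL_FAMILIES, collapse = ", "))
  if (noise_cv < 0) stop("`noise_cv` must be >= 0")
  y <- family_eval(family, aod, a0, a1, a2, a3)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    mult <- with_seed(seed, matrix(
      stats::rlnorm(length(aod), meanlog = -sdlog^2 / 2, sdlog = sdlog),
      nrow(aod), ncol(aod)))
    y <- y * mult
  }
  pmax(y, 0)
}

#' Generate a clustered monitoring-station network
#'
#' Places AOD (sun-photometer) and PM2.5 stations on unique grid cells. With
#' `clustering > 0` and a population surface, placement probability tilts
#' toward dense cells (population smoothed over a 3x3 neighbourhood so
#' point-mass populations still admit several nearby stations), emulating the
#' real-world concentration of stations in developed areas.
#'
#' @param spec A [grid_spec()].
#' @param n_aod,n_pm25 Station counts (>= 0).
#' @param clustering Fraction in `[0, 1]`: 0 = uniform placement, 1 = purely
#'   population-proportional.
#' @param population Optional population matrix for clustered placement.
#' @param seed Integer seed.
#' @return A data.frame with columns `station_id`, `row`, `col`, `kind`.
#' @export
generate_station_network <- function(spec, n_aod = 2, n_pm25 = 41,
                                     clustering = 0.7, population = NULL,
                                     seed = 1L) {
  n <- n_aod + n_pm25
  ncell <- spec$n_rows * spec$n_cols
  if (n_aod < 0 || n_pm25 < 0) stop("station counts must be >= 0")
  if (n > ncell) stop(sprintf("%d stations requested but the grid has only %d cells",
                              n, ncell))
  if (n == 0)
    return(data.frame(station_id = character(), row = integer(),
                      col = integer(), kind = character()))
  w <- rep(1, ncell)
  if (clustering > 0 && !is.null(population)) {
    psm <- gaussian_smooth(population, 1)
    pw <- as.numeric(psm) / sum(psm)
    w <- (1 - clustering) / ncell + clustering * pw
  }
  cells <- with_seed(seed, sample.int(ncell, n, prob = w))
  kind <- c(rep("AOD", n_aod), rep("PM25", n_pm25))
  data.frame(
    station_id = sprintf("%s_%02d", tolower(kind),
                         c(seq_len(n_aod), seq_len(n_pm25))),
    row = ((cells - 1L) %% spec$n_rows) + 1L,
    col = ((cells - 1L) %/% spec$n_rows) + 1L,
    kind = kind,
    stringsAsFactors = FALSE
  )
}

#' Generate a multi-centre population density surface
#'
#' Sum of exponentially decaying kernels around randomly placed urban
#' centres: `density(cell) = sum_k peak * exp(-dist_k / decay)` with
#' distances in cells (= km on the working grid).
#'
#' @param spec A [grid_spec()].
#' @param n_centers Number of urban centres (>= 1).
#' @param peak_density Kernel peak (persons/km2, > 0).
#' @param decay Kernel e-folding length in cells (> 0).
#' @param seed Integer seed.
#' @return Numeric matrix of persons/km2.
#' @export
generate_population <- function(spec, n_centers = 3, peak_density = 5000,
                                decay = 6, seed = 1L) {
  if (n_centers < 1) stop("`n_centers` must be >= 1")
  if (peak_density <= 0) stop("`peak_density` must be > 0")
  if (decay <= 0) stop("`decay` must be > 0")
  nr <- spec$n_rows; nc <- spec$n_cols
  centers <- with_seed(seed, cbind(sample.int(nr, n_centers, replace = TRUE),
                                   sample.int(nc, n_centers, replace = TRUE)))
  rw <- row(matrix(0, nr, nc)); cl <- col(matrix(0, nr, nc))
  dens <- matrix(0, nr, nc)
  for (k in seq_len(n_centers)) {
    d <- sqrt((rw - centers[k, 1])^2 + (cl - centers[k, 2])^2)
    dens <- dens + peak_density * exp(-d / decay)
  }
  dens
}

#' Sample station observations from a field
#'
#' Extracts the field value at each station cell for each date, applies
#' multiplicative lognormal observation noise, and drops records by Bernoulli
#' dropout (mimicking cloud-blocked days). `NA` field cells yield no record.
#'
#' @param field A numeric matrix (one static field) or a list of matrices,
#'   one per date.
#' @param network Station data.frame from [generate_station_network()].
#' @param dates Vector of `Date`s (or coercible).
#' @param obs_noise_cv Observation noise coefficient of variation.
#' @param missing_rate Per-record dropout probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A data.frame `station_id`, `date`, `value`.
#' @export
sample_observations <- function(field, network, dates, obs_noise_cv = 0.05,
                                missing_rate = 0.1, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must lie in [0, 1)")
  dates <- as.Date(dates)
  empty <- data.frame(station_id = character(), date = as.Date(character()),
                      value = numeric())
  if (length(dates) == 0 || nrow(network) == 0) return(empty)
  fields <- if (is.list(field)) field else rep(list(field), length(dates))
  if (length(fields) != length(dates))
    stop("`field` list length must match `dates`")
  dims <- dim(fields[[1]])
  if (any(network$row < 1 | network$row > dims[1] |
          network$col < 1 | network$col > dims[2]))
    stop("station outside the grid")
  recs <- do.call(rbind, lapply(seq_along(dates), function(i) {
    v <- fields[[i]][cbind(network$row, network$col)]
    data.frame(station_id = network$station_id, date = dates[i], value = v,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  recs <- recs[!is.na(recs$value), , drop = FALSE]
  with_seed(seed, {
    if (obs_noise_cv > 0) {
      sdlog <- sqrt(log(1 + obs_noise_cv^2))
      recs$value <- recs$value *
        stats::rlnorm(nrow(recs), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    if (missing_rate > 0)
      recs <- recs[stats::runif(nrow(recs)) >= missing_rate, , drop = FALSE]
  })
  rownames(recs) <- NULL
  recs
}

#' Synthesize a satellite reflectance scene from a true AOD field
#'
#' Builds the apparent-reflectance band triplet the retrieval consumes. The
#' 2.1 um apparent reflectance is computed from the surface NIR reflectance
#' through the forward model; the true visible surface reflectances are then
#' defined by the dark-target ratios applied to that apparent NIR value
#' (red = half, blue = quarter), so the synthetic world satisfies the
#' retrieval's surface assumption by construction, and the forward/inverse
#' round trip isolates lookup-table and solver error. Optionally injects
#' bright cloud blobs.
#'
#' @param aod True AOD matrix (550 nm).
#' @param geom Scene-wide [view_geometry()].
#' @param date Scene date.
#' @param surface_nir Surface reflectance at 2.1 um: scalar or matrix.
#' @param atm Atmospheric functions shared with the lookup table.
#' @param cloud_mask Optional logical matrix; cloudy cells get reflectance
#'   `cloud_reflectance` in all bands.
#' @param cloud_reflectance Apparent reflectance of cloudy cells.
#' @return A `reflectance_scene`: bands `rho_b` (470), `rho_r` (660),
#'   `rho_n` (2100), plus geometry, date and the true cloud mask.
#' @export
synthesize_scene <- function(aod, geom, date = as.Date("2016-05-01"),
                             surface_nir = 0.15, atm = default_atmosphere(),
                             cloud_mask = NULL, cloud_reflectance = 0.8) {
  if (length(surface_nir) == 1)
    surface_nir <- matrix(surface_nir, nrow(aod), ncol(aod))
  rho_n <- toa_reflectance(surface_nir, aod, geom, 2100, atm)
  surf <- estimate_surface_reflectance(rho_n)
  rho_r <- toa_reflectance(surf$red, aod, geom, 660, atm)
  rho_b <- toa_reflectance(surf$blue, aod, geom, 470, atm)
  if (!is.null(cloud_mask)) {
    rho_n[cloud_mask] <- cloud_reflectance
    rho_r[cloud_mask] <- cloud_reflectance
    rho_b[cloud_mask] <- cloud_reflectance
  } else {
    cloud_mask <- matrix(FALSE, nrow(aod), ncol(aod))
  }
  reflectance_scene(rho_b = rho_b, rho_r = rho_r, rho_n = rho_n,
                    geom = geom, date = date, cloud_mask = cloud_mask)
}

#' Generate a random cloud mask
#'
#' Thresholds a smoothed Gaussian noise field at the quantile giving the
#' requested cloud fraction, producing spatially coherent cloud blobs.
#'
#' @param spec A [grid_spec()].
#' @param fraction Cloudy-cell fraction in `[0, 1)`.
#' @param blob_sd Blob length scale in cells.
#' @param seed Integer seed.
#' @return Logical matrix, `TRUE` = cloudy.
#' @export
generate_cloud_mask <- function(spec, fraction = 0.1, blob_sd = 3,
                                seed = 1L) {
  if (fraction < 0 || fraction >= 1) stop("`fraction` must lie in [0, 1)")
  nr <- spec$n_rows; nc <- spec$n_cols
  if (fraction == 0) return(matrix(FALSE, nr, nc))
  z <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  sm <- gaussian_smooth(z, blob_sd)
  sm >= stats::quantile(sm, 1 - fraction)
}

#' Synthetic region labels
#'
#' Splits the grid into a `blocks x blocks` checkerboard of labelled regions,
#' standing in for administrative boundaries.
#'
#' @param spec A [grid_spec()].
#' @param blocks Regions per side.
#' @return Character matrix of region labels (`"R11"`, `"R12"`, ...).
#' @export
generate_regions <- function(spec, blocks = 2) {
  rb <- ceiling(row(matrix(0, spec$n_rows, spec$n_cols)) /
                  (spec$n_rows / blocks))
  cb <- ceiling(col(matrix(0, spec$n_rows, spec$n_cols)) /
                  (spec$n_cols / blocks))
  matrix(sprintf("R%d%d", rb, cb), spec$n_rows, spec$n_cols)
}

#' Generate a complete synthetic truth bundle
#'
#' One call producing every pipeline input with known ground truth: per
#' season, a base AOD field, daily AOD fields (the base modulated by a
#' day-to-day lognormal factor, clamped to `[0, 1.95]`), daily PM2.5 truth
#' grids from the season's generating law with multiplicative noise, and the
#' noise-free seasonal reference PM2.5 grid (the generating law applied to
#' the seasonal mean AOD); plus a population surface, a clustered station
#' network and scene dates. The generating laws default to the published
#' seasonal relations of the study region. Regeneration with the same seed
#' is bit-for-bit identical.
#'
#' @param spec A [grid_spec()].
#' @param season_params Named list (season -> list(family, a0, a1)); defaults
#'   to power laws in spring (57.754 x^0.6976), autumn (63.391 x^0.5718) and
#'   winter (78.184 x^0.4069) and an exponential in summer
#'   (13.855 e^(0.8954 x)).
#' @param n_dates_per_season Scene dates drawn per season.
#' @param noise_cv Multiplicative noise CV of the daily PM2.5 truth.
#' @param day_cv Day-to-day lognormal variation of the AOD level.
#' @param seed Master seed.
#' @return A `truth_bundle` list: `spec`, `season_params`, `aod_fields` and
#'   `pm25_fields` (seasonal truth), `aod_daily` and `pm25_daily` (per-date
#'   lists), `population`, `network`, `dates`, `seed`.
#' @export
truth_bundle <- function(spec,
                         season_params = default_season_params(),
                         n_dates_per_season = 6, noise_cv = 0.1,
                         day_cv = 0.25, seed = 7L) {
  seeds <- derive_seeds(seed, 6 + 4 * length(season_params))
  population <- generate_population(spec, seed = seeds[1])
  network <- generate_station_network(spec, population = population,
                                      seed = seeds[2])
  seasons <- names(season_params)
  month_pool <- list(spring = 3:5, summer = 6:8, autumn = c(9, 11),
                     winter = c(2, 12))
  aod_fields <- list(); pm25_fields <- list()
  aod_daily <- list(); pm25_daily <- list(); dates <- list()
  for (i in seq_along(seasons)) {
    s <- seasons[i]
    sd_base <- seeds[2 + 4 * (i - 1) + 1]
    base <- generate_aod_field(spec, seed = sd_base)
    p <- season_params[[s]]
    mons <- month_pool[[s]]
    dd <- sort(as.Date(sprintf("2016-%02d-%02d",
                               rep(mons, length.out = n_dates_per_season),
                               round(seq(3, 27,
                                         length.out = n_dates_per_season)))))
    sdlog <- sqrt(log(1 + day_cv^2))
    factors <- with_seed(seeds[2 + 4 * (i - 1) + 2],
                         stats::rlnorm(length(dd), -sdlog^2 / 2, sdlog))
    day_seeds <- derive_seeds(seeds[2 + 4 * (i - 1) + 3], length(dd))
    ad <- list(); pd <- list()
    for (k in seq_along(dd)) {
      a <- pmin(pmax(base * factors[k], 0), 1.95)
      ad[[format(dd[k])]] <- a
      pd[[format(dd[k])]] <- generate_pm25_truth(a, p$family, p$a0, p$a1,
                                                 noise_cv = noise_cv,
                                                 seed = day_seeds[k])
    }
    aod_daily[[s]] <- ad
    pm25_daily[[s]] <- pd
    aod_fields[[s]] <- Reduce(`+`, ad) / length(ad)
    pm25_fields[[s]] <- generate_pm25_truth(aod_fields[[s]], p$family,
                                            p$a0, p$a1, noise_cv = 0)
    dates[[s]] <- dd
  }
  structure(list(spec = spec, season_params = season_params,
                 aod_fields = aod_fields, pm25_fields = pm25_fields,
                 aod_daily = aod_daily, pm25_daily = pm25_daily,
                 population = population, network = network, dates = dates,
                 seed = seed),
            class = "truth_bundle")
}

#' @rdname truth_bundle
#' @export
default_season_params <- function() {
  list(
    spring = list(family = "power", a0 = 57.754, a1 = 0.6976),
    summer = list(family = "exponential", a0 = 13.855, a1 = 0.8954),
    autumn = list(family = "power", a0 = 63.391, a1 = 0.5718),
    winter = list(family = "power", a0 = 78.184, a1 = 0.4069)
  )
}
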