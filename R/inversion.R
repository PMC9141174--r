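#' Construct a reflectance scene
#'
#' The retrieval's input: apparent (top-of-atmosphere) reflectance grids at
#' 0.47, 0.66 and 2.1 um sharing one grid, a scene-wide viewing geometry, a
#' date and a cloud mask.
#'
#' @param rho_b,rho_r,rho_n Apparent reflectance matrices at 470 nm, 660 nm
#'   and 2100 nm (values in `[0, 1]` or `NA`).
#' @param geom A [view_geometry()].
#' @param date Scene date.
#' @param cloud_mask Logical matrix (default: all clear).
#' @return A `reflectance_scene`.
#' @export
reflectance_scene <- function(rho_b, rho_r, rho_n, geom,
                              date = as.Date("2016-05-01"),
                              cloud_mask = NULL) {
  dims <- dim(rho_n)
  if (!identical(dim(rho_b), dims) || !identical(dim(rho_r), dims))
    stop("all bands must share one grid")
  for (b in list(rho_b, rho_r, rho_n))
    if (any(b < 0 | b > 1, na.rm = TRUE))
      stop("reflectances must lie in [0, 1] or be NA")
  if (is.null(cloud_mask)) cloud_mask <- matrix(FALSE, dims[1], dims[2])
  if (!identical(dim(cloud_mask), dims))
    stop("`cloud_mask` must share the band grid")
  structure(list(rho_b = rho_b, rho_r = rho_r, rho_n = rho_n, geom = geom,
                 date = as.Date(date), cloud_mask = cloud_mask),
            class = "reflectance_scene")
}

#' Dark-target surface reflectance estimate
#'
#' The core dark-target relations: over dark (vegetated) pixels the 2.1 um
#' channel is nearly transparent to aerosol, so its apparent reflectance
#' approximates the surface, and the visible surface reflectances follow the
#' fixed ratios red = rho_n / 2 and blue = rho_n / 4.
#'
#' @param rho_n Apparent 2.1 um reflectance (matrix or vector), `[0, 1]`
#'   or `NA`.
#' @return A list with matrices `red` and `blue`; `NA` propagates.
#' @export
estimate_surface_reflectance <- function(rho_n) {
  if (any(rho_n < 0 | rho_n > 1, na.rm = TRUE))
    stop("`rho_n` must lie in [0, 1] or be NA")
  list(red = rho_n / 2, blue = rho_n / 4)
}

# Focal (3x3 and larger) standard deviation with edge shrinkage.
focal_sd <- function(m, window = 3) {
  half <- (window - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr, nc); s2 <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  for (dr in -half:half) for (dc in -half:half) {
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    sub <- m[rs + dr, cs + dc, drop = FALSE]
    ok <- !is.na(sub)
    v <- ifelse(ok, sub, 0)
    s[rs, cs] <- s[rs, cs] + v
    s2[rs, cs] <- s2[rs, cs] + v^2
    n[rs, cs] <- n[rs, cs] + ok
  }
  out <- matrix(sqrt(pmax(0, s2 / pmax(n, 1) - (s / pmax(n, 1))^2)), nr, nc)
  out[n < 2] <- 0
  out
}

#' Screen cloudy cells
#'
#' A proxy cloud screen (the operational tool the method relies on is
#' unpublished): a cell is flagged cloudy when its blue-band apparent
#' reflectance exceeds a brightness threshold, or when the local standard
#' deviation of the blue band within a square window exceeds a uniformity
#' limit (clouds are bright and spatially ragged). The default brightness
#' threshold sits above the brightest haze-laden clear sky the atmospheric
#' model can produce over a dark surface (about 0.65 at the heaviest
#' admissible aerosol loading and most slanted geometry), so heavy aerosol is
#' never misclassified as cloud while fully bright cloud decks are always
#' caught.
#'
#' @param scene A [reflectance_scene()].
#' @param brightness_threshold Blue-band reflectance above which a cell is
#'   cloudy (default 0.7).
#' @param sd_threshold Local standard-deviation limit (default 0.08).
#' @param uniformity_window Odd window edge in cells (default 3).
#' @return Logical matrix, `TRUE` = cloudy.
#' @export
detect_clouds <- function(scene, brightness_threshold = 0.7,
                          sd_threshold = 0.08, uniformity_window = 3) {
  if (brightness_threshold <= 0 || brightness_threshold >= 1)
    stop("`brightness_threshold` must lie in (0, 1)")
  if (uniformity_window < 1) stop("`uniformity_window` must be >= 1 cell")
  bright <- !is.na(scene$rho_b) & scene$rho_b > brightness_threshold
  ragged <- if (uniformity_window >= 3) {
    focal_sd(scene$rho_b, uniformity_window) > sd_threshold
  } else matrix(FALSE, nrow(scene$rho_b), ncol(scene$rho_b))
  bright | ragged
}

# Vectorised bisection for the per-cell inversion objective along the
# piecewise-linear interpolated LUT tau axis. `prof` holds rho_a/trans/salb at
# the tau nodes; rho is the per-cell surface reflectance, obs the per-cell
# apparent reflectance. Returns tau per cell (NA where not retrievable).
solve_tau_band <- function(prof, taus, rho, obs, iterations = 60L,
                           deficit_tol = 0.01) {
  pred_at <- function(tau) {
    i <- findInterval(tau, taus, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(taus) - 1L)
    w <- (tau - taus[i]) / (taus[i + 1] - taus[i])
    ra <- prof$rho_a[i] * (1 - w) + prof$rho_a[i + 1] * w
    tr <- prof$trans[i] * (1 - w) + prof$trans[i + 1] * w
    sa <- prof$salb[i] * (1 - w) + prof$salb[i + 1] * w
    ra + tr * rho / (1 - rho * sa)
  }
  lo <- rep(taus[1], length(rho))
  hi <- rep(taus[length(taus)], length(rho))
  f_lo <- pred_at(lo) - obs
  f_hi <- pred_at(hi) - obs
  tau <- rep(NA_real_, length(rho))
  # Observation dimmer than the clean-atmosphere prediction: no aerosol
  # loading explains it. Tolerate small deficits as tau = 0, reject gross ones.
  below <- !is.na(f_lo) & f_lo >= 0
  tau[below & f_lo <= deficit_tol] <- taus[1]
  # Observation brighter than the tau-max prediction: clip to the range top.
  above <- !is.na(f_hi) & f_hi <= 0
  tau[above] <- taus[length(taus)]
  solve <- which(!is.na(f_lo) & f_lo < 0 & f_hi > 0)
  if (length(solve)) {
    l <- lo[solve]; h <- hi[solve]
    r <- rho[solve]; o <- obs[solve]
    pred_sub <- function(tau_v) {
      i <- findInterval(tau_v, taus, rightmost.closed = TRUE)
      i <- pmin(pmax(i, 1L), length(taus) - 1L)
      w <- (tau_v - taus[i]) / (taus[i + 1] - taus[i])
      ra <- prof$rho_a[i] * (1 - w) + prof$rho_a[i + 1] * w
      tr <- prof$trans[i] * (1 - w) + prof$trans[i + 1] * w
      sa <- prof$salb[i] * (1 - w) + prof$salb[i + 1] * w
      ra + tr * r / (1 - r * sa)
    }
    for (it in seq_len(iterations)) {
      mid <- (l + h) / 2
      up <- pred_sub(mid) < o
      l <- ifelse(up, mid, l)
      h <- ifelse(up, h, mid)
    }
    tau[solve] <- (l + h) / 2
  }
  tau
}

#' Retrieve AOD from a reflectance scene
#'
#' The enhanced dark-target retrieval: per valid cell, (i) estimate the
#' visible surface reflectances from the apparent 2.1 um channel
#' ([estimate_surface_reflectance()]); (ii) for each of the red and blue
#' bands, find the AOD whose lookup-table-predicted apparent reflectance
#' matches the observation (bisection on the interpolated, monotone tau axis,
#' tolerance < 1e-6); (iii) average the two per-band retrievals (the
#' surviving one if only one brackets). Cells that are cloud-masked, have
#' missing bands, or fail the dark-pixel screen (`rho_n > dark_limit`) are
#' nodata. Retrievals beyond the table top are clipped to 1.95; observations
#' dimmer than the clean-atmosphere prediction by more than a small
#' reflectance tolerance are nodata.
#'
#' @param scene A [reflectance_scene()].
#' @param lut A `lookup_table` from [build_lookup_table()] or [lut_load()].
#' @param dark_limit Dark-pixel admissibility threshold on apparent 2.1 um
#'   reflectance (default 0.25).
#' @param cloud_mask Optional logical matrix overriding `scene$cloud_mask`.
#' @return An `aod_field`: list with `tau550` matrix (`NA` = nodata) and
#'   `period` (the scene date).
#' @export
invert_aod <- function(scene, lut, dark_limit = 0.25, cloud_mask = NULL) {
  if (dark_limit <= 0 || dark_limit >= 1)
    stop("`dark_limit` must lie in (0, 1)")
  if (!all(c(470, 660) %in% lut$axes$band_nm))
    stop("lookup table lacks a required band (470/660 nm)")
  cm <- if (is.null(cloud_mask)) scene$cloud_mask else cloud_mask
  valid <- !cm & !is.na(scene$rho_n) & !is.na(scene$rho_r) &
    !is.na(scene$rho_b) & scene$rho_n <= dark_limit
  taus <- lut$axes$tau550
  out <- matrix(NA_real_, nrow(scene$rho_n), ncol(scene$rho_n))
  idx <- which(valid)
  if (length(idx)) {
    surf <- estimate_surface_reflectance(scene$rho_n[idx])
    prof_r <- lut_tau_profile(lut, scene$geom, 660)
    prof_b <- lut_tau_profile(lut, scene$geom, 470)
    tau_r <- solve_tau_band(prof_r, taus, surf$red, scene$rho_r[idx])
    tau_b <- solve_tau_band(prof_b, taus, surf$blue, scene$rho_b[idx])
    comb <- rowMeans(cbind(tau_r, tau_b), na.rm = TRUE)
    comb[is.nan(comb)] <- NA_real_
    out[idx] <- pmin(pmax(comb, 0), 1.95)
  }
  structure(list(tau550 = out, period = format(scene$date)),
            class = "aod_field")
}

#' Composite AOD fields over time
#'
#' Cellwise arithmetic mean over the fields in which the cell is valid; a
#' cell is valid in the output if it is valid in at least one input, so
#' cloud gaps in single days do not punch holes in monthly means. Seasonal
#' composites should be built from monthly composites (two-stage averaging),
#' not from pooled daily fields.
#'
#' @param fields Non-empty list of `aod_field` objects (or bare matrices)
#'   sharing one grid.
#' @param period Label for the composite (e.g. `"2016-05"` or `"spring"`).
#' @return An `aod_field` with the composite `tau550` and the given `period`.
#' @export
composite_temporal <- function(fields, period = "composite") {
  if (length(fields) == 0) stop("`fields` must be a non-empty list")
  mats <- lapply(fields, function(f) if (inherits(f, "aod_field")) f$tau550 else f)
  dims <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), dims), TRUE)))
    stop("all fields must share one grid")
  sum_v <- matrix(0, dims[1], dims[2])
  n_v <- matrix(0L, dims[1], dims[2])
  for (m in mats) {
    ok <- !is.na(m)
    sum_v[ok] <- sum_v[ok] + m[ok]
    n_v <- n_v + ok
  }
  out <- sum_v / n_v
  out[n_v == 0L] <- NA_real_
  structure(list(tau550 = out, period = period), class = "aod_field")
}
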