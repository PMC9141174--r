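#' Viewing geometry for a scene
#'
#' Solar and satellite zenith angles (degrees, 0-60: the span of the default
#' lookup table) and the relative azimuth between the two azimuth planes
#' (degrees, 0-180).
#'
#' @param solar_zenith,satellite_zenith Zenith angles in degrees.
#' @param relative_azimuth Relative azimuth in degrees.
#' @return A `view_geometry` with derived cosines `mu0 = cos(solar zenith)`
#'   and `mu = cos(satellite zenith)`.
#' @export
view_geometry <- function(solar_zenith, satellite_zenith, relative_azimuth) {
  chk <- function(v, lo, hi, nm) {
    if (any(!is.finite(v)) || any(v < lo) || any(v > hi))
      stop(sprintf("`%s` must lie in [%g, %g] degrees", nm, lo, hi))
  }
  chk(solar_zenith, 0, 60, "solar_zenith")
  chk(satellite_zenith, 0, 60, "satellite_zenith")
  chk(relative_azimuth, 0, 180, "relative_azimuth")
  structure(
    list(solar_zenith = solar_zenith, satellite_zenith = satellite_zenith,
         relative_azimuth = relative_azimuth,
         mu0 = cos(solar_zenith * pi / 180),
         mu = cos(satellite_zenith * pi / 180)),
    class = "view_geometry"
  )
}

# Cosine of the scattering angle between sun and sensor directions.
scattering_cosine <- function(geom) {
  -geom$mu * geom$mu0 +
    sqrt(pmax(0, 1 - geom$mu^2)) * sqrt(pmax(0, 1 - geom$mu0^2)) *
      cos(geom$relative_azimuth * pi / 180)
}

#' Parametric atmospheric functions
#'
#' A smooth, monotone forward model supplying the three atmospheric
#' quantities of the apparent-reflectance equation: path reflectance
#' `rho_a(tau, geometry, band)`, two-way transmittance product
#' `T(tau, geometry)` and spherical albedo `s(tau)`. It is a deliberately
#' simple single-scattering-style family, not a full radiative-transfer code:
#' the pipeline's correctness claims are about forward/inverse consistency,
#' which any monotone forward model with the correct limits exercises, and
#' the lookup-table interface accepts externally tabulated values wherever a
#' full code's output is available.
#'
#' Spectral scaling follows an Angstrom law `eta(lambda) = (lambda/550)^-1.6`
#' so aerosol influence is strongest in the blue (470 nm) and nearly
#' negligible at 2.1 um, the premise of the dark-target method. The clean
#' atmosphere limits hold exactly: `rho_a(0) = 0`, `T(0) = 1`, `s(0) = 0`.
#' `rho_a` grows as a rational function of the slant optical path, chosen so
#' the top-of-atmosphere reflectance stays strictly increasing in `tau` over
#' dark surfaces throughout the admissible geometry span (the invertibility
#' guarantee), while never pushing the total above 1.
#'
#' @param omega Path-reflectance amplitude (default 0.32).
#' @param b Transmittance decay rate per unit slant optical depth
#'   (default 0.3).
#' @param c_alb Spherical-albedo saturation level (default 0.2).
#' @param angstrom Angstrom exponent of the spectral scaling (default 1.6).
#' @return A list of class `atmospheric_functions` with elements `rho_a`,
#'   `trans`, `salb` (vectorised in `tau`) and the parameter set.
#' @export
default_atmosphere <- function(omega = 0.32, b = 0.3, c_alb = 0.2,
                               angstrom = 1.6) {
  eta <- function(band_nm) (band_nm / 550)^(-angstrom)
  structure(list(
    rho_a = function(tau, geom, band_nm) {
      m <- 1 / geom$mu + 1 / geom$mu0
      p <- 0.75 + 0.25 * scattering_cosine(geom)^2
      x <- tau * eta(band_nm) * m
      omega * p * x / (1 + 0.4 * x)
    },
    trans = function(tau, geom) {
      m <- 1 / geom$mu + 1 / geom$mu0
      exp(-b * tau * m / 2)
    },
    salb = function(tau) c_alb * (1 - exp(-tau)),
    params = list(omega = omega, b = b, c_alb = c_alb, angstrom = angstrom)
  ), class = "atmospheric_functions")
}

#' Top-of-atmosphere (apparent) reflectance
#'
#' The standard coupling of surface and atmosphere:
#' `rho* = rho_a + T * rho / (1 - rho * s)`,
#' with `rho_a` the atmospheric path reflectance, `T` the product of downward
#' and upward transmittances, `rho` the surface reflectance and `s` the
#' atmospheric spherical albedo.
#'
#' @param surface_refl Surface reflectance in `[0, 1)`; vector or matrix.
#' @param tau550 AOD at 550 nm in `[0, 1.95]`; scalar or shaped like
#'   `surface_refl`.
#' @param geom A [view_geometry()].
#' @param band_nm Band centre wavelength in nm (470, 660 or 2100 for the
#'   standard triplet; any positive value is accepted by the parametric model).
#' @param atm Atmospheric functions, default [default_atmosphere()].
#' @return Apparent reflectance, same shape as `surface_refl`, in `[0, 1]`.
#' @export
toa_reflectance <- function(surface_refl, tau550, geom, band_nm,
                            atm = default_atmosphere()) {
  ok <- is.na(surface_refl) | (surface_refl >= 0 & surface_refl < 1)
  if (!all(ok)) stop("`surface_refl` must lie in [0, 1)")
  if (any(tau550 < 0 | tau550 > 1.95, na.rm = TRUE))
    stop("`tau550` must lie in [0, 1.95]")
  s <- atm$salb(tau550)
  denom <- 1 - surface_refl * s
  if (any(denom <= 0, na.rm = TRUE))
    stop("rho * s >= 1: multiple-scattering series diverges")
  atm$rho_a(tau550, geom, band_nm) +
    atm$trans(tau550, geom) * surface_refl / denom
}

#' Default lookup-table axes
#'
#' Zenith angles every 12 degrees from 0 to 60, relative azimuth every 24
#' degrees with the 180-degree endpoint appended, the six AOD nodes
#' 0/0.25/0.50/1.00/1.50/1.95, and the 470/660/2100 nm band triplet.
#'
#' @return A named list of axis vectors.
#' @export
default_lut_axes <- function() {
  list(
    satellite_zenith = c(0, 12, 24, 36, 48, 60),
    solar_zenith = c(0, 12, 24, 36, 48, 60),
    relative_azimuth = c(seq(0, 168, by = 24), 180),
    tau550 = c(0, 0.25, 0.50, 1.00, 1.50, 1.95),
    band_nm = c(470, 660, 2100)
  )
}

#' Build an atmospheric lookup table
#'
#' Evaluates the atmospheric functions on the full grid of
#' geometry x AOD x band nodes. The retrieval interpolates this table rather
#' than calling the forward model, so a table computed offline by a full
#' radiative-transfer code can be dropped in via [lut_load()].
#'
#' @param atm Atmospheric functions ([default_atmosphere()] by default).
#' @param axes Axis definition as from [default_lut_axes()].
#' @return A `lookup_table`: the axes plus arrays `rho_a`, `trans`, `salb`
#'   indexed `[satellite_zenith, solar_zenith, relative_azimuth, tau, band]`.
#' @export
build_lookup_table <- function(atm = default_atmosphere(),
                               axes = default_lut_axes()) {
  need <- c("satellite_zenith", "solar_zenith", "relative_azimuth",
            "tau550", "band_nm")
  if (!all(need %in% names(axes))) stop("`axes` must define: ",
                                        paste(need, collapse = ", "))
  for (nm in need) {
    v <- axes[[nm]]
    if (length(v) < 1 || is.unsorted(v, strictly = TRUE))
      stop(sprintf("axis `%s` must be strictly increasing", nm))
  }
  if (length(axes$tau550) < 2)
    stop("`tau550` axis needs at least 2 nodes for the inversion")
  dims <- vapply(axes[need], length, 0L)
  rho_a <- array(NA_real_, dims)
  trans <- array(NA_real_, dims)
  salb <- array(NA_real_, dims)
  for (i in seq_along(axes$satellite_zenith))
    for (j in seq_along(axes$solar_zenith))
      for (k in seq_along(axes$relative_azimuth)) {
        g <- view_geometry(axes$solar_zenith[j], axes$satellite_zenith[i],
                           axes$relative_azimuth[k])
        for (b in seq_along(axes$band_nm)) {
          rho_a[i, j, k, , b] <- atm$rho_a(axes$tau550, g, axes$band_nm[b])
          trans[i, j, k, , b] <- atm$trans(axes$tau550, g)
          salb[i, j, k, , b] <- atm$salb(axes$tau550)
        }
      }
  lut <- structure(list(axes = axes[need], rho_a = rho_a, trans = trans,
                        salb = salb), class = "lookup_table")
  validate_lut(lut)
  lut
}

validate_lut <- function(lut) {
  if (length(lut$axes$tau550) < 2)
    stop("lookup table has a single tau node: inversion impossible")
  mono <- apply(lut$rho_a, c(1, 2, 3, 5), function(v) all(diff(v) > 0))
  if (!all(mono))
    stop("lookup table path reflectance is not strictly increasing in tau")
  invisible(lut)
}

# Locate v on a strictly increasing axis: bracket indices and weight.
axis_weight <- function(axis, v, name) {
  if (v < axis[1] - 1e-12 || v > axis[length(axis)] + 1e-12)
    stop(sprintf("query %.6g outside the span of axis `%s` [%g, %g]",
                 v, name, axis[1], axis[length(axis)]))
  v <- min(max(v, axis[1]), axis[length(axis)])
  if (length(axis) == 1L) return(list(i0 = 1L, i1 = 1L, w = 0))
  i1 <- findInterval(v, axis, rightmost.closed = TRUE)
  i1 <- min(max(i1, 1L), length(axis) - 1L)
  w <- (v - axis[i1]) / (axis[i1 + 1] - axis[i1])
  list(i0 = i1, i1 = i1 + 1L, w = w)
}

#' Interpolate the lookup table
#'
#' Multi-linear interpolation over the four continuous axes (two zeniths,
#' relative azimuth, AOD); the band is matched to the nearest band node.
#' Exact at table nodes.
#'
#' @param lut A `lookup_table`.
#' @param geom A [view_geometry()] (scalar angles).
#' @param tau550 AOD query (scalar or vector).
#' @param band_nm Band wavelength; snapped to the nearest band axis node.
#' @return A list of vectors `rho_a`, `trans`, `salb`, one value per `tau550`.
#' @export
interpolate_lut <- function(lut, geom, tau550, band_nm) {
  ax <- lut$axes
  bi <- which.min(abs(ax$band_nm - band_nm))
  wv <- axis_weight(ax$satellite_zenith, geom$satellite_zenith,
                    "satellite_zenith")
  ws <- axis_weight(ax$solar_zenith, geom$solar_zenith, "solar_zenith")
  wa <- axis_weight(ax$relative_azimuth, geom$relative_azimuth,
                    "relative_azimuth")
  out <- lapply(tau550, function(tv) {
    wt <- axis_weight(ax$tau550, tv, "tau550")
    acc <- c(rho_a = 0, trans = 0, salb = 0)
    for (a1 in 0:1) for (a2 in 0:1) for (a3 in 0:1) for (a4 in 0:1) {
      wgt <- (if (a1) wv$w else 1 - wv$w) * (if (a2) ws$w else 1 - ws$w) *
             (if (a3) wa$w else 1 - wa$w) * (if (a4) wt$w else 1 - wt$w)
      if (wgt == 0) next
      i <- if (a1) wv$i1 else wv$i0
      j <- if (a2) ws$i1 else ws$i0
      k <- if (a3) wa$i1 else wa$i0
      l <- if (a4) wt$i1 else wt$i0
      acc <- acc + wgt * c(lut$rho_a[i, j, k, l, bi],
                           lut$trans[i, j, k, l, bi],
                           lut$salb[i, j, k, l, bi])
    }
    acc
  })
  m <- do.call(rbind, out)
  list(rho_a = m[, 1], trans = m[, 2], salb = m[, 3])
}

# Geometry-slice of the LUT: atmospheric quantities at every tau node for one
# band, interpolated to the scene geometry. The workhorse of the inversion.
lut_tau_profile <- function(lut, geom, band_nm) {
  interpolate_lut(lut, geom, lut$axes$tau550, band_nm)
}

#' Save / load a lookup table
#'
#' Serialises the table (axes + value arrays) to a self-describing JSON text
#' container; the loader re-validates the monotonicity invariant, so an
#' externally tabulated radiative-transfer LUT can be substituted.
#'
#' @param lut A `lookup_table`.
#' @param path File path.
#' @return `lut_save` returns `path` invisibly; `lut_load` returns the table.
#' @export
lut_save <- function(lut, path) {
  payload <- list(axes = lut$axes,
                  dim = dim(lut$rho_a),
                  rho_a = as.numeric(lut$rho_a),
                  trans = as.numeric(lut$trans),
                  salb = as.numeric(lut$salb))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname lut_save
#' @export
lut_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- stats::setNames(as.integer(p$dim), names(p$axes))
  lut <- structure(list(
    axes = lapply(p$axes, as.numeric),
    rho_a = array(p$rho_a, dims),
    trans = array(p$trans, dims),
    salb = array(p$salb, dims)
  ), class = "lookup_table")
  validate_lut(lut)
  lut
}
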