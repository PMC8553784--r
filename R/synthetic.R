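#' Specification for synthetic control/scenario fields
#'
#' Describes the statistical structure that the emergence detector assumes:
#' a stationary control with AR(1) interannual noise and optional linear
#' drift, and scenario runs sharing the control's noise statistics plus
#' spatially varying linear ramp trends with known onset years. All
#' randomness is driven by the explicit `seed`; there is no hidden global
#' random state.
#'
#' @param nlat,nlon Grid shape.
#' @param lat_range,lon_range Coordinate extents in degrees (cell centers
#'   are placed at regular intervals inside the range).
#' @param years Consecutive years of the runs (default 1801:2100).
#' @param mean Control mean level (tracer units).
#' @param drift Control linear drift (units yr-1; default 0).
#' @param phi AR(1) coefficient in [0, 0.95] (default 0.5, giving the mild
#'   decadal persistence that motivates an 11-yr smoothing window).
#' @param innovation_sd AR(1) innovation SD (> 0); the marginal SD of the
#'   noise is `innovation_sd / sqrt(1 - phi^2)`.
#' @param onset_year Trend onset year, scalar or `[nlat, nlon]` matrix.
#' @param ramp_rate Linear trend rate after onset (units yr-1), scalar or
#'   matrix.
#' @param amplitude Spatial amplitude mask multiplying the ramp, scalar or
#'   matrix (default 1 everywhere).
#' @param seed Integer random seed (mandatory).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(nlat = 16, nlon = 32, lat_range = c(-60, 60),
                       lon_range = c(0, 360), years = 1801:2100,
                       mean = 5, drift = 0, phi = 0.5, innovation_sd = 0.1,
                       onset_year = 2000, ramp_rate = 0, amplitude = 1,
                       seed) {
  if (missing(seed)) stop("an explicit integer seed is required", call. = FALSE)
  stopifnot(phi >= 0, phi <= 0.95, innovation_sd > 0, nlat >= 1, nlon >= 1)
  years <- as.integer(years)
  if (any(diff(years) != 1L)) stop("years must be consecutive", call. = FALSE)
  as_field <- function(x, what) {
    if (length(x) == 1) x <- matrix(x, nlat, nlon)
    if (!identical(dim(x), c(as.integer(nlat), as.integer(nlon)))) {
      stop(sprintf("'%s' must be a scalar or an [nlat, nlon] matrix", what), call. = FALSE)
    }
    x
  }
  onset_year <- as_field(onset_year, "onset_year")
  if (any(onset_year < min(years) | onset_year > max(years))) {
    stop("onset years must lie within the simulated span", call. = FALSE)
  }
  lat <- seq(lat_range[1], lat_range[2], length.out = nlat + 1)
  lat <- (lat[-1] + lat[-(nlat + 1)]) / 2
  lon <- seq(lon_range[1], lon_range[2], length.out = nlon + 1)
  lon <- (lon[-1] + lon[-(nlon + 1)]) / 2
  structure(list(nlat = nlat, nlon = nlon, lat = lat, lon = lon,
                 years = years, mean = mean, drift = drift, phi = phi,
                 innovation_sd = innovation_sd, onset_year = onset_year,
                 ramp_rate = as_field(ramp_rate, "ramp_rate"),
                 amplitude = as_field(amplitude, "amplitude"),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# AR(1) noise matrix [nyear, ncell] with stationary initialization,
# leaving the caller's RNG state untouched
ar1_noise <- function(spec, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  ncell <- spec$nlat * spec$nlon
  n <- length(spec$years)
  marg_sd <- spec$innovation_sd / sqrt(1 - spec$phi^2)
  e <- matrix(0, n, ncell)
  e[1, ] <- stats::rnorm(ncell, 0, marg_sd)
  innov <- matrix(stats::rnorm((n - 1) * ncell, 0, spec$innovation_sd), n - 1, ncell)
  for (t in 2:n) e[t, ] <- spec$phi * e[t - 1, ] + innov[t - 1, ]
  e
}

#' Generate a synthetic preindustrial control grid
#'
#' Mean + drift + AR(1) noise per cell, bit-reproducible from the spec's
#' seed.
#'
#' @param spec A [synth_spec()].
#' @return An [annual_grid()] with `role = "control"`.
#' @export
gen_control <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  base <- spec$mean + spec$drift * (spec$years - spec$years[1])
  vals <- ar1_noise(spec, spec$seed) + base
  annual_grid(array(vals, c(length(spec$years), spec$nlat, spec$nlon)),
              spec$years, spec$lat, spec$lon, var = "tracer",
              units = "", role = "control")
}

#' Generate a synthetic forced-scenario grid with known truth
#'
#' An independent AR(1) noise realization with the control's statistics,
#' plus a per-cell linear ramp `ramp_rate * amplitude * max(0, year -
#' onset_year)` superposed on the control baseline. The true onset-year and
#' effective-rate fields are attached as attribute `"truth"` for
#' parameter-recovery studies.
#'
#' @param spec A [synth_spec()]; the scenario realization uses `seed + 1`
#'   so that control and scenario noise are independent but jointly
#'   reproducible.
#' @return An [annual_grid()] with `role = "scenario"`.
#' @export
gen_scenario <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  base <- spec$mean + spec$drift * (spec$years - spec$years[1])
  rate <- spec$ramp_rate * spec$amplitude
  elapsed <- outer(spec$years, as.vector(spec$onset_year), function(y, o) pmax(0, y - o))
  ramp <- elapsed * rep(as.vector(rate), each = length(spec$years))
  vals <- ar1_noise(spec, spec$seed + 1L) + base + ramp
  g <- annual_grid(array(vals, c(length(spec$years), spec$nlat, spec$nlon)),
                   spec$years, spec$lat, spec$lon, var = "tracer",
                   units = "", role = "scenario")
  attr(g, "truth") <- list(onset_year = spec$onset_year, rate = rate)
  g
}

#' Build flux fields with prescribed isotopic signatures
#'
#' Constructs the six per-cell biogeochemical nitrate flux components
#' (nitrification source, new-production and denitrification sinks; light
#' and heavy each) from light-isotope magnitudes and per-mil signatures,
#' using the enrichment-weighted heavy convention. On single-flux cells the
#' tendency diagnostic recovers the prescribed signature exactly.
#'
#' @param signatures Named list/vector with per-mil entries `nitr`, `new`,
#'   `den` (scalar or `[nlat, nlon]` matrix each).
#' @param magnitudes Named list with non-negative light-flux magnitudes
#'   `nitr`, `new`, `den` (mmol N m-3 yr-1; scalar or matrix each).
#' @param nlat,nlon Grid shape used to expand scalars.
#' @return A [flux_fields()] object.
#' @export
gen_flux_fields <- function(signatures, magnitudes, nlat = 1, nlon = 1) {
  need <- c("nitr", "new", "den")
  stopifnot(all(need %in% names(signatures)), all(need %in% names(magnitudes)))
  expand <- function(x) {
    if (length(x) == 1) matrix(x, nlat, nlon) else as.matrix(x)
  }
  light <- lapply(magnitudes[need], expand)
  delta <- lapply(signatures[need], expand)
  if (any(vapply(light, function(m) any(m < 0), logical(1)))) {
    stop("flux magnitudes must be >= 0", call. = FALSE)
  }
  flux_fields(nitr14 = light$nitr, nitr15 = heavy_from_delta(light$nitr, delta$nitr),
              new14 = light$new, new15 = heavy_from_delta(light$new, delta$new),
              den14 = light$den, den15 = heavy_from_delta(light$den, delta$den))
}
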