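#' Isotopic signature of a pool pair
#'
#' Computes the per-mil nitrogen-isotope signature of a pool under the
#' enrichment-weighted bookkeeping convention used throughout this package:
#' the "light" pool holds the total nitrogen amount and the "heavy" pool
#' holds the same amount weighted by its enrichment relative to a standard
#' ratio of exactly 1, so that `(heavy / light - 1) * 1000` is delta15N in
#' per mil.
#'
#' @param light Numeric vector/array of light-pool amounts (mmol N m-3 or
#'   any consistent unit). Must be strictly positive.
#' @param heavy Numeric vector/array of enrichment-weighted heavy-pool
#'   amounts, same shape and units as `light`.
#' @return Numeric delta15N values in per mil, same shape as the inputs.
#' @examples
#' delta15n(2, 2.010)  # 5 per mil
#' @export
delta15n <- function(light, heavy) {
  check_same_shape(light, heavy)
  if (any(!is.finite(light)) || any(light <= 0)) {
    stop("delta15n is undefined where the light pool is <= 0 or non-finite; ",
         "mask such cells before converting", call. = FALSE)
  }
  (heavy / light - 1) * 1000
}

#' Heavy pool implied by a signature
#'
#' Inverse of [delta15n()]: builds the enrichment-weighted heavy pool that a
#' light pool with the given per-mil signature would carry.
#'
#' @param light Non-negative numeric vector/array of light-pool amounts.
#' @param delta Per-mil signature(s), recycled against `light`.
#' @return Heavy-pool amounts, `light * (1 + delta / 1000)`.
#' @export
heavy_from_delta <- function(light, delta) {
  stopifnot(is.numeric(light), is.numeric(delta))
  if (any(light < 0, na.rm = TRUE)) {
    stop("light pool amounts must be >= 0", call. = FALSE)
  }
  light * (1 + delta / 1000)
}

#' Mask isotope values below the measurement detection limit
#'
#' Nitrate isotope measurements require a minimum substrate concentration
#' (0.3 mmol m-3 for standard denitrifier-method analyses). Signature values
#' where the concentration falls below the threshold are flagged invalid
#' (`NA`), never zeroed, so that downstream statistics skip them.
#'
#' @param conc Concentration field (mmol N m-3).
#' @param delta Per-mil signature field, same shape as `conc`.
#' @param threshold Detection limit in mmol N m-3 (default 0.3).
#' @return `delta` with `NA` wherever `conc < threshold`.
#' @export
mask_below_detection <- function(conc, delta, threshold = 0.3) {
  check_same_shape(conc, delta)
  stopifnot(length(threshold) == 1, is.finite(threshold), threshold >= 0)
  delta[conc < threshold] <- NA_real_
  delta
}

#' N-star tracer
#'
#' Excess nitrate relative to Redfield stoichiometry, `N* = NO3 - 16 * PO4`.
#' Negative values mark nitrogen deficit (denitrification influence),
#' positive values nitrogen excess (nitrogen-fixation influence).
#'
#' @param nitrate,phosphate Concentration fields (mmol m-3), same shape.
#' @return N* field in mmol m-3.
#' @export
nstar <- function(nitrate, phosphate) {
  check_same_shape(nitrate, phosphate)
  nitrate - 16 * phosphate
}

#' Light-based depth-zone boundaries
#'
#' Locates the bottom of the euphotic zone (0.1 % of incident irradiance)
#' and of the twilight zone (0.0001 % of incident irradiance) on a discrete
#' irradiance-fraction profile. Crossings are interpolated log-linearly in
#' the irradiance fraction, since light decays approximately exponentially
#' with depth.
#'
#' @param depth Strictly increasing depths (m), starting at the surface.
#' @param frac Fraction of surface irradiance at each depth; must start at 1
#'   and be strictly decreasing.
#' @return A list with `euphotic_bottom` and `twilight_bottom` depths (m;
#'   `NA` with the matching `*_open` flag set to `TRUE` when the profile
#'   never reaches the threshold).
#' @examples
#' z <- 0:400
#' depth_zone_bounds(z, exp(-z / 20))  # analytic: 138.2 m and 276.3 m
#' @export
depth_zone_bounds <- function(depth, frac) {
  stopifnot(length(depth) == length(frac), length(depth) >= 2)
  if (any(diff(depth) <= 0)) stop("depth must be strictly increasing", call. = FALSE)
  if (any(diff(frac) > 0)) stop("irradiance fraction must be non-increasing", call. = FALSE)
  if (abs(frac[1] - 1) > 1e-8) stop("profile must start at 1 at the surface", call. = FALSE)
  eu <- interp_crossing(depth, frac, 1e-3)
  tw <- interp_crossing(depth, frac, 1e-6)
  list(euphotic_bottom = eu, twilight_bottom = tw,
       euphotic_open = is.na(eu), twilight_open = is.na(tw))
}

# log-linear interpolation of the depth where frac first reaches `level`
interp_crossing <- function(depth, frac, level) {
  if (min(frac) > level) return(NA_real_)
  i <- which(frac <= level)[1]
  if (frac[i] == level || i == 1) return(depth[i])
  lf <- log(frac)
  depth[i - 1] + (log(level) - lf[i - 1]) * (depth[i] - depth[i - 1]) / (lf[i] - lf[i - 1])
}

check_same_shape <- function(a, b) {
  name_a <- deparse(substitute(a)); name_b <- deparse(substitute(b))
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop(sprintf("'%s' and '%s' must share shape", name_a, name_b), call. = FALSE)
  }
  invisible(TRUE)
}
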