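#' Noise and drift statistics of a preindustrial control series
#'
#' Fits an ordinary least-squares line to the full control series and
#' measures noise as the standard deviation of the residuals, i.e. the raw
#' interannual variability of the control after removing its own linear
#' drift and mean. No smoothing is applied to the noise estimate.
#'
#' @param values Annual-mean control values.
#' @param years Matching consecutive years (length >= 30 for a usable noise
#'   estimate).
#' @return An object of class `control_stats` with fields `slope`
#'   (units yr-1), `mean`, `sd` (detrended interannual SD), `ref_year`
#'   (centering year of the fit) and `n`.
#' @export
control_stats <- function(values, years) {
  stopifnot(length(values) == length(years))
  if (length(values) < 30) stop("control series must have >= 30 years", call. = FALSE)
  if (any(diff(years) != 1)) stop("years must be consecutive", call. = FALSE)
  st <- column_control_stats(matrix(values, ncol = 1), years)
  scale <- max(abs(values), .Machine$double.xmin)
  if (is.na(st$sd[1]) || st$sd[1] / scale < 1e-12) {
    stop("control series is constant or noise-free; noise SD must be > 0", call. = FALSE)
  }
  structure(list(slope = st$slope[1], mean = st$mean[1], sd = st$sd[1],
                 ref_year = st$ref_year, n = length(values)),
            class = "control_stats")
}

# vectorized per-column OLS line + residual SD; years centered on their mean
column_control_stats <- function(m, years) {
  t_c <- years - mean(years)
  sxx <- sum(t_c^2)
  mu <- colMeans(m)
  slope <- as.vector(crossprod(m, t_c)) / sxx
  resid <- m - outer(rep(1, length(years)), mu) - outer(t_c, slope)
  sd <- sqrt(colSums(resid^2) / (length(years) - 1))
  list(slope = slope, mean = mu, sd = sd, ref_year = mean(years))
}

#' Anomaly relative to the control's linear baseline
#'
#' Removes the control's mean and linear drift from a series:
#' `value - mean - slope * (year - ref_year)`. A control series processed
#' with its own statistics varies about zero; forced scenarios deviate from
#' zero as their trends develop.
#'
#' @param values Series values (control or scenario).
#' @param years Matching years.
#' @param stats A [control_stats()] object from the matching cell/variable.
#' @return Anomaly series, same length as `values`.
#' @export
toe_anomaly <- function(values, years, stats) {
  stopifnot(inherits(stats, "control_stats"), length(values) == length(years))
  values - stats$mean - stats$slope * (years - stats$ref_year)
}

#' Centered boxcar moving average
#'
#' Flat moving average with an odd window. At the series edges the window
#' shrinks symmetrically to the available points (minimum 1), so the output
#' has the same length as the input and the final years remain defined,
#' which the emergence persistence rule requires.
#'
#' @param x Numeric vector (or matrix smoothed column-wise).
#' @param window Odd window length in years (default 11).
#' @return Smoothed series, same shape as `x`.
#' @export
boxcar_smooth <- function(x, window = 11) {
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1", call. = FALSE)
  m <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(m)
  h <- (window - 1) / 2
  cs <- rbind(0, apply(m, 2, cumsum))
  out <- m
  for (i in seq_len(n)) {
    hi <- min(h, i - 1, n - i)
    out[i, ] <- (cs[i + hi + 1, ] - cs[i - hi, ]) / (2 * hi + 1)
  }
  if (is.matrix(x)) out else as.vector(out)
}

#' Time of emergence of a smoothed anomaly series
#'
#' Returns the first year from which the absolute anomaly exceeds
#' `k` standard deviations of control noise in every year through the end
#' of the series. Excursions that fall back inside the envelope before the
#' final year are rejected, making the estimate conservative.
#'
#' @param anomaly Smoothed anomaly series (see [boxcar_smooth()]).
#' @param years Matching years.
#' @param noise_sd Interannual control noise SD (see [control_stats()]).
#' @param k Envelope multiplier (default 2, the ~95 % confidence envelope).
#' @return The emergence year, or `NA` if the signal never emerges.
#' @export
toe_year <- function(anomaly, years, noise_sd, k = 2) {
  stopifnot(length(anomaly) == length(years), k > 0, noise_sd >= 0)
  idx <- toe_index(matrix(abs(anomaly) > k * noise_sd, ncol = 1))
  if (is.na(idx)) NA_integer_ else as.integer(years[idx])
}

# per column: first row index from which `exceed` is TRUE through the end;
# suffix-AND is TRUE only on the final contiguous run, so its count gives the
# run length directly
toe_index <- function(exceed) {
  n <- nrow(exceed)
  suffix <- apply(exceed[n:1, , drop = FALSE], 2, cumprod)
  tail_run <- colSums(suffix)
  idx <- n - as.integer(tail_run) + 1L
  idx[tail_run == 0] <- NA_integer_
  idx
}

#' Per-cell Time-of-Emergence map
#'
#' Applies the full detection chain -- control statistics, anomaly,
#' boxcar smoothing, persistent exceedance -- to every grid cell of a
#' scenario run against its control.
#'
#' @param scenario,control [annual_grid()] objects on the same geometry;
#'   the control must span >= 30 years.
#' @param k Envelope multiplier (default 2).
#' @param window Boxcar window in years (default 11).
#' @return An object of class `toe_map`: a list with `toe` (integer matrix
#'   `[nlat, nlon]` of emergence years, `NA` = never emerged), `missing`
#'   (logical matrix; cells with non-finite data), `lat`, `lon`, `weights`
#'   (cos-latitude), `k`, `window` and `end_year`.
#' @export
toe_map <- function(scenario, control, k = 2, window = 11) {
  stopifnot(inherits(scenario, "annual_grid"), inherits(control, "annual_grid"))
  if (!same_geometry(scenario, control)) {
    stop("scenario and control grids must share geometry", call. = FALSE)
  }
  ctl <- grid_as_matrix(control)
  scn <- grid_as_matrix(scenario)
  missing_cell <- apply(!is.finite(ctl), 2, any) | apply(!is.finite(scn), 2, any)
  st <- column_control_stats(ctl, control$years)
  anom <- scn - outer(rep(1, length(scenario$years)), st$mean) -
    outer(scenario$years - st$ref_year, st$slope)
  sm <- boxcar_smooth(anom, window)
  exceed <- abs(sm) > outer(rep(1, nrow(sm)), k * st$sd)
  exceed[, missing_cell | st$sd == 0] <- FALSE
  idx <- toe_index(exceed)
  toe <- matrix(scenario$years[idx], nrow = length(scenario$lat))
  missing <- matrix(missing_cell, nrow = length(scenario$lat))
  toe[missing] <- NA_integer_
  structure(list(toe = toe, missing = missing, lat = scenario$lat,
                 lon = scenario$lon, weights = area_weights(scenario),
                 k = k, window = window, end_year = max(scenario$years)),
            class = "toe_map")
}

#' @export
print.toe_map <- function(x, ...) {
  n_ok <- sum(!x$missing)
  cat(sprintf("toe_map: %d x %d cells (%d usable), k = %g, window = %d yr, end %d\n",
              nrow(x$toe), ncol(x$toe), n_ok, x$k, x$window, x$end_year))
  cat(sprintf("  emerged cells: %d (%.1f%% unweighted)\n",
              sum(!is.na(x$toe)), 100 * sum(!is.na(x$toe)) / max(1, n_ok)))
  invisible(x)
}

#' Area fraction of a region with emergent trends
#'
#' Cos-latitude-weighted percentage of usable region cells whose emergence
#' year is at or before each requested year. Monotone non-decreasing in
#' `by_year`.
#'
#' @param toe A [toe_map()].
#' @param by_year Year(s) at which to evaluate the emerged fraction.
#' @param region Latitude band `c(south, north)` in degrees; default the
#'   low-latitude ocean 45S-45N.
#' @return Percentages (0-100), same length as `by_year`.
#' @export
emerged_fraction <- function(toe, by_year, region = c(-45, 45)) {
  stopifnot(inherits(toe, "toe_map"), length(region) == 2)
  in_band <- toe$lat >= region[1] & toe$lat <= region[2]
  use <- outer(in_band, rep(TRUE, length(toe$lon))) & !toe$missing
  total <- sum(toe$weights[use])
  if (total <= 0) stop("region contains no usable cells", call. = FALSE)
  vapply(by_year, function(y) {
    em <- use & !is.na(toe$toe) & toe$toe <= y
    100 * sum(toe$weights[em]) / total
  }, numeric(1))
}

#' Spearman pattern agreement between two fields
#'
#' Pixel-by-pixel Spearman rank correlation over cells that are finite in
#' both fields (average ranks for ties), the non-parametric measure used to
#' compare 2-D response patterns between experiments.
#'
#' @param field_a,field_b Numeric matrices (or [annual_grid()] single-year
#'   slices) on the same geometry.
#' @return Spearman's rank correlation coefficient.
#' @export
pattern_agreement <- function(field_a, field_b) {
  a <- if (inherits(field_a, "annual_grid")) grid_as_matrix(field_a) else field_a
  b <- if (inherits(field_b, "annual_grid")) grid_as_matrix(field_b) else field_b
  check_same_shape(a, b)
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need at least 3 common unmasked cells", call. = FALSE)
  stats::cor(as.vector(a[ok]), as.vector(b[ok]), method = "spearman")
}
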