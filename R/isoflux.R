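#' Per-cell biogeochemical nitrate flux fields
#'
#' Container for the six flux components entering the offline nitrate
#' isotope tendency diagnostic: the nitrification source and the
#' new-production and denitrification sinks, each split into a light
#' (total nitrogen) and an enrichment-weighted heavy component. The heavy
#' component of nitrification carries implicitly whatever isotopic
#' signature upstream remineralization, excretion and nitrogen fixation
#' imprinted on the ammonium pool; no fractionation is applied here.
#'
#' @param nitr14,nitr15,new14,new15,den14,den15 Non-negative flux magnitude
#'   matrices (mmol N m-3 yr-1), all the same shape.
#' @return An object of class `flux_fields`.
#' @export
flux_fields <- function(nitr14, nitr15, new14, new15, den14, den15) {
  fl <- list(nitr14 = as.matrix(nitr14), nitr15 = as.matrix(nitr15),
             new14 = as.matrix(new14), new15 = as.matrix(new15),
             den14 = as.matrix(den14), den15 = as.matrix(den15))
  d <- dim(fl$nitr14)
  for (nm in names(fl)) {
    if (!identical(dim(fl[[nm]]), d)) stop("all six flux fields must share shape", call. = FALSE)
    if (any(fl[[nm]] < 0, na.rm = TRUE)) {
      stop(sprintf("flux magnitudes must be >= 0 ('%s')", nm), call. = FALSE)
    }
  }
  structure(fl, class = "flux_fields")
}

#' @export
print.flux_fields <- function(x, ...) {
  cat(sprintf("flux_fields: %d x %d cells; gross light flux %.3g-%.3g\n",
              nrow(x$nitr14), ncol(x$nitr14),
              min(x$nitr14 + x$new14 + x$den14), max(x$nitr14 + x$new14 + x$den14)))
  invisible(x)
}

#' Biogeochemical tendency of nitrate delta15N
#'
#' The within-cell, circulation-free tendency of nitrate delta15N implied
#' by the balance of biogeochemical sources and sinks: the per-mil
#' signature of the net flux, `((15nitr - 15new - 15den) / (14nitr - 14new
#' - 14den) - 1) * 1000`. Only fluxes local to each cell enter; upstream
#' biological changes and circulation are excluded by construction.
#'
#' The ratio is numerically meaningless where the light-isotope net flux is
#' near zero, and unphysical where numerator and denominator have opposite
#' signs (that would imply negative isotope abundance); such cells are
#' masked with a diagnostic flag, never clipped.
#'
#' @param fluxes A [flux_fields()] object.
#' @param tol Absolute tolerance on the light net flux below which a cell is
#'   masked. Default `1e-6` of the cell's gross light flux (sum of the
#'   three magnitudes).
#' @return Per-mil tendency matrix with `NA` at masked cells; attribute
#'   `"flag"` holds an integer matrix (0 = valid, 1 = near-zero net light
#'   flux, 2 = unphysical sign combination).
#' @export
biogeochem_delta_tendency <- function(fluxes, tol = NULL) {
  stopifnot(inherits(fluxes, "flux_fields"))
  net15 <- fluxes$nitr15 - fluxes$new15 - fluxes$den15
  net14 <- fluxes$nitr14 - fluxes$new14 - fluxes$den14
  gross <- fluxes$nitr14 + fluxes$new14 + fluxes$den14
  if (is.null(tol)) tol <- 1e-6 * gross
  stopifnot(all(tol >= 0))
  flag <- matrix(0L, nrow(net14), ncol(net14))
  flag[abs(net14) < tol | gross == 0] <- 1L
  flag[flag == 0L & (net15 / net14 < 0)] <- 2L
  out <- (net15 / net14 - 1) * 1000
  out[flag != 0L] <- NA_real_
  attr(out, "flag") <- flag
  out
}

#' Change in the biogeochemical delta15N tendency between runs
#'
#' Difference of [biogeochem_delta_tendency()] between a scenario and a
#' reference flux state, masked wherever either side is masked. This is the
#' quantity that isolates climate-driven biogeochemical effects on nitrate
#' delta15N from circulation effects.
#'
#' @param scenario,reference [flux_fields()] on the same geometry.
#' @param tol Passed to [biogeochem_delta_tendency()].
#' @return Per-mil change matrix with combined `"flag"` attribute (the
#'   element-wise maximum of the two sides' flags).
#' @export
tendency_change <- function(scenario, reference, tol = NULL) {
  a <- biogeochem_delta_tendency(scenario, tol)
  b <- biogeochem_delta_tendency(reference, tol)
  check_same_shape(a, b)
  out <- a - b
  attr(out, "flag") <- pmax(attr(a, "flag"), attr(b, "flag"))
  out
}
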