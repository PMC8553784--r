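#' Annual-mean gridded tracer field
#'
#' A light container for (year, lat, lon) annual-mean fields, the working
#' currency of the emergence detector. Values are stored as a 3-D array with
#' the year axis first; latitude and longitude are cell-center coordinates
#' in degrees.
#'
#' @param values Numeric array `[nyear, nlat, nlon]`.
#' @param years Consecutive integer years, length `nyear`.
#' @param lat,lon Cell-center coordinates (degrees), lengths `nlat`, `nlon`.
#' @param var Variable name (free text, e.g. `"d15N_NO3"`).
#' @param units Units string recorded as metadata (e.g. `"permil"`).
#' @param role `"control"` or `"scenario"`.
#' @return An object of class `annual_grid`.
#' @export
annual_grid <- function(values, years, lat, lon, var = "tracer",
                        units = "", role = c("control", "scenario")) {
  role <- match.arg(role)
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("values must be a [year, lat, lon] array", call. = FALSE)
  years <- as.integer(years)
  if (any(diff(years) != 1L)) stop("years must be consecutive integers", call. = FALSE)
  if (!identical(dim(values), c(length(years), length(lat), length(lon)))) {
    stop("dim(values) must match (length(years), length(lat), length(lon))", call. = FALSE)
  }
  structure(list(values = values, years = years, lat = as.numeric(lat),
                 lon = as.numeric(lon), var = var, units = units, role = role),
            class = "annual_grid")
}

#' @export
print.annual_grid <- function(x, ...) {
  cat(sprintf("annual_grid '%s' [%s]: %d years (%d-%d), %d x %d cells, role = %s\n",
              x$var, x$units, length(x$years), min(x$years), max(x$years),
              length(x$lat), length(x$lon), x$role))
  invisible(x)
}

# grid geometry equality used by multi-grid operations
same_geometry <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon))
}

# flatten the spatial axes: years x (nlat*nlon) matrix, cells in lat-major order
grid_as_matrix <- function(g) {
  matrix(g$values, nrow = length(g$years))
}

#' Cosine-latitude area weights of a grid
#'
#' Relative cell areas for a regular lat-lon grid, proportional to
#' `cos(lat)` and constant in longitude.
#'
#' @param grid An [annual_grid()] or anything with `lat`/`lon` fields.
#' @return Matrix `[nlat, nlon]` of non-negative weights.
#' @export
area_weights <- function(grid) {
  w <- cos(grid$lat * pi / 180)
  w[w < 0] <- 0
  matrix(rep(w, times = length(grid$lon)), nrow = length(grid$lat))
}

#' Write an annual grid as long-format CSV
#'
#' One row per (year, lat, lon) cell with a `# var:units:role` header
#' comment, readable back with [read_annual_grid()]. Plain text keeps runs
#' self-describing and diff-able.
#'
#' @param grid An [annual_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annual_grid <- function(grid, path) {
  stopifnot(inherits(grid, "annual_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# isotoe annual_grid var=%s units=%s role=%s",
                     grid$var, grid$units, grid$role), con)
  df <- expand.grid(year = grid$years, lat = grid$lat, lon = grid$lon,
                    KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(grid$values)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an annual grid written by [write_annual_grid()]
#'
#' @param path CSV file path.
#' @return An [annual_grid()].
#' @export
read_annual_grid <- function(path) {
  header <- readLines(path, n = 1)
  meta <- c(var = "tracer", units = "", role = "control")
  if (startsWith(header, "#")) {
    for (nm in names(meta)) {
      m <- regmatches(header, regexpr(sprintf("%s=[^ ]*", nm), header))
      if (length(m)) meta[[nm]] <- sub(sprintf("%s=", nm), "", m)
    }
  }
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("year", "lat", "lon", "value") %in% names(df)))
  years <- sort(unique(df$year)); lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  df <- df[order(df$lon, df$lat, df$year), ]
  values <- array(df$value, dim = c(length(years), length(lat), length(lon)))
  annual_grid(values, years, lat, lon, var = meta[["var"]],
              units = meta[["units"]], role = meta[["role"]])
}
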