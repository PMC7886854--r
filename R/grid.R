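#' Regular longitude/latitude analysis grid
#'
#' Builds a regular lon/lat grid with cell-centre registration.  Cells are
#' indexed `1..nx*ny` with longitude varying fastest; cell `k` covers the
#' half-open box `[west, east) x [south, north)` so that every point in the
#' extent belongs to exactly one cell.
#'
#' @param lon_min,lon_max,lat_min,lat_max grid extent in decimal degrees.
#' @param resolution cell size in degrees (default 0.1).
#' @return an object of class `world_grid` with elements `nx`, `ny`,
#'   `lon` (cell-centre longitudes, length `nx`), `lat` (length `ny`),
#'   `resolution` and the extent.
#' @examples
#' g <- world_grid(0, 3, 0, 2, resolution = 1)
#' g$nx * g$ny        # 6 cells
#' grid_coords(g)[1, ] # first centre at (0.5, 0.5)
#' @export
world_grid <- function(lon_min, lon_max, lat_min, lat_max, resolution = 0.1) {
  stopifnot_scalar_number(resolution, "resolution", positive = TRUE)
  for (v in c("lon_min", "lon_max", "lat_min", "lat_max"))
    stopifnot_scalar_number(get(v), v)
  if (lon_max <= lon_min || lat_max <= lat_min)
    stop("grid extent is empty: require lon_max > lon_min and lat_max > lat_min")
  nx <- (lon_max - lon_min) / resolution
  ny <- (lat_max - lat_min) / resolution
  if (abs(nx - round(nx)) > 1e-6 || abs(ny - round(ny)) > 1e-6)
    stop("resolution does not divide the grid extent")
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  structure(list(
    lon_min = lon_min, lon_max = lon_max,
    lat_min = lat_min, lat_max = lat_max,
    resolution = resolution, nx = nx, ny = ny,
    lon = lon_min + (seq_len(nx) - 0.5) * resolution,
    lat = lat_min + (seq_len(ny) - 0.5) * resolution
  ), class = "world_grid")
}

#' @export
print.world_grid <- function(x, ...) {
  cat(sprintf("<world_grid> %dx%d cells at %g deg, lon [%g, %g], lat [%g, %g]\n",
              x$nx, x$ny, x$resolution, x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid a `world_grid`.
#' @return integer cell count.
#' @export
n_cells <- function(grid) grid$nx * grid$ny

#' Cell-centre coordinates
#'
#' @param grid a `world_grid`.
#' @return a data.frame with columns `cell`, `lon`, `lat` in cell-index order.
#' @export
grid_coords <- function(grid) {
  data.frame(cell = seq_len(n_cells(grid)),
             lon = rep(grid$lon, times = grid$ny),
             lat = rep(grid$lat, each = grid$nx))
}

#' Locate points on the grid
#'
#' Assigns lon/lat points to cells using half-open intervals
#' `[west, east) x [south, north)`; points outside the extent get `NA`.
#'
#' @param grid a `world_grid`.
#' @param lon,lat coordinate vectors (degrees).
#' @return integer vector of cell ids (NA outside the extent).
#' @export
locate_cells <- function(grid, lon, lat) {
  ix <- floor((lon - grid$lon_min) / grid$resolution) + 1
  iy <- floor((lat - grid$lat_min) / grid$resolution) + 1
  ok <- ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny
  out <- rep(NA_integer_, length(lon))
  out[ok] <- as.integer((iy[ok] - 1) * grid$nx + ix[ok])
  out
}

same_grid <- function(a, b, tol = 1e-9) {
  is.list(a) && is.list(b) &&
    a$nx == b$nx && a$ny == b$ny &&
    abs(a$lon_min - b$lon_min) < tol && abs(a$lat_min - b$lat_min) < tol &&
    abs(a$resolution - b$resolution) < tol
}
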