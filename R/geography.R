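# Region masks and distributional centroids (range-shift summaries).

#' Build a region mask on a grid
#'
#' Default split between the Mediterranean Sea (cells east of the Strait
#' of Gibraltar, lon > -5.6, within 30--46 N) and the European Atlantic
#' facade (all remaining cells); `"all"` selects the whole grid and
#' `"custom"` takes a user-supplied boolean field.
#'
#' @param grid a `world_grid`.
#' @param region `"atlantic_facade"`, `"mediterranean"`, `"all"` or
#'   `"custom"`.
#' @param custom logical field (length `n_cells(grid)`) for
#'   `region = "custom"`.
#' @param lon_split,lat_range Gibraltar longitude and Mediterranean
#'   latitude band used by the default split.
#' @return an object of class `region_mask`: list with `region` and the
#'   logical field `mask`.
#' @export
region_mask <- function(grid, region = c("atlantic_facade", "mediterranean",
                                         "all", "custom"),
                        custom = NULL, lon_split = -5.6,
                        lat_range = c(30, 46)) {
  region <- match.arg(region)
  co <- grid_coords(grid)
  med <- co$lon > lon_split & co$lat >= lat_range[1] & co$lat <= lat_range[2]
  mask <- switch(region,
    mediterranean = med,
    atlantic_facade = !med,
    all = rep(TRUE, n_cells(grid)),
    custom = {
      if (is.null(custom) || length(custom) != n_cells(grid))
        stop("`custom` must be a logical field on the grid")
      as.logical(custom)
    })
  structure(list(region = region, mask = mask, grid = grid),
            class = "region_mask")
}

#' ESI-weighted distributional centroid
#'
#' The centroid of a potential distribution is the ESI-weighted barycentre
#' of all retained geographical cells in the region:
#' `lon = sum(ESI_c * lon_c) / sum(ESI_c)` (and likewise for latitude).
#' Masked cells contribute nothing; weights normalise out, so the
#' centroid is invariant to uniform rescaling of the ESI.
#'
#' @param map a `suitability_map`.
#' @param mask a `region_mask` on the same grid.
#' @param esi_cutoff optional minimum ESI for a cell to contribute
#'   (default 0 = all retained cells).
#' @param area_weight if `TRUE`, weights are additionally multiplied by
#'   `cos(latitude)` (cell-area weighting; off by default — the centroid
#'   is over cells, not areas).
#' @return an object of class `centroid`: list with `lon`, `lat`,
#'   `region`, `rcp`, `decade`.
#' @export
weighted_centroid <- function(map, mask, esi_cutoff = 0, area_weight = FALSE) {
  if (!same_grid(map$grid, mask$grid)) stop("map and mask grids differ")
  co <- grid_coords(map$grid)
  w <- map$esi
  w[!mask$mask | is.na(w) | w < esi_cutoff] <- 0
  w[is.na(w)] <- 0
  if (area_weight) w <- w * cos(co$lat * pi / 180)
  if (sum(w) <= 0)
    stop("all-zero ESI in region '", mask$region, "'")
  structure(list(lon = sum(w * co$lon) / sum(w),
                 lat = sum(w * co$lat) / sum(w),
                 region = mask$region,
                 rcp = map$scenario$rcp %||% NA_character_,
                 decade = map$decade),
            class = "centroid")
}

#' @export
print.centroid <- function(x, ...) {
  cat(sprintf("<centroid> %s %s/%s: (%.3f E, %.3f N)\n", x$region,
              x$rcp, x$decade, x$lon, x$lat))
  invisible(x)
}

#' Distributional centroid shift
#'
#' Simple coordinate differences between two centroids of the same
#' region; east and north are positive.
#'
#' @param from,to `centroid` objects sharing a region.
#' @return named numeric vector `c(dlon, dlat)` in degrees.
#' @export
centroid_shift <- function(from, to) {
  if (!identical(from$region, to$region))
    stop("centroids belong to different regions ('", from$region,
         "' vs '", to$region, "')")
  c(dlon = to$lon - from$lon, dlat = to$lat - from$lat)
}
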