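# Occurrence cleaning and gridding: raw georeferenced records ->
# unique presence cells on the analysis grid.

#' Clean raw occurrence records
#'
#' Applies, in order: coordinate-range check, grid-extent check, land-mask
#' check, precautionary bathymetry cutoff (records over cells deeper than
#' `depth_cutoff_m` are discarded), flag-based exclusion of unreliable
#' records, and exact-duplicate removal on the key
#' (species, lon, lat, date) after rounding coordinates to 1e-4 degree.
#' Every rejection carries a machine-readable reason; cleaning is
#' idempotent and `nrow(kept) + nrow(rejected) == nrow(records)`.
#'
#' @param records data.frame with columns `species`, `decimalLongitude`,
#'   `decimalLatitude`, and optionally `eventDate`, `source`, `qc_flag`.
#' @param stack `layer_stack` supplying the grid, ocean mask and
#'   `bathymetry` field (positive-down depth in metres).
#' @param depth_cutoff_m precautionary depth threshold (default 1000 m).
#' @param exclude_flags `qc_flag` values to reject as unreliable
#'   (e.g. `"preserved_specimen"`); not inferred, supplied by the caller.
#' @param swap_check if `TRUE`, a record whose cell is on land but whose
#'   lat/lon-swapped position is in an ocean cell is rejected with reason
#'   `"suspect_inversion"` instead of `"on_land"` (heuristic for
#'   coordinate inversion; off by default).
#' @return list with data.frames `kept` and `rejected` (the latter with a
#'   `reason` column).
#' @export
clean_records <- function(records, stack, depth_cutoff_m = 1000,
                          exclude_flags = character(), swap_check = FALSE) {
  stopifnot(inherits(stack, "layer_stack"))
  need <- c("species", "decimalLongitude", "decimalLatitude")
  if (!all(need %in% names(records)))
    stop("`records` must have columns: ", paste(need, collapse = ", "))
  n <- nrow(records)
  lon <- records$decimalLongitude
  lat <- records$decimalLatitude
  reason <- rep(NA_character_, n)

  bad_range <- !is.finite(lon) | !is.finite(lat) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90
  reason[bad_range] <- "coordinates_out_of_range"

  cell <- locate_cells(stack$grid, lon, lat)
  outside <- is.na(reason) & is.na(cell)
  reason[outside] <- "outside_grid"

  on_land <- is.na(reason) & !stack$ocean[cell]
  if (swap_check && any(on_land)) {
    swapped <- locate_cells(stack$grid, lat, lon)
    inverted <- on_land & !is.na(swapped) & stack$ocean[pmax(swapped, 1L)]
    reason[inverted] <- "suspect_inversion"
    on_land <- on_land & !inverted
  }
  reason[on_land] <- "on_land"

  ok <- is.na(reason)
  depth <- stack$factors$bathymetry[cell[ok]]
  if (any(is.na(depth)))
    stop("missing bathymetry for ", sum(is.na(depth)), " ocean record cell(s)")
  too_deep <- ok
  too_deep[ok] <- depth > depth_cutoff_m
  reason[too_deep] <- "too_deep"

  if (length(exclude_flags) && "qc_flag" %in% names(records)) {
    unreliable <- is.na(reason) & records$qc_flag %in% exclude_flags
    reason[unreliable] <- "unreliable"
  }

  date <- if ("eventDate" %in% names(records)) as.character(records$eventDate)
          else rep(NA_character_, n)
  key <- paste(records$species, round(lon, 4), round(lat, 4), date, sep = "|")
  dup <- is.na(reason) & duplicated(replace(key, !is.na(reason), NA))
  reason[dup] <- "duplicate"

  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Aggregate cleaned records to presence cells
#'
#' One presence per occupied grid cell regardless of the number of records
#' in it; per-cell and per-source counts are preserved as provenance.
#' Cell membership uses half-open intervals `[west, east) x [south, north)`.
#'
#' @param kept cleaned records (see [clean_records()]).
#' @param grid a `world_grid`.
#' @return an object of class `occurrence_set` with elements `species`,
#'   `cells` (sorted unique cell ids), `cell_counts`, `provenance`
#'   (records per source) and `n_records`.
#' @export
grid_occurrences <- function(kept, grid) {
  stopifnot(inherits(grid, "world_grid"))
  if (nrow(kept) == 0) stop("no records to grid")
  cell <- locate_cells(grid, kept$decimalLongitude, kept$decimalLatitude)
  if (any(is.na(cell)))
    stop(sum(is.na(cell)), " record(s) fall outside the grid extent")
  counts <- table(cell)
  species <- unique(as.character(kept$species))
  if (length(species) != 1)
    stop("records must belong to a single species; got ",
         paste(species, collapse = ", "))
  prov <- if ("source" %in% names(kept)) table(as.character(kept$source))
          else table(rep("unknown", nrow(kept)))
  structure(list(species = species,
                 cells = as.integer(names(counts)),
                 cell_counts = as.integer(counts),
                 provenance = prov,
                 n_records = nrow(kept)),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d presence cells from %d records\n",
              x$species, length(x$cells), x$n_records))
  invisible(x)
}

#' Write / read occurrence records as CSV
#'
#' Column order follows the DarwinCore-like convention
#' `species, decimalLongitude, decimalLatitude, eventDate, source`.
#'
#' @param records occurrence data.frame.
#' @param path file path.
#' @param header optional provenance comment line(s) written before the CSV.
#' @return `path` invisibly (write) or a data.frame (read).
#' @export
write_occurrences_csv <- function(records, path, header = NULL) {
  cols <- intersect(c("species", "decimalLongitude", "decimalLatitude",
                      "eventDate", "source", "qc_flag", "reason"),
                    names(records))
  if (!is.null(header)) writeLines(paste0("# ", header), path)
  suppressWarnings(utils::write.table(records[cols], path, sep = ",",
                                      row.names = FALSE, quote = FALSE,
                                      append = !is.null(header)))
  invisible(path)
}

#' @rdname write_occurrences_csv
#' @export
read_occurrences_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
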