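# Aligned environmental predictor stack: container, thermal indices,
# bilinear regridding, collinearity screening and permutation importance.

#' Aligned environmental layer stack
#'
#' Container for environmental fields on a common grid.  Fields are numeric
#' vectors in cell-index order; land cells carry `NA`.
#'
#' @param grid a `world_grid`.
#' @param factors named list of numeric fields (each of length
#'   `n_cells(grid)`); canonical names include `SBT`, `SBTrange`, `SBTvar`,
#'   `SSS`, `bathymetry` (positive-down depth, m) and `dist_to_coast` (km).
#' @param ocean logical ocean mask (TRUE = ocean).
#' @param period period label, e.g. `"contemporary"` or a decade.
#' @param monthly_sbt optional array `n_cells x 12 x n_years` of monthly SBT.
#' @param scenario optional list with `gcm`, `rcp`, `decade` labels.
#' @return an object of class `layer_stack`.
#' @export
layer_stack <- function(grid, factors, ocean, period = "contemporary",
                        monthly_sbt = NULL, scenario = NULL) {
  stopifnot(inherits(grid, "world_grid"), is.list(factors))
  nc <- n_cells(grid)
  for (f in names(factors)) {
    if (length(factors[[f]]) != nc)
      stop("factor '", f, "' does not match the grid (", nc, " cells)")
  }
  if (length(ocean) != nc || !is.logical(ocean))
    stop("`ocean` must be a logical mask on the grid")
  if (!is.null(factors$SBTrange) && any(factors$SBTrange < -1e-9, na.rm = TRUE))
    stop("SBTrange must be non-negative")
  if (!is.null(factors$SBTvar) && any(factors$SBTvar < -1e-9, na.rm = TRUE))
    stop("SBTvar must be non-negative")
  structure(list(grid = grid, factors = factors, ocean = ocean,
                 period = period, monthly_sbt = monthly_sbt,
                 scenario = scenario),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> period '%s': %s on %dx%d grid (%d ocean cells)\n",
              x$period, paste(names(x$factors), collapse = ", "),
              x$grid$nx, x$grid$ny, sum(x$ocean)))
  invisible(x)
}

#' Extract factor values at cells
#'
#' @param stack a `layer_stack`.
#' @param factors character vector of factor names.
#' @param cells integer cell ids (default: all cells).
#' @return data.frame of factor values (rows in `cells` order).
#' @export
stack_values <- function(stack, factors, cells = NULL) {
  missing <- setdiff(factors, names(stack$factors))
  if (length(missing))
    stop("stack lacks factor field(s): ", paste(missing, collapse = ", "))
  cells <- cells %||% seq_len(n_cells(stack$grid))
  out <- lapply(stack$factors[factors], function(v) v[cells])
  as.data.frame(out, col.names = factors)
}

ocean_cells <- function(stack) which(stack$ocean)

#' Derive thermal indices from monthly SBT
#'
#' Per year and cell: the annual mean, the range (warmest-month minus
#' coldest-month SBT) and the inter-month variance across the 12 months;
#' each index is then averaged across years.
#'
#' @param monthly_sbt array `n_cells x 12 x n_years` (a `n_cells x 12`
#'   matrix is treated as one year).  Cells that are all-`NA` (land) yield
#'   `NA`; partially missing months are an error.
#' @return list with numeric fields `SBT`, `SBTrange`, `SBTvar`.
#' @examples
#' m <- matrix(5:16, nrow = 1)             # one cell, months 5..16 deg C
#' derive_thermal_indices(m)$SBTrange      # 11
#' @export
derive_thermal_indices <- function(monthly_sbt) {
  if (is.matrix(monthly_sbt))
    monthly_sbt <- array(monthly_sbt, dim = c(dim(monthly_sbt), 1L))
  d <- dim(monthly_sbt)
  if (length(d) != 3L || d[2] != 12L)
    stop("`monthly_sbt` must be an n_cells x 12 x n_years array")
  nc <- d[1]; ny <- d[3]
  mean_y <- range_y <- var_y <- matrix(NA_real_, nc, ny)
  for (y in seq_len(ny)) {
    m <- monthly_sbt[, , y, drop = TRUE]
    if (ny == 1L && nc == 1L) m <- matrix(m, nrow = 1L)
    if (is.null(dim(m))) m <- matrix(m, nrow = nc)
    n_na <- rowSums(is.na(m))
    if (any(n_na > 0 & n_na < 12))
      stop("cells with partially missing months in year ", y)
    mean_y[, y] <- rowMeans(m)
    range_y[, y] <- apply(m, 1, max) - apply(m, 1, min)
    var_y[, y] <- apply(m, 1, stats::var)
  }
  list(SBT = rowMeans(mean_y), SBTrange = rowMeans(range_y),
       SBTvar = rowMeans(var_y))
}

#' Bilinear regridding of a field
#'
#' Interpolates linearly in longitude and latitude from the four source
#' cell centres surrounding each target centre.  Target centres within the
#' half-cell margin outside the outermost source centres (but inside the
#' source extent) use edge clamping; if any of the four corner values is
#' `NA` (land), the nearest valid corner is used instead (nearest-valid-
#' neighbour fallback); all four `NA` yields `NA`.
#'
#' @param field numeric field on `source_grid` (cell-index order).
#' @param source_grid,target_grid `world_grid` objects; the target extent
#'   must lie within the source extent.
#' @return numeric field on `target_grid`.
#' @export
regrid_bilinear <- function(field, source_grid, target_grid) {
  if (length(field) != n_cells(source_grid))
    stop("`field` does not match `source_grid`")
  if (target_grid$lon_min < source_grid$lon_min - 1e-9 ||
      target_grid$lon_max > source_grid$lon_max + 1e-9 ||
      target_grid$lat_min < source_grid$lat_min - 1e-9 ||
      target_grid$lat_max > source_grid$lat_max + 1e-9)
    stop("target grid extends outside the source coverage")
  co <- grid_coords(target_grid)
  # fractional position in source cell-centre coordinates
  gx <- (co$lon - source_grid$lon[1]) / source_grid$resolution + 1
  gy <- (co$lat - source_grid$lat[1]) / source_grid$resolution + 1
  i0 <- pmin(pmax(floor(gx), 1L), source_grid$nx - 1L)
  j0 <- pmin(pmax(floor(gy), 1L), source_grid$ny - 1L)
  if (source_grid$nx == 1L) i0 <- rep(1L, nrow(co))
  if (source_grid$ny == 1L) j0 <- rep(1L, nrow(co))
  tx <- pmin(pmax(gx - i0, 0), 1)
  ty <- pmin(pmax(gy - j0, 0), 1)
  i1 <- pmin(i0 + 1L, source_grid$nx)
  j1 <- pmin(j0 + 1L, source_grid$ny)
  idx <- function(i, j) (j - 1L) * source_grid$nx + i
  v00 <- field[idx(i0, j0)]; v10 <- field[idx(i1, j0)]
  v01 <- field[idx(i0, j1)]; v11 <- field[idx(i1, j1)]
  w00 <- (1 - tx) * (1 - ty); w10 <- tx * (1 - ty)
  w01 <- (1 - tx) * ty;       w11 <- tx * ty
  out <- w00 * v00 + w10 * v10 + w01 * v01 + w11 * v11
  # nearest valid corner fallback where some corners are NA
  bad <- is.na(out) & !(is.na(v00) & is.na(v10) & is.na(v01) & is.na(v11))
  if (any(bad)) {
    vals <- cbind(v00, v10, v01, v11)[bad, , drop = FALSE]
    dist <- cbind(w00, w10, w01, w11)[bad, , drop = FALSE]
    dist[is.na(vals)] <- -Inf  # exclude NA corners; pick largest weight
    pick <- max.col(dist, ties.method = "first")
    out[bad] <- vals[cbind(seq_len(nrow(vals)), pick)]
  }
  out
}

#' Collinearity screen over presence-cell values
#'
#' Computes pairwise Pearson correlations of candidate factors over the
#' presence cells only, groups factors into components of the
#' `|r| > threshold` graph, and keeps a single factor per component: SBT
#' always survives as the keeper of its own component; other components
#' keep their most important member by [permutation_importance()] of an
#' NPPEN model fitted on all candidates.
#'
#' @param stack a `layer_stack`.
#' @param presence_cells integer ids of presence cells (>= 3).
#' @param threshold absolute-correlation threshold (default 0.7).
#' @param candidates candidate factor names (default the four niche
#'   predictors `SBT`, `SBTrange`, `SBTvar`, `SSS`).
#' @param importance optional named importance vector overriding the
#'   NPPEN-based ranking.
#' @param seed seed for the permutation importance.
#' @return character vector of retained factor names (in candidate order).
#' @export
collinearity_screen <- function(stack, presence_cells, threshold = 0.7,
                                candidates = c("SBT", "SBTrange", "SBTvar", "SSS"),
                                importance = NULL, seed = 1) {
  if (length(presence_cells) < 3) stop("need >= 3 presence cells")
  if (!"SBT" %in% candidates) stop("`candidates` must contain SBT")
  vals <- stack_values(stack, candidates, presence_cells)
  sds <- vapply(vals, stats::sd, numeric(1))
  if (any(!is.finite(sds) | sds == 0))
    stop("zero-variance factor(s) over presence cells: ",
         paste(candidates[!is.finite(sds) | sds == 0], collapse = ", "))
  r <- abs(stats::cor(vals))
  adj <- r > threshold; diag(adj) <- FALSE
  # connected components by BFS
  comp <- rep(NA_integer_, length(candidates)); k <- 0L
  for (i in seq_along(candidates)) {
    if (!is.na(comp[i])) next
    k <- k + 1L; queue <- i
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[j])) next
      comp[j] <- k
      queue <- c(queue, which(adj[j, ] & is.na(comp)))
    }
  }
  if (is.null(importance)) {
    model <- fit_nppen(vals)
    importance <- vapply(candidates, function(f)
      permutation_importance(model, stack, f, seed = derive_seed(seed, f)),
      numeric(1))
    names(importance) <- candidates
  }
  keep <- logical(length(candidates))
  sbt_comp <- comp[candidates == "SBT"]
  for (g in unique(comp)) {
    members <- which(comp == g)
    if (g == sbt_comp) keep[candidates == "SBT"] <- TRUE
    else {
      imp <- importance[candidates[members]]
      keep[members[which.max(imp)]] <- TRUE
    }
  }
  candidates[keep]
}

#' Permutation importance of an environmental factor
#'
#' Importance is `1 - mean Pearson r` between the reference ESI map (over
#' ocean cells) and ESI maps recomputed with the factor's values permuted
#' across ocean cells.  A factor the model ignores scores ~0; the sole
#' factor of a single-factor model scores close to 1.
#'
#' @param model a fitted model with a [predict_esi()] method (NPPEN model,
#'   classifier member or ensemble).
#' @param stack a `layer_stack` providing all model factors.
#' @param factor factor name to permute.
#' @param n_perm number of permutations (default 10).
#' @param seed integer seed.
#' @return importance in `[0, 1]`.
#' @export
permutation_importance <- function(model, stack, factor, n_perm = 10, seed = 1) {
  fs <- model_factors(model)
  if (!factor %in% fs)
    stop("factor '", factor, "' is not in the model's factor set")
  oc <- ocean_cells(stack)
  env <- stack_values(stack, fs, oc)
  ref <- predict_esi(model, env)
  rs <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- env
    p[[factor]] <- sample(p[[factor]])
    perm <- predict_esi(model, p)
    if (stats::sd(perm) == 0 || stats::sd(ref) == 0) return(1)
    stats::cor(ref, perm)
  }, numeric(1)))
  min(max(1 - mean(rs), 0), 1)
}

#' Candidate factor combinations to test in the models
#'
#' The parsimonious candidate sets: SBT alone, SBT with either SBTrange or
#' SBTvar, and each of those with SSS as a supplementary factor —
#' restricted to factors that survived the collinearity screen.
#'
#' @param retained factor names retained by [collinearity_screen()].
#' @return list of character vectors, each containing SBT.
#' @export
candidate_factor_sets <- function(retained = c("SBT", "SBTrange", "SSS")) {
  if (!"SBT" %in% retained) stop("`retained` must contain SBT")
  base <- list("SBT")
  if ("SBTrange" %in% retained) base <- c(base, list(c("SBT", "SBTrange")))
  if ("SBTvar" %in% retained) base <- c(base, list(c("SBT", "SBTvar")))
  out <- base
  if ("SSS" %in% retained)
    out <- c(out, lapply(base, function(b) c(b, "SSS")))
  lapply(out, unlist)
}

#' Write / read a layer stack as plain-text CSV
#'
#' Long-format CSV (one row per cell: lon, lat, ocean flag, one column per
#' factor).  Used in place of NetCDF, which has no reader in this
#' installation; attributes `period` and scenario labels travel in a
#' comment header.
#'
#' @param stack a `layer_stack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack_csv <- function(stack, path) {
  co <- grid_coords(stack$grid)
  df <- cbind(co, ocean = stack$ocean, as.data.frame(stack$factors))
  hdr <- sprintf("# ensdm layer_stack period=%s res=%g extent=%g,%g,%g,%g",
                 stack$period, stack$grid$resolution,
                 stack$grid$lon_min, stack$grid$lon_max,
                 stack$grid$lat_min, stack$grid$lat_max)
  if (!is.null(stack$scenario))
    hdr <- paste0(hdr, sprintf(" gcm=%s rcp=%s", stack$scenario$gcm,
                               stack$scenario$rcp))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                      append = TRUE, quote = FALSE))
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  meta <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  ext <- as.numeric(strsplit(meta[["extent"]], ",")[[1]])
  grid <- world_grid(ext[1], ext[2], ext[3], ext[4],
                     resolution = as.numeric(meta[["res"]]))
  df <- utils::read.csv(path, comment.char = "#")
  fac <- setdiff(names(df), c("cell", "lon", "lat", "ocean"))
  scenario <- NULL
  if (!is.na(meta["gcm"]))
    scenario <- list(gcm = meta[["gcm"]], rcp = meta[["rcp"]],
                     decade = meta[["period"]])
  layer_stack(grid, as.list(df[fac]), ocean = df$ocean,
              period = meta[["period"]], scenario = scenario)
}
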