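# Scenario projection: Taylor statistics, delta-change bias correction,
# multi-GCM/RCP suitability projection, hierarchical geographic filtering
# and ESI anomalies.

#' Taylor-diagram statistics between two fields
#'
#' Pearson correlation, standard-deviation ratio (model / observation) and
#' centred root-mean-square difference over the valid (ocean) cells of two
#' aligned fields.
#'
#' @param obs,model numeric fields on the same grid; cells that are `NA`
#'   in either field are ignored.
#' @return list with `r`, `sd_ratio`, `crmsd`, `n`.
#' @export
taylor_stats <- function(obs, model) {
  if (length(obs) != length(model)) stop("fields are not aligned")
  ok <- is.finite(obs) & is.finite(model)
  if (sum(ok) < 2) stop("need at least 2 valid cells")
  o <- obs[ok]; m <- model[ok]
  so <- stats::sd(o); sm <- stats::sd(m)
  r <- if (so == 0 || sm == 0) 1 else stats::cor(o, m)
  crmsd <- sqrt(mean(((m - mean(m)) - (o - mean(o)))^2))
  list(r = r, sd_ratio = if (so == 0) NA_real_ else sm / so,
       crmsd = crmsd, n = sum(ok))
}

#' Delta-change bias correction of a scenario stack
#'
#' Corrects every cell of each GCM field by the difference relative to the
#' corresponding cell of the observation-based contemporary field over the
#' common baseline period:
#' `corrected(cell) = gcm(cell) - (gcm_baseline(cell) - obs_baseline(cell))`.
#' Applied per factor; the corrected baseline is cell-wise identical to
#' the observation baseline, so Taylor statistics on the common period
#' give r = 1, sd ratio = 1 and zero centred RMSD.  Factors held constant
#' in time (SSS) and static fields are restored from the observation
#' baseline.
#'
#' @param gcm_stack scenario `layer_stack` (any decade).
#' @param obs_baseline contemporary observation-based `layer_stack`.
#' @param gcm_baseline the same GCM's baseline-decade `layer_stack`.
#' @param factors factor names to correct (default the SBT family).
#' @param constant_factors factors copied from the observation baseline
#'   (default `"SSS"`, plus the static bathymetry / distance fields).
#' @return corrected `layer_stack`.
#' @export
delta_correct <- function(gcm_stack, obs_baseline, gcm_baseline,
                          factors = c("SBT", "SBTrange", "SBTvar"),
                          constant_factors = "SSS") {
  if (!same_grid(gcm_stack$grid, obs_baseline$grid) ||
      !same_grid(gcm_stack$grid, gcm_baseline$grid))
    stop("stacks are not on the same grid")
  out <- gcm_stack
  for (f in intersect(factors, names(gcm_stack$factors))) {
    delta <- gcm_baseline$factors[[f]] - obs_baseline$factors[[f]]
    if (any(is.na(delta) & gcm_stack$ocean))
      stop("missing baseline cell(s) for factor '", f, "'")
    out$factors[[f]] <- gcm_stack$factors[[f]] - delta
  }
  for (f in intersect(c(constant_factors, "bathymetry", "dist_to_coast"),
                      names(obs_baseline$factors)))
    out$factors[[f]] <- obs_baseline$factors[[f]]
  out
}

#' Project future suitability across GCMs, RCPs and decades
#'
#' For each RCP x decade: the ESI of every GCM's (bias-corrected) stack is
#' computed with [ensemble_predict()] and averaged across GCMs; the SD is
#' pooled over all member x replicate x GCM predictions.
#'
#' @param ensemble an `ensemble_model`.
#' @param scenario_stacks list of corrected `layer_stack`s carrying
#'   `scenario` metadata (`gcm`, `rcp`) and a decade `period`.
#' @return named list of `suitability_map`s, keys `"<rcp>_<decade>"`.
#' @export
project_future <- function(ensemble, scenario_stacks) {
  if (!length(scenario_stacks)) stop("no scenario stacks supplied")
  key_of <- function(s) paste(s$scenario$rcp, s$period, sep = "_")
  keys <- vapply(scenario_stacks, key_of, character(1))
  out <- list()
  for (k in unique(keys)) {
    group <- scenario_stacks[keys == k]
    P <- NULL; grid <- group[[1]]$grid; oc <- ocean_cells(group[[1]])
    for (s in group) {
      env <- stack_values(s, ensemble$factors, oc)
      P <- cbind(P, member_prediction_matrix(ensemble, env))
    }
    nc <- n_cells(grid)
    esi <- sd <- rep(NA_real_, nc)
    esi[oc] <- rowMeans(P)
    sd[oc] <- if (ncol(P) > 1) apply(P, 1, stats::sd) else 0
    out[[k]] <- suitability_map(grid, esi, sd,
                                scenario = list(gcm = "multi-GCM mean",
                                                rcp = group[[1]]$scenario$rcp,
                                                n_gcm = length(group)),
                                decade = group[[1]]$period)
  }
  out
}

#' Hierarchical geographic filter
#'
#' A-posteriori mask on suitability maps: a cell is retained iff its depth
#' is at most `depth_max` (300 m, the commonly observed depth range), or —
#' when the distance-to-coast filter is enabled — it lies within
#' `coast_km` of the coast (so that suitable coastal cells without a
#' continental shelf are kept).  Masked cells become `NA`, not 0.
#'
#' @param map a `suitability_map`.
#' @param stack `layer_stack` providing `bathymetry` and `dist_to_coast`.
#' @param depth_max bathymetry threshold in metres (default 300).
#' @param coast_km distance-to-coast threshold in km (default 50).
#' @param coast_enabled whether the coast filter applies (default FALSE).
#' @return the filtered `suitability_map` (`masked = TRUE`).
#' @export
hierarchical_filter <- function(map, stack, depth_max = 300, coast_km = 50,
                                coast_enabled = FALSE) {
  if (!same_grid(map$grid, stack$grid)) stop("map and stack grids differ")
  depth <- stack$factors$bathymetry
  if (is.null(depth)) stop("stack lacks a bathymetry field")
  keep <- !is.na(depth) & depth <= depth_max
  if (coast_enabled) {
    dist <- stack$factors$dist_to_coast
    if (is.null(dist)) stop("coast filter enabled but no dist_to_coast field")
    keep <- keep | (!is.na(dist) & dist <= coast_km)
  }
  map$esi[!keep] <- NA_real_
  map$sd[!keep] <- NA_real_
  map$masked <- TRUE
  map
}

#' ESI anomaly between two suitability maps
#'
#' `future ESI - contemporary ESI` per retained cell; both maps must share
#' the grid and the mask (same NA pattern).
#'
#' @param future_map,contemporary_map `suitability_map`s.
#' @return numeric anomaly field in `[-1, 1]` (NA on masked cells).
#' @export
anomaly <- function(future_map, contemporary_map) {
  if (!same_grid(future_map$grid, contemporary_map$grid))
    stop("maps are not on the same grid")
  if (!identical(is.na(future_map$esi), is.na(contemporary_map$esi)))
    stop("mask mismatch between the two maps")
  future_map$esi - contemporary_map$esi
}
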