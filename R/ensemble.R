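# Ensemble container and map-scale prediction.

#' Assemble an ensemble model
#'
#' @param members list of fitted members (NPPEN models and/or classifier
#'   members), typically one per retained algorithm x CV replicate; all
#'   must share the same FactorSet.
#' @param factors the shared FactorSet.
#' @param q hull quantile pair used for pseudo-absence selection.
#' @param filters list with `depth_max` (m) and `coast_enabled` /
#'   `coast_km` controlling the hierarchical geographic filter.
#' @param cbi data.frame of per-member CBI metadata (optional).
#' @param member_labels optional labels (e.g. `"GLM_rep3"`).
#' @return an object of class `ensemble_model`.
#' @export
ensemble_model <- function(members, factors, q = c(10, 90),
                           filters = list(depth_max = 300,
                                          coast_enabled = FALSE,
                                          coast_km = 50),
                           cbi = NULL, member_labels = NULL) {
  if (!length(members)) stop("an ensemble needs at least one member")
  for (m in members) {
    mf <- model_factors(m)
    if (!setequal(mf, factors))
      stop("all members must share the ensemble FactorSet")
  }
  structure(list(members = members, factors = factors, q = q,
                 filters = filters, cbi = cbi,
                 member_labels = member_labels %||%
                   paste0("member", seq_along(members))),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d members on factors: %s (hull q = %g-%g)\n",
              length(x$members), paste(x$factors, collapse = ", "),
              x$q[1], x$q[2]))
  invisible(x)
}

#' @export
predict_esi.ensemble_model <- function(object, newdata) {
  rowMeans(member_prediction_matrix(object, newdata))
}

member_prediction_matrix <- function(ensemble, env) {
  vapply(ensemble$members, function(m) predict_esi(m, env),
         numeric(nrow(env)))
}

#' Predict a suitability map from an ensemble
#'
#' Per ocean cell: ESI is the unweighted mean over all member x replicate
#' predictions and SD the standard deviation over the same set (0 for a
#' single member).  Non-ocean cells carry `NA`.
#'
#' @param ensemble an `ensemble_model`.
#' @param stack a `layer_stack` providing every FactorSet field.
#' @return an object of class `suitability_map` with fields `esi`, `sd`
#'   (full-grid vectors), the grid, and scenario/decade labels from the
#'   stack.
#' @export
ensemble_predict <- function(ensemble, stack) {
  miss <- setdiff(ensemble$factors, names(stack$factors))
  if (length(miss))
    stop("stack lacks factor field(s): ", paste(miss, collapse = ", "))
  oc <- ocean_cells(stack)
  env <- stack_values(stack, ensemble$factors, oc)
  P <- member_prediction_matrix(ensemble, env)
  if (is.null(dim(P))) P <- matrix(P, ncol = length(ensemble$members))
  esi_o <- rowMeans(P)
  sd_o <- if (ncol(P) > 1) apply(P, 1, stats::sd) else rep(0, nrow(P))
  nc <- n_cells(stack$grid)
  esi <- sd <- rep(NA_real_, nc)
  esi[oc] <- esi_o; sd[oc] <- sd_o
  suitability_map(stack$grid, esi, sd,
                  scenario = stack$scenario %||% list(gcm = NA, rcp = NA),
                  decade = stack$period)
}

#' Suitability map container
#'
#' @param grid a `world_grid`.
#' @param esi,sd full-grid numeric fields (NA = masked / land).
#' @param scenario list of scenario labels.
#' @param decade decade / period label.
#' @param masked whether the hierarchical filter has been applied.
#' @return an object of class `suitability_map`.
#' @export
suitability_map <- function(grid, esi, sd, scenario = NULL,
                            decade = "contemporary", masked = FALSE) {
  stopifnot(length(esi) == n_cells(grid), length(sd) == n_cells(grid))
  if (any(esi < -1e-9 | esi > 1 + 1e-9, na.rm = TRUE))
    stop("ESI values must lie in [0, 1]")
  if (any(sd < -1e-9, na.rm = TRUE)) stop("SD must be non-negative")
  structure(list(grid = grid, esi = esi, sd = sd, scenario = scenario,
                 decade = decade, masked = masked),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> %s%s: mean ESI %.3f over %d valid cells%s\n",
              x$decade,
              if (!is.null(x$scenario$rcp) && !is.na(x$scenario$rcp))
                paste0(" ", x$scenario$rcp) else "",
              mean(x$esi, na.rm = TRUE), sum(!is.na(x$esi)),
              if (x$masked) " (filtered)" else ""))
  invisible(x)
}

#' Write a suitability map as CSV
#'
#' @param map a `suitability_map`.
#' @param path output path.
#' @param header optional provenance comment line.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path, header = NULL) {
  co <- grid_coords(map$grid)
  df <- cbind(co, esi = map$esi, sd = map$sd)
  meta <- sprintf("# ensdm suitability_map decade=%s rcp=%s masked=%s%s",
                  map$decade, map$scenario$rcp %||% NA, map$masked,
                  if (is.null(header)) "" else paste0(" ", header))
  writeLines(meta, path)
  suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  invisible(path)
}
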