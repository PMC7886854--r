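# End-to-end orchestration: configuration schema, provenance, and the
# staged pipeline (simulate -> clean -> fit -> project -> centroids ->
# report).  Deterministic given the config seeds.

#' Default pipeline configuration
#'
#' All tunables of a synthetic end-to-end run, validated by
#' [validate_config()] before any computation.  Every stochastic step
#' consumes a named seed derived from `seed`.
#'
#' @param seed base seed.
#' @return a named list (the config).
#' @export
default_config <- function(seed = 1) {
  list(
    species = "synthetic_species",
    seed = seed,
    grid = list(lon_min = 0, lon_max = 6, lat_min = 40, lat_max = 44,
                resolution = 0.1),
    niche = list(optimum = c(SBT = 16, SBTrange = 5),
                 tolerance = c(SBT = 2.5, SBTrange = 2), s_max = 0.9),
    n_occurrences = 500,
    depth_cutoff_m = 1000,
    exclude_flags = character(),
    factor_sets = list("SBT", c("SBT", "SBTrange")),
    quantile_pairs = list(c(2.5, 97.5), c(5, 95), c(10, 90)),
    algorithms = c("NPPEN", "GLM", "GAM", "ANN"),
    cbi_threshold = 0.5,
    n_cv = 10,
    bin_widths = default_bin_widths(),
    filters = list(depth_max = 300, coast_enabled = FALSE, coast_km = 50),
    n_gcm = 5,
    rcps = c("RCP2.6", "RCP4.5", "RCP8.5"),
    decades = c("2030-2039", "2050-2059", "2090-2099"),
    region = "all"
  )
}

#' Validate a pipeline configuration
#'
#' Schema check performed before any computation: required fields, closed
#' vocabularies (RCP and decade labels), positive sizes and seeds.
#'
#' @param config a config list (see [default_config()]).
#' @return the config, invisibly; errors describe every violation found.
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- c("species", "seed", "grid", "niche", "n_occurrences",
            "factor_sets", "quantile_pairs", "algorithms", "cbi_threshold",
            "n_cv", "bin_widths", "filters", "n_gcm", "rcps", "decades")
  miss <- setdiff(need, names(config))
  if (length(miss))
    problems <- c(problems, paste("missing field(s):",
                                  paste(miss, collapse = ", ")))
  if (!length(problems)) {
    bad_rcp <- setdiff(config$rcps, rcp_presets()$rcp)
    if (length(bad_rcp))
      problems <- c(problems, paste("invalid RCP label(s):",
                                    paste(bad_rcp, collapse = ", ")))
    bad_dec <- setdiff(config$decades, decade_labels())
    if (length(bad_dec))
      problems <- c(problems, paste("invalid decade label(s):",
                                    paste(bad_dec, collapse = ", ")))
    if (!is.numeric(config$seed) || length(config$seed) != 1)
      problems <- c(problems, "`seed` must be a single number")
    if (!is.numeric(config$n_occurrences) || config$n_occurrences <= 0)
      problems <- c(problems, "`n_occurrences` must be > 0")
    bad_alg <- setdiff(config$algorithms, KNOWN_ALGORITHMS)
    if (length(bad_alg))
      problems <- c(problems, paste("unknown algorithm id(s):",
                                    paste(bad_alg, collapse = ", ")))
  }
  if (length(problems))
    stop("invalid config:\n  - ", paste(problems, collapse = "\n  - "))
  invisible(config)
}

config_hash <- function(config) digest::digest(config, algo = "md5")

provenance_header <- function(config, stage) {
  sprintf("stage=%s config_hash=%s seed=%s", stage, config_hash(config),
          config$seed)
}

log_line <- function(run, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", sep = "", file = file.path(run, "pipeline.log"),
      append = TRUE)
  invisible(msg)
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in order, writing each stage's outputs
#' (CSV with a provenance comment header carrying the config hash and
#' seed) into `out_dir` and caching intermediate objects in the returned
#' state so stages are individually re-runnable.
#'
#' Stages: `simulate` (synthetic world + occurrences), `clean`
#' (occurrence cleaning and gridding), `fit` (filtration, pseudo-absence
#' selection, CV, CBI, ensemble selection), `project` (scenario stacks,
#' delta correction, multi-GCM ESI, hierarchical filter, anomalies),
#' `centroids` (ESI-weighted centroid tracks), `report` (JSON summary).
#'
#' @param config config list, validated first.
#' @param out_dir output directory (created if absent).
#' @param stages stages to run (default all, in order).
#' @param state optional state list from a previous partial run.
#' @return the state list (grid, stacks, occurrences, ensemble, maps,
#'   centroids, file paths), invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "clean", "fit", "project",
                                    "centroids", "report"),
                         state = list()) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- state
  seed <- config$seed
  for (stage in stages) {
    st <- switch(stage,
      simulate = stage_simulate(config, out_dir, st),
      clean = stage_clean(config, out_dir, st),
      fit = stage_fit(config, out_dir, st),
      project = stage_project(config, out_dir, st),
      centroids = stage_centroids(config, out_dir, st),
      report = stage_report(config, out_dir, st),
      stop("unknown stage '", stage, "'"))
  }
  invisible(st)
}

stage_simulate <- function(config, out_dir, st) {
  g <- config$grid
  st$grid <- world_grid(g$lon_min, g$lon_max, g$lat_min, g$lat_max,
                        g$resolution)
  st$niche <- true_niche(unlist(config$niche$optimum),
                         unlist(config$niche$tolerance),
                         config$niche$s_max %||% 0.9)
  st$stack <- generate_contemporary_stack(st$grid,
                                          seed = derive_seed(config$seed, "world"))
  st$raw_records <- sample_occurrences(st$stack, st$niche,
                                       n_target = config$n_occurrences,
                                       seed = derive_seed(config$seed, "occ"),
                                       species = config$species)
  write_stack_csv(st$stack, file.path(out_dir, "contemporary_stack.csv"))
  write_occurrences_csv(st$raw_records,
                        file.path(out_dir, "occurrences_raw.csv"),
                        header = provenance_header(config, "simulate"))
  log_line(out_dir, "simulate: %d raw records on %dx%d grid",
           nrow(st$raw_records), st$grid$nx, st$grid$ny)
  st
}

stage_clean <- function(config, out_dir, st) {
  if (is.null(st$raw_records))
    st$raw_records <- read_occurrences_csv(file.path(out_dir,
                                                     "occurrences_raw.csv"))
  cl <- clean_records(st$raw_records, st$stack,
                      depth_cutoff_m = config$depth_cutoff_m,
                      exclude_flags = config$exclude_flags)
  st$cleaned <- cl$kept
  st$occ <- grid_occurrences(cl$kept, st$grid)
  write_occurrences_csv(cl$kept, file.path(out_dir, "occurrences_clean.csv"),
                        header = provenance_header(config, "clean"))
  write_occurrences_csv(cl$rejected,
                        file.path(out_dir, "occurrences_rejected.csv"),
                        header = provenance_header(config, "clean"))
  log_line(out_dir, "clean: kept %d / %d records -> %d presence cells",
           nrow(cl$kept), nrow(st$raw_records), length(st$occ$cells))
  st
}

stage_fit <- function(config, out_dir, st) {
  sel <- select_ensemble(st$occ, st$stack,
                         factor_sets = config$factor_sets,
                         quantile_pairs = config$quantile_pairs,
                         algorithms = config$algorithms,
                         threshold = config$cbi_threshold,
                         n_rep = config$n_cv,
                         bin_widths = unlist(config$bin_widths),
                         filters = config$filters,
                         seed = derive_seed(config$seed, "fit"))
  st$ensemble <- sel$ensemble
  st$selection <- sel$selection
  hdr <- provenance_header(config, "fit")
  p <- file.path(out_dir, "selection_report.csv")
  writeLines(paste0("# ", hdr), p)
  suppressWarnings(utils::write.table(sel$report, p, sep = ",",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  p2 <- file.path(out_dir, "selected_ensemble.csv")
  writeLines(paste0("# ", hdr), p2)
  suppressWarnings(utils::write.table(sel$selection, p2, sep = ",",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  st$contemp_map <- hierarchical_filter(
    ensemble_predict(st$ensemble, st$stack), st$stack,
    depth_max = config$filters$depth_max,
    coast_km = config$filters$coast_km,
    coast_enabled = isTRUE(config$filters$coast_enabled))
  write_map_csv(st$contemp_map, file.path(out_dir, "esi_contemporary.csv"),
                header = hdr)
  log_line(out_dir, "fit: selected %s [%s], CBI = %.3f",
           sel$selection$algorithms, sel$selection$factors,
           sel$selection$cbi)
  st
}

stage_project <- function(config, out_dir, st) {
  hdr <- provenance_header(config, "project")
  forc <- gcm_forcings(st$grid, n_gcm = config$n_gcm,
                       seed = derive_seed(config$seed, "gcm"))
  forc <- Filter(function(f) f$rcp_id %in% config$rcps, forc)
  corrected <- list()
  for (f in forc) {
    base <- generate_gcm_stack(st$stack, f, "baseline")
    for (dec in config$decades) {
      raw <- generate_gcm_stack(st$stack, f, dec)
      corrected[[paste(f$gcm_id, f$rcp_id, dec, sep = "_")]] <-
        delta_correct(raw, st$stack, base)
    }
  }
  st$future_maps <- project_future(st$ensemble, corrected)
  st$future_maps <- lapply(st$future_maps, function(m)
    hierarchical_filter(m, st$stack,
                        depth_max = config$filters$depth_max,
                        coast_km = config$filters$coast_km,
                        coast_enabled = isTRUE(config$filters$coast_enabled)))
  for (k in names(st$future_maps)) {
    write_map_csv(st$future_maps[[k]],
                  file.path(out_dir, sprintf("esi_%s.csv", gsub("\\.", "", k))),
                  header = hdr)
    an <- anomaly(st$future_maps[[k]], st$contemp_map)
    df <- cbind(grid_coords(st$grid), anomaly = an)
    p <- file.path(out_dir, sprintf("anomaly_%s.csv", gsub("\\.", "", k)))
    writeLines(paste0("# ", hdr), p)
    suppressWarnings(utils::write.table(df, p, sep = ",", row.names = FALSE,
                                        quote = FALSE, append = TRUE))
  }
  log_line(out_dir, "project: %d RCP x decade maps from %d GCMs",
           length(st$future_maps), config$n_gcm)
  st
}

stage_centroids <- function(config, out_dir, st) {
  mask <- region_mask(st$grid, config$region %||% "all")
  rows <- list()
  cc <- weighted_centroid(st$contemp_map, mask)
  rows[[1]] <- data.frame(region = mask$region, rcp = "contemporary",
                          decade = "contemporary", lon = cc$lon, lat = cc$lat,
                          dlon = 0, dlat = 0)
  for (k in names(st$future_maps)) {
    fc <- weighted_centroid(st$future_maps[[k]], mask)
    sh <- centroid_shift(cc, fc)
    rows[[length(rows) + 1]] <- data.frame(
      region = mask$region, rcp = fc$rcp, decade = fc$decade,
      lon = fc$lon, lat = fc$lat, dlon = sh[["dlon"]], dlat = sh[["dlat"]])
  }
  st$centroids <- do.call(rbind, rows)
  p <- file.path(out_dir, "centroids.csv")
  writeLines(paste0("# ", provenance_header(config, "centroids")), p)
  suppressWarnings(utils::write.table(st$centroids, p, sep = ",",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  log_line(out_dir, "centroids: %d rows (region %s)", nrow(st$centroids),
           mask$region)
  st
}

stage_report <- function(config, out_dir, st) {
  report <- list(
    species = config$species,
    config_hash = config_hash(config),
    seed = config$seed,
    n_records = if (!is.null(st$raw_records)) nrow(st$raw_records) else NA,
    n_kept = if (!is.null(st$cleaned)) nrow(st$cleaned) else NA,
    n_presence_cells = if (!is.null(st$occ)) length(st$occ$cells) else NA,
    selection = st$selection,
    centroids = st$centroids
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_line(out_dir, "report: written")
  st
}
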