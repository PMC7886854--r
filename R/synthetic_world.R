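# Synthetic world: gridded environmental fields with a known Gaussian niche,
# scenario forcings and biased occurrence sampling.  Every generator is
# deterministic under a fixed seed so downstream stages are testable without
# external data.

#' Define a Gaussian "true" ecological niche
#'
#' The true niche is Gaussian and separable per environmental factor:
#' `suitability(x) = s_max * exp(-sum_f (x_f - mu_f)^2 / (2 sigma_f^2))`.
#'
#' @param optimum named numeric vector of per-factor optima (factor units).
#' @param tolerance named numeric vector of per-factor tolerances (standard
#'   deviations, same names as `optimum`), all > 0.
#' @param s_max maximum suitability in (0, 1].
#' @return an object of class `true_niche`.
#' @examples
#' niche <- true_niche(c(SBT = 16, SBTrange = 5), c(SBT = 2.5, SBTrange = 2))
#' niche_suitability(niche, data.frame(SBT = 16, SBTrange = 5)) # = s_max
#' @export
true_niche <- function(optimum, tolerance, s_max = 0.9) {
  if (is.null(names(optimum)) || is.null(names(tolerance)) ||
      !setequal(names(optimum), names(tolerance)))
    stop("`optimum` and `tolerance` must be named with the same factor names")
  tolerance <- tolerance[names(optimum)]
  if (any(tolerance <= 0)) stop("all tolerances must be > 0")
  stopifnot_scalar_number(s_max, "s_max", positive = TRUE)
  if (s_max > 1) stop("`s_max` must be in (0, 1]")
  structure(list(optimum = optimum, tolerance = tolerance, s_max = s_max),
            class = "true_niche")
}

#' Evaluate true suitability
#'
#' @param niche a `true_niche`.
#' @param env data.frame or matrix with one column per niche factor.
#' @return numeric vector of suitabilities in `[0, s_max]`.
#' @export
niche_suitability <- function(niche, env) {
  env <- as.data.frame(env)
  missing <- setdiff(names(niche$optimum), names(env))
  if (length(missing))
    stop("environment lacks niche factor(s): ", paste(missing, collapse = ", "))
  z2 <- 0
  for (f in names(niche$optimum))
    z2 <- z2 + (env[[f]] - niche$optimum[[f]])^2 / (2 * niche$tolerance[[f]]^2)
  niche$s_max * exp(-z2)
}

#' Default synthetic-world parameters
#'
#' The default world is a 60 x 40 cell shelf sea at 0.1 degree resolution
#' (lon 0--6 E, lat 40--44 N) with land along the southern edge.  Sea bottom
#' temperature (SBT) runs from `sbt_south` at the coast to `sbt_north`
#' offshore; the seasonal amplitude (hence SBTrange) increases eastwards;
#' sea surface salinity (SSS) increases eastwards; depth deepens offshore,
#' crossing both the 300 m hierarchical-filter level and the 1000 m
#' cleaning threshold at the shelf break.
#'
#' @return a named list of generator parameters.
#' @export
default_world_params <- function() {
  list(
    land_rows        = 2L,     # southern rows are land (the "coast")
    sbt_south        = 24,     # deg C at the coast
    sbt_north        = 8,      # deg C at the northern edge
    sbt_noise_sd     = 0.6,    # per-cell spatial noise on annual-mean SBT
    amp_west         = 1.0,    # seasonal SBT amplitude, western edge (deg C)
    amp_east         = 4.5,    # seasonal SBT amplitude, eastern edge
    amp_noise_sd     = 0.3,
    month_noise_sd   = 0.15,   # within-month noise on monthly SBT
    year_noise_sd    = 0.25,   # year-to-year offset on annual SBT
    sss_west         = 34,
    sss_east         = 38,
    sss_noise_sd     = 0.3,
    n_years          = 3L,     # years of monthly SBT used to derive indices
    shelf_depth_max  = 250,    # depth at the shelf break (m)
    slope_depth_max  = 1400,   # depth at the outer edge (m)
    shelf_frac       = 0.8     # fraction of the offshore span that is shelf
  )
}

#' Default grid for the synthetic world
#' @return a 60 x 40 cell `world_grid` at 0.1 degree resolution.
#' @export
default_world_grid <- function() world_grid(0, 6, 40, 44, resolution = 0.1)

#' Default Gaussian niche used in tests and examples
#' @return a `true_niche` on SBT and SBTrange.
#' @export
default_niche <- function()
  true_niche(optimum = c(SBT = 16, SBTrange = 5),
             tolerance = c(SBT = 2.5, SBTrange = 2), s_max = 0.9)

#' Generate the contemporary environmental layer stack
#'
#' Produces aligned fields SBT, SBTrange, SBTvar, SSS, bathymetry and
#' dist_to_coast on `grid`, together with the monthly SBT series from which
#' the thermal indices are derived (they are computed by
#' [derive_thermal_indices()], not injected).  Land cells carry `NA` in all
#' environmental fields.
#'
#' @param grid a `world_grid`.
#' @param params generator parameters, see [default_world_params()].
#' @param seed integer seed; the stack is identical under the same seed.
#' @return a `layer_stack` with `period = "contemporary"`.
#' @export
generate_contemporary_stack <- function(grid, params = default_world_params(),
                                        seed = 1) {
  stopifnot(inherits(grid, "world_grid"))
  nc <- n_cells(grid)
  co <- grid_coords(grid)
  iy <- rep(seq_len(grid$ny), each = grid$nx)
  land <- iy <= params$land_rows
  ocean <- !land
  # offshore fraction: 0 at first ocean row, 1 at the northern edge
  off <- (iy - params$land_rows - 0.5) / max(grid$ny - params$land_rows, 1L)
  off <- pmax(off, 0)
  lon_frac <- (co$lon - grid$lon_min) / (grid$lon_max - grid$lon_min)

  with_seed(seed, {
    sbt_mean <- params$sbt_south + (params$sbt_north - params$sbt_south) * off +
      stats::rnorm(nc, 0, params$sbt_noise_sd)
    amp <- pmax(params$amp_west + (params$amp_east - params$amp_west) * lon_frac +
                  stats::rnorm(nc, 0, params$amp_noise_sd), 0.2)
    monthly <- array(NA_real_, dim = c(nc, 12L, params$n_years))
    for (y in seq_len(params$n_years)) {
      yoff <- stats::rnorm(1, 0, params$year_noise_sd)
      for (m in 1:12) {
        monthly[, m, y] <- sbt_mean + yoff +
          amp * cos(2 * pi * (m - 8) / 12) +
          stats::rnorm(nc, 0, params$month_noise_sd)
      }
    }
    sss <- params$sss_west + (params$sss_east - params$sss_west) * lon_frac +
      stats::rnorm(nc, 0, params$sss_noise_sd)
  })

  # shelf profile: gentle slope to shelf_depth_max, then a steep shelf break
  shelf <- pmin(off / params$shelf_frac, 1)
  depth <- 10 + (params$shelf_depth_max - 10) * shelf
  deepfrac <- pmax((off - params$shelf_frac) / (1 - params$shelf_frac), 0)
  depth <- depth + (params$slope_depth_max - params$shelf_depth_max) * deepfrac
  dist_coast <- (iy - params$land_rows - 0.5) * grid$resolution * 111

  monthly[land, , ] <- NA_real_
  idx <- derive_thermal_indices(monthly)
  factors <- list(
    SBT = idx$SBT, SBTrange = idx$SBTrange, SBTvar = idx$SBTvar,
    SSS = ifelse(ocean, sss, NA_real_),
    bathymetry = ifelse(ocean, depth, NA_real_),
    dist_to_coast = ifelse(ocean, dist_coast, NA_real_)
  )
  layer_stack(grid, factors, ocean = ocean, period = "contemporary",
              monthly_sbt = monthly)
}

#' RCP warming presets
#'
#' Decadal sea-bottom warming trends by Representative Concentration
#' Pathway: peak-and-decline (RCP2.6), intermediate (RCP4.5) and
#' business-as-usual (RCP8.5).  The trends are ordered
#' RCP2.6 <= RCP4.5 <= RCP8.5.
#'
#' @return data.frame with columns `rcp` and `trend_per_decade` (deg C).
#' @export
rcp_presets <- function() {
  data.frame(rcp = c("RCP2.6", "RCP4.5", "RCP8.5"),
             trend_per_decade = c(0.10, 0.25, 0.45))
}

#' Decade labels understood by the scenario generator
#' @return character vector of decade labels.
#' @export
decade_labels <- function() c("baseline", "2030-2039", "2050-2059", "2090-2099")

decades_since_baseline <- function(decade) {
  lab <- decade_labels()
  if (!decade %in% lab)
    stop("unknown decade label '", decade, "'; expected one of: ",
         paste(lab, collapse = ", "))
  c(baseline = 0, `2030-2039` = 2, `2050-2059` = 4, `2090-2099` = 8)[[decade]]
}

#' Define a GCM x RCP scenario forcing
#'
#' A forcing is an additive per-cell bias field (the GCM's systematic error,
#' frozen for all decades of that GCM) plus an RCP-dependent warming trend
#' applied to the SBT fields.
#'
#' @param grid a `world_grid`.
#' @param gcm_id label of the general circulation model.
#' @param rcp_id one of `"RCP2.6"`, `"RCP4.5"`, `"RCP8.5"`.
#' @param seed seed for the bias field (derive it from the gcm id for a
#'   reproducible multi-GCM set, see [gcm_forcings()]).
#' @param bias_mean,bias_sd moments of the bias field: a GCM-wide offset
#'   drawn once plus per-cell noise.
#' @param trend_per_decade warming trend (deg C / decade); defaults to the
#'   [rcp_presets()] value for `rcp_id`.
#' @return an object of class `scenario_forcing`.
#' @export
scenario_forcing <- function(grid, gcm_id, rcp_id, seed = 1,
                             bias_mean = 0, bias_sd = 0.4,
                             trend_per_decade = NULL) {
  presets <- rcp_presets()
  if (!rcp_id %in% presets$rcp)
    stop("unknown RCP label '", rcp_id, "'; expected one of: ",
         paste(presets$rcp, collapse = ", "))
  trend <- trend_per_decade %||%
    presets$trend_per_decade[presets$rcp == rcp_id]
  bias <- with_seed(seed, {
    stats::rnorm(1, bias_mean, 0.5) + stats::rnorm(n_cells(grid), 0, bias_sd)
  })
  structure(list(gcm_id = gcm_id, rcp_id = rcp_id, bias = bias,
                 trend_per_decade = trend, seed = seed),
            class = "scenario_forcing")
}

#' A reproducible set of GCM forcings for every RCP
#'
#' @param grid a `world_grid`.
#' @param n_gcm number of GCMs (default 5).
#' @param seed base seed; each GCM's bias field is derived from it and is
#'   shared across RCPs (only the trend differs), so warming is ordered
#'   RCP2.6 <= RCP4.5 <= RCP8.5 cell by cell.
#' @return list of `scenario_forcing`, one per GCM x RCP.
#' @export
gcm_forcings <- function(grid, n_gcm = 5, seed = 1) {
  out <- list()
  for (g in seq_len(n_gcm)) {
    gid <- sprintf("gcm%02d", g)
    for (r in rcp_presets()$rcp) {
      out[[paste(gid, r, sep = "_")]] <-
        scenario_forcing(grid, gid, r, seed = derive_seed(seed, gid))
    }
  }
  out
}

#' Generate a GCM scenario layer stack
#'
#' `field = contemporary + bias + trend x (decades since baseline)` for the
#' SBT field; the baseline decade carries the bias only.  A uniform within-
#' year shift leaves SBTrange and SBTvar unchanged; SSS, bathymetry and
#' distance to coast are held constant in time.
#'
#' @param contemporary the observation-based `layer_stack`.
#' @param forcing a `scenario_forcing`.
#' @param decade one of [decade_labels()].
#' @return a `layer_stack` with scenario metadata.
#' @export
generate_gcm_stack <- function(contemporary, forcing, decade) {
  stopifnot(inherits(contemporary, "layer_stack"),
            inherits(forcing, "scenario_forcing"))
  if (length(forcing$bias) != n_cells(contemporary$grid))
    stop("forcing bias field does not match the contemporary grid")
  shift <- forcing$bias +
    forcing$trend_per_decade * decades_since_baseline(decade)
  factors <- contemporary$factors
  factors$SBT <- factors$SBT + shift
  layer_stack(contemporary$grid, factors, ocean = contemporary$ocean,
              period = decade, monthly_sbt = NULL,
              scenario = list(gcm = forcing$gcm_id, rcp = forcing$rcp_id,
                              decade = decade))
}

#' Sample occurrence records from the true niche
#'
#' Poisson thinning of a per-cell intensity proportional to
#' `suitability x sampling bias` over ocean cells; the total count is
#' Poisson with mean `n_target`.  Records carry lon/lat jittered within the
#' cell, a date uniform in the contemporary period (1990--2017) and a
#' source label, so they can be fed to the cleaning pipeline as raw data.
#'
#' @param stack contemporary `layer_stack`.
#' @param niche a `true_niche` whose factors are all in the stack.
#' @param n_target expected number of records for a niche whose optimum is
#'   realised somewhere on the grid; a niche outside the available
#'   environmental range yields far fewer records (thinning).
#' @param bias_field optional non-negative multiplicative sampling-intensity
#'   field (length = number of cells); default uniform.
#' @param seed integer seed.
#' @param species species label for the records.
#' @return data.frame with columns `species`, `decimalLongitude`,
#'   `decimalLatitude`, `eventDate`, `source`, `cell`.
#' @export
sample_occurrences <- function(stack, niche, n_target = 500, bias_field = NULL,
                               seed = 1, species = "synthetic_species") {
  stopifnot(inherits(stack, "layer_stack"), inherits(niche, "true_niche"))
  nc <- n_cells(stack$grid)
  bias_field <- bias_field %||% rep(1, nc)
  if (length(bias_field) != nc || any(bias_field < 0, na.rm = TRUE))
    stop("`bias_field` must be a non-negative field on the stack grid")
  env <- stack_values(stack, names(niche$optimum))
  suit <- niche_suitability(niche, env)
  w <- ifelse(stack$ocean, suit * bias_field, 0)
  w[is.na(w)] <- 0
  if (sum(w) <= 0)
    stop("suitability x bias is zero over all ocean cells; nothing to sample")
  # Poisson thinning: a niche whose optimum is realised somewhere on the
  # grid yields ~n_target records; a niche poorly matched to the available
  # conditions is thinned by the best achievable relative suitability.
  thin <- max(suit[stack$ocean], na.rm = TRUE) / niche$s_max
  lambda <- n_target * thin * w / sum(w)
  with_seed(seed, {
    counts <- stats::rpois(nc, lambda)
    cells <- rep(seq_len(nc), counts)
    n <- length(cells)
    co <- grid_coords(stack$grid)
    res <- stack$grid$resolution
    dates <- as.Date("1990-01-01") +
      floor(stats::runif(n, 0, as.numeric(as.Date("2017-12-31") -
                                            as.Date("1990-01-01")) + 1))
    data.frame(
      species = rep(species, n),
      decimalLongitude = co$lon[cells] + stats::runif(n, -res / 2, res / 2),
      decimalLatitude = co$lat[cells] + stats::runif(n, -res / 2, res / 2),
      eventDate = as.character(dates),
      source = sample(c("obis", "gbif", "sealifebase"), n, replace = TRUE,
                      prob = c(0.45, 0.45, 0.10)),
      cell = cells
    )
  })
}
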