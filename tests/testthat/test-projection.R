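test_that("taylor statistics behave on identity, offset and anti-correlated fields", {
  set.seed(1)
  x <- stats::rnorm(200)
  t1 <- taylor_stats(x, x)
  expect_equal(c(t1$r, t1$sd_ratio, t1$crmsd), c(1, 1, 0))
  t2 <- taylor_stats(x, x + 5)   # centring removes a constant offset
  expect_equal(c(t2$r, t2$crmsd), c(1, 0))
  t3 <- taylor_stats(x, -x)
  expect_equal(t3$r, -1)
  expect_error(taylor_stats(x, x[-1]), "not aligned")
  expect_error(taylor_stats(c(1, NA), c(NA, 1)), "2 valid")
})

test_that("delta correction follows the per-cell formula and restores the baseline", {
  w <- small_world()
  f <- scenario_forcing(w$grid, "g1", "RCP8.5", seed = 7)
  base <- generate_gcm_stack(w$stack, f, "baseline")
  fut <- generate_gcm_stack(w$stack, f, "2050-2059")
  corr <- delta_correct(fut, w$stack, base)
  oc <- which(w$stack$ocean)
  # obs 10, gcm_baseline 12, gcm_future 15 -> corrected 13, cell-wise
  expect_equal(corr$factors$SBT[oc],
               (fut$factors$SBT - (base$factors$SBT - w$stack$factors$SBT))[oc])
  # corrected baseline is cell-wise identical to the observation baseline
  corr0 <- delta_correct(base, w$stack, base)
  expect_equal(corr0$factors$SBT[oc], w$stack$factors$SBT[oc])
  ts <- taylor_stats(w$stack$factors$SBT, corr0$factors$SBT)
  expect_equal(c(ts$r, ts$sd_ratio, ts$crmsd), c(1, 1, 0))
  # zero-bias GCM: correction is the identity
  f0 <- f; f0$bias <- rep(0, n_cells(w$grid))
  b0 <- generate_gcm_stack(w$stack, f0, "baseline")
  fu0 <- generate_gcm_stack(w$stack, f0, "2050-2059")
  expect_equal(delta_correct(fu0, w$stack, b0)$factors$SBT, fu0$factors$SBT)
  # SSS restored from the observation baseline (kept constant in time)
  expect_equal(corr$factors$SSS, w$stack$factors$SSS)
})

test_that("multi-GCM projection averages per-RCP and stays in the member envelope", {
  sel <- test_selection()
  w <- test_world()
  forc <- gcm_forcings(w$grid, n_gcm = 3, seed = 12)
  stacks <- list()
  for (f in forc[grepl("RCP8.5", names(forc))]) {
    base <- generate_gcm_stack(w$stack, f, "baseline")
    stacks[[f$gcm_id]] <- delta_correct(
      generate_gcm_stack(w$stack, f, "2050-2059"), w$stack, base)
  }
  maps <- project_future(sel$ensemble, stacks)
  expect_named(maps, "RCP8.5_2050-2059")
  m <- maps[[1]]
  # identical GCM stacks reduce to the single-GCM map
  maps1 <- project_future(sel$ensemble, list(stacks[[1]], stacks[[1]]))
  single <- ensemble_predict(sel$ensemble, stacks[[1]])
  expect_equal(maps1[[1]]$esi, single$esi)
  # multi-GCM mean lies within the per-GCM envelope at every cell
  per_gcm <- vapply(stacks, function(s)
    ensemble_predict(sel$ensemble, s)$esi, numeric(n_cells(w$grid)))
  oc <- which(w$stack$ocean)
  expect_true(all(m$esi[oc] >= apply(per_gcm, 1, min)[oc] - 1e-12))
  expect_true(all(m$esi[oc] <= apply(per_gcm, 1, max)[oc] + 1e-12))
})

test_that("bias correction brings projections closer to the truth-driven ESI", {
  sel <- test_selection()
  w <- test_world()
  f <- scenario_forcing(w$grid, "gwarm", "RCP4.5", seed = 3,
                        bias_mean = 3, bias_sd = 0.5)  # strongly warm-biased
  base <- generate_gcm_stack(w$stack, f, "baseline")
  fut <- generate_gcm_stack(w$stack, f, "2050-2059")
  corr <- delta_correct(fut, w$stack, base)
  # the "true" future: contemporary + pure trend (no GCM bias)
  truth <- w$stack
  truth$factors$SBT <- truth$factors$SBT +
    f$trend_per_decade * ensdm:::decades_since_baseline("2050-2059")
  esi_truth <- ensemble_predict(sel$ensemble, truth)$esi
  esi_corr <- ensemble_predict(sel$ensemble, corr)$esi
  esi_raw <- ensemble_predict(sel$ensemble, fut)$esi
  oc <- which(w$stack$ocean)
  err_corr <- mean(abs(esi_corr - esi_truth)[oc])
  err_raw <- mean(abs(esi_raw - esi_truth)[oc])
  expect_lt(err_corr, err_raw)
})

test_that("hierarchical filter implements the depth / coast truth table", {
  g <- world_grid(0, 0.3, 0, 0.1, resolution = 0.1)  # 3 cells
  stack <- layer_stack(g, list(
    SBT = c(10, 10, 10),
    bathymetry = c(200, 400, 400),
    dist_to_coast = c(200, 30, 200)), ocean = rep(TRUE, 3))
  map <- suitability_map(g, esi = c(0.5, 0.5, 0.5), sd = rep(0, 3))
  # coast filter on: depth rule OR within 50 km of the coast
  f_on <- hierarchical_filter(map, stack, coast_enabled = TRUE)
  expect_equal(is.na(f_on$esi), c(FALSE, FALSE, TRUE))
  # coast filter off: depth rule only
  f_off <- hierarchical_filter(map, stack, coast_enabled = FALSE)
  expect_equal(is.na(f_off$esi), c(FALSE, TRUE, TRUE))
  expect_true(f_on$masked)
  no_depth <- layer_stack(g, list(SBT = c(1, 1, 1)), ocean = rep(TRUE, 3))
  expect_error(hierarchical_filter(map, no_depth), "bathymetry")
})

test_that("anomalies are differences on a shared mask and antisymmetric", {
  g <- world_grid(0, 0.2, 0, 0.1, resolution = 0.1)
  a <- suitability_map(g, esi = c(0.3, NA), sd = c(0, NA))
  b <- suitability_map(g, esi = c(0.9, NA), sd = c(0, NA))
  expect_equal(anomaly(b, a), c(0.6, NA))
  expect_equal(anomaly(a, b), -anomaly(b, a))
  expect_equal(anomaly(a, a), c(0, NA))
  c_bad <- suitability_map(g, esi = c(NA, 0.5), sd = c(NA, 0))
  expect_error(anomaly(a, c_bad), "mask mismatch")
})
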