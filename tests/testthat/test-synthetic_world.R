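test_that("world_grid builds deterministic cell-centre grids and validates input", {
  g <- world_grid(0, 3, 0, 2, resolution = 1)
  expect_equal(c(g$nx, g$ny), c(3L, 2L))
  co <- grid_coords(g)
  expect_equal(unlist(co[1, c("lon", "lat")], use.names = FALSE), c(0.5, 0.5))
  expect_equal(nrow(co), 6L)
  expect_equal(anyDuplicated(paste(co$lon, co$lat)), 0L)

  g2 <- world_grid(0, 0.2, 0, 0.2, resolution = 0.1)
  expect_equal(c(g2$nx, g2$ny), c(2L, 2L))

  expect_error(world_grid(0, 1, 0, 1, resolution = 0), "> 0")
  expect_error(world_grid(0, 1, 0, 1, resolution = -0.1), "> 0")
  expect_error(world_grid(0, 1, 0, 1, resolution = 0.3), "divide")
})

test_that("cell membership uses half-open intervals", {
  g <- world_grid(0, 2, 0, 2, resolution = 1)
  # west/south edges belong to the cell, east/north edges to the next
  expect_equal(locate_cells(g, 0, 0), 1L)
  expect_equal(locate_cells(g, 1, 0), 2L)
  expect_equal(locate_cells(g, 0, 1), 3L)
  expect_true(is.na(locate_cells(g, 2, 0)))   # east boundary is outside
  expect_true(is.na(locate_cells(g, -0.01, 0)))
})

test_that("contemporary stack is deterministic, aligned, and carries the stated structure", {
  g <- small_world()$grid
  a <- generate_contemporary_stack(g, seed = 5)
  b <- generate_contemporary_stack(g, seed = 5)
  expect_identical(a$factors, b$factors)
  expect_identical(a$monthly_sbt, b$monthly_sbt)
  expect_false(identical(a$factors$SBT,
                         generate_contemporary_stack(g, seed = 6)$factors$SBT))

  for (f in names(a$factors)) expect_length(a$factors[[f]], n_cells(g))
  oc <- which(a$ocean)
  # latitudinal SBT gradient: south warmer than north on average
  co <- grid_coords(g)
  south <- oc[co$lat[oc] < stats::median(co$lat[oc])]
  north <- setdiff(oc, south)
  expect_gt(mean(a$factors$SBT[south]), mean(a$factors$SBT[north]))
  # indices are derived from the monthly series, not injected
  idx <- derive_thermal_indices(a$monthly_sbt)
  expect_equal(a$factors$SBT[oc], idx$SBT[oc])
  expect_equal(a$factors$SBTrange[oc], idx$SBTrange[oc])
  # deep cells beyond the cleaning threshold exist
  expect_true(any(a$factors$bathymetry[oc] > 1000))
  # land cells are NA in every environmental field
  expect_true(all(is.na(a$factors$SBT[!a$ocean])))
})

test_that("true suitability follows the separable Gaussian formula pointwise", {
  niche <- true_niche(c(SBT = 16, SBTrange = 5), c(SBT = 2, SBTrange = 1),
                      s_max = 0.8)
  env <- data.frame(SBT = c(16, 18, 10), SBTrange = c(5, 6, 2))
  expected <- 0.8 * exp(-((env$SBT - 16)^2 / (2 * 4) +
                            (env$SBTrange - 5)^2 / 2))
  expect_equal(niche_suitability(niche, env), expected)
  expect_equal(niche_suitability(niche, env)[1], 0.8)
  expect_true(all(niche_suitability(niche, env) <= 0.8))
  expect_error(true_niche(c(SBT = 1), c(SBT = 0)), "> 0")
  expect_error(true_niche(c(SBT = 1), c(x = 1)), "same factor names")
})

test_that("gcm stacks follow field = contemporary + bias + trend x decades", {
  w <- small_world()
  f <- scenario_forcing(w$grid, "gcmX", "RCP4.5", seed = 9,
                        trend_per_decade = 0.3)
  f0 <- f; f0$bias <- rep(2, n_cells(w$grid)); f0$trend_per_decade <- 0
  base <- generate_gcm_stack(w$stack, f0, "baseline")
  expect_equal(base$factors$SBT, w$stack$factors$SBT + 2)

  fut <- generate_gcm_stack(w$stack, f, "2090-2099")
  b <- generate_gcm_stack(w$stack, f, "baseline")
  # 8 decades after baseline at 0.3 deg C / decade
  expect_equal(fut$factors$SBT, b$factors$SBT + 0.3 * 8)
  # SBTrange, SSS, bathymetry held constant
  expect_equal(fut$factors$SBTrange, w$stack$factors$SBTrange)
  expect_equal(fut$factors$SSS, w$stack$factors$SSS)
  expect_error(generate_gcm_stack(w$stack, f, "2040-2049"), "unknown decade")
})

test_that("preset RCP warming is ordered RCP2.6 <= RCP4.5 <= RCP8.5 per cell and decade", {
  w <- small_world()
  forc <- gcm_forcings(w$grid, n_gcm = 2, seed = 4)
  oc <- which(w$stack$ocean)
  for (g in c("gcm01", "gcm02")) {
    for (dec in c("2030-2039", "2090-2099")) {
      s26 <- generate_gcm_stack(w$stack, forc[[paste0(g, "_RCP2.6")]], dec)
      s45 <- generate_gcm_stack(w$stack, forc[[paste0(g, "_RCP4.5")]], dec)
      s85 <- generate_gcm_stack(w$stack, forc[[paste0(g, "_RCP8.5")]], dec)
      expect_true(all(s26$factors$SBT[oc] <= s45$factors$SBT[oc]))
      expect_true(all(s45$factors$SBT[oc] <= s85$factors$SBT[oc]))
    }
  }
})

test_that("occurrence sampling tracks true suitability", {
  w <- small_world()
  oc <- which(w$stack$ocean)
  suit <- niche_suitability(w$niche, stack_values(w$stack,
                                                  names(w$niche$optimum), oc))
  counts <- rep(0, length(oc))
  n_max <- 0
  best <- which.max(suit)
  for (r in 1:200) {
    occ <- sample_occurrences(w$stack, w$niche, n_target = 50, seed = 1000 + r)
    tab <- table(factor(occ$cell, levels = oc))
    counts <- counts + as.integer(tab)
    n_max <- n_max + as.integer(tab)[best]
  }
  # maximum-suitability cells are sampled at the highest empirical rates:
  # the optimum cell sits in the top tail and the top suitability decile
  # out-draws every other decile
  expect_gte(counts[best], stats::quantile(counts, 0.95))
  expect_gt(n_max, 0)
  dec <- cut(suit, stats::quantile(suit, 0:10 / 10), include.lowest = TRUE,
             labels = FALSE)
  rate <- tapply(counts, dec, mean)
  expect_equal(which.max(rate), c(`10` = 10L))
  # sampling density correlates positively with true suitability
  expect_gt(stats::cor(counts, suit, method = "spearman"), 0.5)
  # determinism under a fixed seed
  expect_identical(sample_occurrences(w$stack, w$niche, 50, seed = 7),
                   sample_occurrences(w$stack, w$niche, 50, seed = 7))
})

test_that("occurrence sampling thins when the optimum lies outside the grid", {
  w <- small_world()
  far <- true_niche(c(SBT = 40, SBTrange = 30), c(SBT = 1, SBTrange = 1))
  n <- nrow(sample_occurrences(w$stack, far, n_target = 500, seed = 3))
  expect_lt(n, 50)
  impossible <- true_niche(c(SBT = 1e6), c(SBT = 1e-3))
  expect_error(sample_occurrences(w$stack, impossible, 100, seed = 1), "zero")
})
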