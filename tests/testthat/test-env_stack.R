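test_that("thermal indices follow the yearly-then-average definition", {
  # constant series: mean only
  m <- matrix(10, nrow = 2, ncol = 12)
  idx <- derive_thermal_indices(m)
  expect_equal(idx$SBT, c(10, 10))
  expect_equal(idx$SBTrange, c(0, 0))
  expect_equal(idx$SBTvar, c(0, 0))
  # linear months 5..16: range = max - min = 11
  expect_equal(derive_thermal_indices(matrix(5:16, 1))$SBTrange, 11)
  # two years with ranges 4 and 6 average to 5
  a <- array(0, dim = c(1, 12, 2))
  a[1, , 1] <- c(rep(0, 11), 4)
  a[1, , 2] <- c(rep(0, 11), 6)
  expect_equal(derive_thermal_indices(a)$SBTrange, 5)
  # per-year variance then averaged, not variance of the pooled series
  expect_equal(derive_thermal_indices(a)$SBTvar,
               mean(c(stats::var(a[1, , 1]), stats::var(a[1, , 2]))))
  expect_error(derive_thermal_indices(matrix(1, 1, 11)), "12")
  bad <- matrix(1, 1, 12); bad[1, 3] <- NA
  expect_error(derive_thermal_indices(bad), "missing months")
})

test_that("bilinear regridding preserves constants and linear fields", {
  src <- world_grid(0, 5, 0, 5, resolution = 0.5)
  tgt <- world_grid(0.5, 4.5, 0.5, 4.5, resolution = 0.1)
  co <- grid_coords(src)
  expect_equal(regrid_bilinear(rep(7, n_cells(src)), src, tgt),
               rep(7, n_cells(tgt)))
  lin <- 2 * co$lon - 3 * co$lat + 1
  cot <- grid_coords(tgt)
  expect_equal(regrid_bilinear(lin, src, tgt),
               2 * cot$lon - 3 * cot$lat + 1, tolerance = 1e-12)
  expect_error(regrid_bilinear(lin, src, world_grid(0, 6, 0, 5, 0.5)),
               "outside the source")
})

test_that("regridded midpoints match hand-computed bilinear weights", {
  src <- world_grid(0, 2, 0, 2, resolution = 0.5)  # 4 x 4 source centres
  field <- seq_len(n_cells(src))^2                  # nonlinear on purpose
  tgt <- world_grid(0.7, 0.8, 0.9, 1.0, resolution = 0.1)  # single centre
  cot <- grid_coords(tgt)   # centre (0.75, 0.95)
  # surrounding source centres: lon 0.25/0.75 -> i0 = 2, lat 0.75/1.25 -> j0 = 2
  tx <- (0.75 - 0.75) / 0.5 + 1; ty <- (0.95 - 0.75) / 0.5
  f <- function(i, j) field[(j - 1) * 4 + i]
  expected <- bilinear_by_hand(f(2, 2), f(3, 2), f(2, 3), f(3, 3),
                               tx = (0.75 - 0.25) / 0.5 - 1, ty = ty)
  expect_equal(regrid_bilinear(field, src, tgt), expected)
  # 1-D gradient: target midway between flanking centres = their average
  src1 <- world_grid(0, 2, 0, 0.5, resolution = 0.5)
  g1 <- grid_coords(src1)$lon * 10
  tgt1 <- world_grid(0.45, 0.55, 0.2, 0.3, resolution = 0.1) # centre 0.5
  expect_equal(regrid_bilinear(g1, src1, tgt1), mean(c(2.5, 7.5)))
})

test_that("nearest-valid fallback fills NA corners", {
  src <- world_grid(0, 1, 0, 1, resolution = 0.5)
  field <- c(1, NA, 3, 4)
  tgt <- world_grid(0.4, 0.6, 0.4, 0.6, resolution = 0.2)  # centre (0.5, 0.5)
  v <- regrid_bilinear(field, src, tgt)
  expect_true(is.finite(v))
  expect_true(v %in% c(1, 3, 4) || (v >= 1 && v <= 4))
  expect_true(all(is.na(regrid_bilinear(rep(NA_real_, 4), src, tgt))))
})

test_that("collinearity screen drops duplicated factors and keeps SBT", {
  w <- test_world()
  stack <- w$stack
  # duplicate SBTrange as SBTvar to force r = 1 within the pair
  stack$factors$SBTvar <- stack$factors$SBTrange
  kept <- collinearity_screen(stack, w$occ$cells,
                              candidates = c("SBT", "SBTrange", "SBTvar"),
                              importance = c(SBT = 1, SBTrange = 0.8,
                                             SBTvar = 0.2))
  expect_true("SBT" %in% kept)
  expect_equal(sum(c("SBTrange", "SBTvar") %in% kept), 1L)
  expect_equal(kept, c("SBT", "SBTrange"))  # the more important of the pair
  # independent factors are all retained
  vals <- stack_values(w$stack, c("SBT", "SBTrange", "SSS"), w$occ$cells)
  r <- abs(stats::cor(vals)); diag(r) <- 0
  if (max(r) < 0.7) {
    kept2 <- collinearity_screen(w$stack, w$occ$cells,
                                 candidates = c("SBT", "SBTrange", "SSS"),
                                 importance = c(SBT = 1, SBTrange = 0.5,
                                                SSS = 0.3))
    expect_setequal(kept2, c("SBT", "SBTrange", "SSS"))
  }
  const <- w$stack
  const$factors$SSS <- rep(1, n_cells(w$grid))
  expect_error(collinearity_screen(const, w$occ$cells,
                                   candidates = c("SBT", "SSS")),
               "zero-variance")
})

test_that("permutation importance separates used from ignored factors", {
  w <- test_world()
  pres <- env_points(w$stack, w$occ$cells, c("SBT", "SBTrange"))
  # single-factor NPPEN: permuting its only factor destroys the map
  m1 <- fit_nppen(pres["SBT"])
  expect_gt(permutation_importance(m1, w$stack, "SBT", seed = 1), 0.3)
  # a GLM member on (SBT, SSS) where presence depends on SBT only:
  # permuting the ignored SSS barely changes the map, permuting SBT does
  oc <- which(w$stack$ocean)
  env <- stack_values(w$stack, c("SBT", "SSS"), oc)
  role <- ifelse(abs(env$SBT - 16) < 2, "presence", "pseudo_absence")
  toy <- cbind(role = role, cell = oc, env)
  # the deterministic threshold rule separates classes almost perfectly,
  # so glm emits convergence warnings that are irrelevant to the contract
  m2 <- suppressWarnings(fit_member("GLM", toy, c("SBT", "SSS")))
  imp_sbt <- permutation_importance(m2, w$stack, "SBT", seed = 2)
  imp_sss <- permutation_importance(m2, w$stack, "SSS", seed = 2)
  expect_lt(imp_sss, 0.1)   # ignored factor: importance ~ 0
  expect_gt(imp_sbt, imp_sss + 0.2)
  expect_error(permutation_importance(m1, w$stack, "SSS"), "not in the model")
  # spread over repeated seeds is small (importance stable in expectation)
  imps <- vapply(1:20, function(s)
    permutation_importance(m1, w$stack, "SBT", n_perm = 10, seed = s),
    numeric(1))
  expect_lt(stats::sd(imps), 0.05)
})

test_that("candidate factor sets follow the enumeration design and contain SBT", {
  fs <- candidate_factor_sets(c("SBT", "SBTrange", "SBTvar", "SSS"))
  expect_length(fs, 6L)
  expect_true(all(vapply(fs, function(f) "SBT" %in% f, logical(1))))
  expect_true(any(vapply(fs, function(f) setequal(f, c("SBT", "SBTrange", "SSS")),
                         logical(1))))
  expect_length(candidate_factor_sets("SBT"), 1L)
  expect_error(candidate_factor_sets("SSS"), "SBT")
})

test_that("layer stack CSV round-trips fields and metadata", {
  w <- small_world()
  path <- withr::local_tempfile(fileext = ".csv")
  write_stack_csv(w$stack, path)
  back <- read_stack_csv(path)
  expect_equal(back$factors$SBT, w$stack$factors$SBT)
  expect_equal(back$ocean, w$stack$ocean)
  expect_equal(back$period, w$stack$period)
  expect_true(ensdm:::same_grid(back$grid, w$stack$grid))
})
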