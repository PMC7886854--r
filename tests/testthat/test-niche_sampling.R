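test_that("environmental filtration keeps one point per bin and is idempotent", {
  pts <- data.frame(cell = c(3L, 1L, 2L), SBT = c(15.1, 15.3, 15.6))
  out <- environmental_filter(pts, c(SBT = 0.5))
  # 15.1 and 15.3 share the [15.0, 15.5) bin; 15.6 is its own bin
  expect_equal(nrow(out), 2L)
  # keeper is the first in cell-id order: cell 1 (15.3)
  expect_equal(out$SBT, c(15.3, 15.6))
  expect_equal(environmental_filter(out, c(SBT = 0.5)), out)
  expect_error(environmental_filter(pts, c(SBT = 0)), "> 0")
  expect_error(environmental_filter(pts, c(SSS = 0.5)), "no bin width")
})

test_that("filtration contract holds on random datasets (property)", {
  bw <- c(SBT = 0.5, SSS = 0.5)
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:120, 1)
    pts <- data.frame(cell = sample(1e4, n),
                      SBT = stats::runif(n, 0, 25),
                      SSS = stats::runif(n, 30, 40))
    f1 <- environmental_filter(pts, bw)
    key <- paste(floor(f1$SBT / 0.5), floor(f1$SSS / 0.5))
    expect_equal(anyDuplicated(key), 0L)       # <= 1 point per bin
    expect_equal(environmental_filter(f1, bw), f1)  # idempotent
  }
})

test_that("restricted hulls trim outer quantiles per dimension", {
  set.seed(7)
  pts <- data.frame(cell = 1:100,
                    SBT = stats::runif(100), SBTrange = stats::runif(100))
  h <- build_restricted_hull(pts, c(10, 90))
  qs <- apply(pts[c("SBT", "SBTrange")], 2, stats::quantile,
              probs = c(0.1, 0.9))
  expect_true(all(h$points[, "SBT"] >= qs[1, "SBT"] &
                    h$points[, "SBT"] <= qs[2, "SBT"]))
  expect_true(all(h$points[, "SBTrange"] >= qs[1, "SBTrange"] &
                    h$points[, "SBTrange"] <= qs[2, "SBTrange"]))
  # a gross outlier is never a hull vertex under trimming
  out_pts <- rbind(pts, data.frame(cell = 101L, SBT = 50, SBTrange = 50))
  h2 <- build_restricted_hull(out_pts, c(10, 90))
  expect_false(any(h2$points[, "SBT"] == 50))
  # q = (0, 100) keeps everything (unrestricted hull)
  h3 <- build_restricted_hull(out_pts, c(0, 100))
  expect_equal(h3$n_retained, 101L)
  expect_true(any(h3$points[, "SBT"] == 50))
  expect_error(build_restricted_hull(pts[1:2, ], c(10, 90)), "too few")
  expect_error(build_restricted_hull(pts, c(90, 10)), "q1 < q2")
})

test_that("simplex membership test agrees with the 2-D facet oracle", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(8:40, 1)
    V <- cbind(stats::rnorm(n), stats::rnorm(n))
    colnames(V) <- c("a", "b")
    hull <- structure(list(points = V[grDevices::chull(V), , drop = FALSE],
                           q = c(0, 100), factors = c("a", "b"), d = 2L,
                           n_retained = n), class = "restricted_hull")
    X <- cbind(a = stats::rnorm(30, sd = 1.5), b = stats::rnorm(30, sd = 1.5))
    got <- in_hull(hull, as.data.frame(X))
    want <- apply(X, 1, function(x) facet_in_hull_2d(V, x))
    expect_equal(got, unname(want))
  }
  # vertices themselves are inside (boundary counts as inside)
  V <- cbind(a = c(0, 1, 0.5), b = c(0, 0, 1))
  hull <- structure(list(points = V, q = c(0, 100), factors = c("a", "b"),
                         d = 2L, n_retained = 3L), class = "restricted_hull")
  expect_true(all(in_hull(hull, as.data.frame(V))))
  expect_true(in_hull(hull, data.frame(a = 0.5, b = 0.25)))
  expect_false(in_hull(hull, data.frame(a = 2, b = 2)))
})

test_that("membership works in 1-D and 3-D", {
  pts1 <- data.frame(cell = 1:20, SBT = 1:20)
  h1 <- build_restricted_hull(pts1, c(10, 90))
  rng <- range(h1$points)
  expect_true(in_hull(h1, data.frame(SBT = mean(rng))))
  expect_false(in_hull(h1, data.frame(SBT = rng[2] + 1)))
  expect_true(in_hull(h1, data.frame(SBT = rng[1])))  # boundary inside

  set.seed(3)
  pts3 <- data.frame(cell = 1:60, x = stats::rnorm(60), y = stats::rnorm(60),
                     z = stats::rnorm(60))
  h3 <- build_restricted_hull(pts3, c(0, 100))
  # centroid is inside; a far point is outside
  expect_true(in_hull(h3, data.frame(x = mean(pts3$x), y = mean(pts3$y),
                                     z = mean(pts3$z))))
  expect_false(in_hull(h3, data.frame(x = 10, y = 10, z = 10)))
  # every generator point is inside its own hull
  expect_true(all(in_hull(h3, pts3)))
})

test_that("pseudo-absences are equal in number and strictly outside the hull", {
  w <- test_world()
  factors <- c("SBT", "SBTrange")
  pres <- environmental_filter(env_points(w$stack, w$occ$cells, factors))
  hull <- build_restricted_hull(pres, c(10, 90))
  bg <- env_points(w$stack, which(w$stack$ocean), factors)
  pa <- sample_pseudo_absences(bg, hull, nrow(pres), seed = 5)
  expect_equal(nrow(pa), nrow(pres))
  expect_false(any(in_hull(hull, pa)))
  # independent facet-test oracle confirms every point is outside
  V <- hull$points
  expect_false(any(apply(as.matrix(pa[factors]), 1,
                         function(x) facet_in_hull_2d(V, x))))
  # determinism and a clear deficit error
  expect_identical(sample_pseudo_absences(bg, hull, nrow(pres), seed = 5), pa)
  expect_error(sample_pseudo_absences(bg, hull, 1e5, seed = 1), "deficit")
})

test_that("widening the quantile pair never shrinks the eligible pool", {
  w <- test_world()
  factors <- c("SBT", "SBTrange")
  pres <- environmental_filter(env_points(w$stack, w$occ$cells, factors))
  bg <- environmental_filter(env_points(w$stack, which(w$stack$ocean), factors))
  eligible <- function(q) sum(!in_hull(build_restricted_hull(pres, q), bg))
  e_wide <- eligible(c(2.5, 97.5))   # widest hull, fewest eligible
  e_mid <- eligible(c(5, 95))
  e_narrow <- eligible(c(10, 90))
  expect_lte(e_wide, e_mid)
  expect_lte(e_mid, e_narrow)
})

test_that("niche datasets enforce presence / pseudo-absence parity", {
  w <- test_world()
  nd <- build_niche_dataset(w$occ, w$stack, c("SBT", "SBTrange"),
                            q = c(10, 90), seed = 8)
  expect_s3_class(nd, "niche_dataset")
  expect_equal(sum(nd$role == "presence"), sum(nd$role == "pseudo_absence"))
  expect_equal(attr(nd, "factors"), c("SBT", "SBTrange"))
  pres <- nd[nd$role == "presence", ]
  expect_error(niche_dataset(pres, pres[-1, ], c("SBT", "SBTrange"),
                             c(10, 90)),
               "counts differ")
})
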