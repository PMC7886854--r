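# Shared fixtures, built in code and cached for the test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Desk-scale default world (60 x 40 at 0.1 deg) with the stated niche.
test_world <- function() fixture("world", function() {
  grid <- default_world_grid()
  stack <- generate_contemporary_stack(grid, seed = 101)
  niche <- default_niche()
  raw <- sample_occurrences(stack, niche, n_target = 500, seed = 202)
  occ <- grid_occurrences(clean_records(raw, stack)$kept, grid)
  list(grid = grid, stack = stack, niche = niche, raw = raw, occ = occ)
})

# Small fast world for property loops.
small_world <- function() fixture("small", function() {
  grid <- world_grid(0, 3, 40, 42, resolution = 0.1)
  stack <- generate_contemporary_stack(grid, seed = 33)
  list(grid = grid, stack = stack, niche = default_niche())
})

# A fitted NPPEN + GLM ensemble on the default world (reused by the
# heavier acceptance criteria).
test_selection <- function() fixture("selection", function() {
  w <- test_world()
  select_ensemble(w$occ, w$stack,
                  factor_sets = list(c("SBT", "SBTrange")),
                  quantile_pairs = list(c(10, 90)),
                  algorithms = c("NPPEN", "GLM"),
                  seed = 404)
})

# --- independent oracles ------------------------------------------------

# Counting oracle for NPPEN: stats::mahalanobis + naive proportion.
nppen_oracle <- function(Z, X) {
  zbar <- colMeans(Z)
  V <- stats::cov(Z)
  d2ref <- stats::mahalanobis(Z, zbar, V)
  d2x <- stats::mahalanobis(X, zbar, V)
  vapply(d2x, function(d) sum(d2ref >= d) / nrow(Z), numeric(1))
}

# 2-D point-in-convex-hull oracle: half-space (cross-product) facet test
# on the chull-ordered vertices; boundary counts as inside.
facet_in_hull_2d <- function(V, x, tol = 1e-9) {
  h <- grDevices::chull(V[, 1], V[, 2])
  P <- V[h, , drop = FALSE]
  n <- nrow(P)
  cr <- vapply(seq_len(n), function(i) {
    a <- P[i, ]; b <- P[if (i == n) 1 else i + 1, ]
    (b[1] - a[1]) * (x[2] - a[2]) - (b[2] - a[2]) * (x[1] - a[1])
  }, numeric(1))
  all(cr <= tol) || all(cr >= -tol)
}

# Hand-computed bilinear interpolation at one point from a source grid.
bilinear_by_hand <- function(f00, f10, f01, f11, tx, ty) {
  (1 - tx) * (1 - ty) * f00 + tx * (1 - ty) * f10 +
    (1 - tx) * ty * f01 + tx * ty * f11
}
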