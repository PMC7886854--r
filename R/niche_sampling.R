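# Environmental-space sampling design: filtration of presences on an
# environmental grid, restricted convex hulls, and pseudo-absence selection
# outside the hull.

#' Environmental vectors of cells
#'
#' @param stack a `layer_stack`.
#' @param cells integer cell ids.
#' @param factors factor names (one column each).
#' @return data.frame with a `cell` column plus one column per factor;
#'   rows with non-finite values are dropped.
#' @export
env_points <- function(stack, cells, factors) {
  df <- cbind(cell = cells, stack_values(stack, factors, cells))
  ok <- stats::complete.cases(df)
  df[ok, , drop = FALSE]
}

#' Default environmental bin widths
#'
#' 0.5 deg C for thermal factors and 0.5 (practical salinity) for SSS —
#' the resolution of the environmental filtration domain.
#'
#' @param factors factor names.
#' @return named numeric vector of bin widths.
#' @export
default_bin_widths <- function(factors = c("SBT", "SBTrange", "SBTvar", "SSS")) {
  stats::setNames(rep(0.5, length(factors)), factors)
}

#' Environmental filtration of presence points
#'
#' Partitions environmental space into a multidimensional grid of bins
#' (`floor(x / width)` per factor) and keeps exactly one point per occupied
#' bin — the first in deterministic cell-id order — so every observed
#' environmental condition enters the models with the same weight,
#' independent of the geographic sampling effort.  Idempotent.
#'
#' @param points env-point data.frame (see [env_points()]).
#' @param bin_widths named bin widths covering every factor column
#'   (default [default_bin_widths()]).
#' @return the filtered subset of `points`, ordered by cell id.
#' @export
environmental_filter <- function(points, bin_widths = default_bin_widths()) {
  factors <- setdiff(names(points), "cell")
  miss <- setdiff(factors, names(bin_widths))
  if (length(miss))
    stop("no bin width given for factor(s): ", paste(miss, collapse = ", "))
  if (any(bin_widths[factors] <= 0)) stop("bin widths must be > 0")
  points <- points[order(points$cell), , drop = FALSE]
  key <- do.call(paste, c(lapply(factors, function(f)
    floor(points[[f]] / bin_widths[[f]])), sep = "|"))
  out <- points[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a restricted convex hull in environmental space
#'
#' Drops points outside the `[q_low, q_high]` per-dimension empirical
#' quantiles in any dimension, then takes the convex hull of the
#' remainder.  The quantile pair controls the permeability of the niche
#' edge; `q = c(0, 100)` gives the unrestricted hull.
#'
#' @param points env-point data.frame of filtered presences.
#' @param q numeric quantile pair in percent, one of the study designs
#'   `c(2.5, 97.5)`, `c(5, 95)`, `c(10, 90)` (any pair with
#'   `0 <= q1 < q2 <= 100` is accepted).
#' @return an object of class `restricted_hull` holding the retained
#'   points (whose convex hull defines the envelope), the quantile pair
#'   and, in one dimension, the interval bounds.
#' @export
build_restricted_hull <- function(points, q = c(10, 90)) {
  if (length(q) != 2 || q[1] < 0 || q[2] > 100 || q[1] >= q[2])
    stop("`q` must be a percent pair with 0 <= q1 < q2 <= 100")
  factors <- setdiff(names(points), "cell")
  X <- as.matrix(points[factors])
  d <- ncol(X)
  keep <- rep(TRUE, nrow(X))
  bounds <- matrix(NA_real_, 2, d, dimnames = list(c("lo", "hi"), factors))
  for (j in seq_len(d)) {
    bounds[, j] <- stats::quantile(X[, j], q / 100, names = FALSE)
    keep <- keep & X[, j] >= bounds[1, j] & X[, j] <= bounds[2, j]
  }
  V <- X[keep, , drop = FALSE]
  if (nrow(V) < d + 1)
    stop("too few points after quantile trimming (", nrow(V),
         "); need at least d + 1 = ", d + 1)
  # reduce to hull vertices in 2-D for cheaper membership tests
  if (d == 2L) {
    h <- grDevices::chull(V[, 1], V[, 2])
    V <- V[h, , drop = FALSE]
  }
  structure(list(points = V, q = q, factors = factors, d = d,
                 n_retained = sum(keep), bounds = bounds),
            class = "restricted_hull")
}

#' @export
print.restricted_hull <- function(x, ...) {
  cat(sprintf("<restricted_hull> %d-D, q = (%g, %g), %d retained points\n",
              x$d, x$q[1], x$q[2], x$n_retained))
  invisible(x)
}

# Phase-1 simplex feasibility: is there lambda >= 0 with V' lambda = x,
# sum(lambda) = 1?  V is n x d (rows = hull generator points).  Exact up to
# `tol`; boundary points count as inside.
simplex_in_hull <- function(V, x, tol = 1e-9) {
  n <- nrow(V); d <- ncol(V)
  A <- rbind(t(V), rep(1, n))
  b <- c(x, 1)
  # scale rows for conditioning
  s <- pmax(apply(abs(A), 1, max), 1)
  A <- A / s; b <- b / s
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg]
  m <- d + 1L
  # tableau with artificial basis: [A | I | b]
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost <- c(rep(0, n), rep(1, m))
  maxit <- 200L * (n + m)
  for (it in seq_len(maxit)) {
    cb <- cost[basis]
    y <- crossprod(Tb[, seq_len(n + m), drop = FALSE], cb)
    red <- cost - as.vector(y)
    enter <- which(red < -1e-12)[1]          # Bland's rule
    if (is.na(enter)) break
    col <- Tb[, enter]
    pos <- which(col > 1e-12)
    if (!length(pos)) break                   # unbounded (cannot happen here)
    ratio <- Tb[pos, n + m + 1L] / col[pos]
    leave <- pos[order(ratio, basis[pos])][1] # smallest ratio, Bland tie-break
    Tb[leave, ] <- Tb[leave, ] / Tb[leave, enter]
    for (r in seq_len(m)) if (r != leave && abs(Tb[r, enter]) > 0)
      Tb[r, ] <- Tb[r, ] - Tb[r, enter] * Tb[leave, ]
    basis[leave] <- enter
  }
  obj <- sum(cost[basis] * Tb[, n + m + 1L])
  obj <= tol * max(1, max(abs(b)))
}

#' Test points against a restricted convex hull
#'
#' Membership in the convex hull of the retained points, decided by a
#' phase-1 simplex feasibility test (exact linear programming, any
#' dimension); boundary points count as inside.  In one dimension the hull
#' is the interval between the trimmed minimum and maximum.
#'
#' @param hull a `restricted_hull`.
#' @param points env-point data.frame or matrix with the hull's factor
#'   columns.
#' @param tol numerical tolerance in factor units (default 1e-9).
#' @return logical vector, `TRUE` for inside (or on the boundary).
#' @export
in_hull <- function(hull, points, tol = 1e-9) {
  X <- as.matrix(as.data.frame(points)[hull$factors])
  if (hull$d == 1L) {
    rng <- range(hull$points[, 1])
    return(X[, 1] >= rng[1] - tol & X[, 1] <= rng[2] + tol)
  }
  V <- hull$points
  # bounding-box pre-filter: outside the box => outside the hull
  lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  inside_box <- rep(TRUE, nrow(X))
  for (j in seq_len(hull$d))
    inside_box <- inside_box & X[, j] >= lo[j] - tol & X[, j] <= hi[j] + tol
  out <- logical(nrow(X))
  for (i in which(inside_box))
    out[i] <- simplex_in_hull(V, X[i, ], tol = tol)
  out
}

#' Sample pseudo-absences outside the restricted hull
#'
#' The background pool (environmental vectors of all ocean cells of the
#' calibration domain) is first environmentally deduplicated at the
#' filtration bin widths — selecting several pseudo-absences with
#' identical environmental conditions would contradict the filtration
#' procedure — then points strictly outside the hull are sampled uniformly
#' without replacement, in equal number to the filtered presences.
#'
#' @param background env-point data.frame of the calibration-domain ocean
#'   cells.
#' @param hull a `restricted_hull`.
#' @param n number of pseudo-absences (= number of filtered presences).
#' @param bin_widths filtration bin widths for the deduplication.
#' @param seed integer seed.
#' @return env-point data.frame of `n` pseudo-absences.
#' @export
sample_pseudo_absences <- function(background, hull, n,
                                   bin_widths = default_bin_widths(),
                                   seed = 1) {
  pool <- environmental_filter(background, bin_widths)
  eligible <- pool[!in_hull(hull, pool), , drop = FALSE]
  if (nrow(eligible) < n)
    stop(sprintf(paste0("only %d eligible background points outside the hull ",
                        "for %d pseudo-absences (deficit %d); consider a ",
                        "narrower quantile pair"),
                 nrow(eligible), n, n - nrow(eligible)))
  idx <- with_seed(seed, sample(nrow(eligible), n))
  out <- eligible[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a presence / pseudo-absence niche dataset
#'
#' @param presences filtered presence env-points.
#' @param pseudo_absences pseudo-absence env-points (same factor columns,
#'   same number of rows).
#' @param factors factor names (the model's FactorSet).
#' @param q hull quantile pair used for the pseudo-absence selection.
#' @return an object of class `niche_dataset`: a data.frame with a `role`
#'   column (`"presence"` / `"pseudo_absence"`) plus factor columns, and
#'   attributes `factors` and `q`.
#' @export
niche_dataset <- function(presences, pseudo_absences, factors, q) {
  if (nrow(presences) != nrow(pseudo_absences))
    stop("presence / pseudo-absence counts differ (",
         nrow(presences), " vs ", nrow(pseudo_absences), ")")
  df <- rbind(cbind(role = "presence", presences[c("cell", factors)]),
              cbind(role = "pseudo_absence", pseudo_absences[c("cell", factors)]))
  rownames(df) <- NULL
  structure(df, factors = factors, q = q, class = c("niche_dataset",
                                                    "data.frame"))
}

#' Build a niche dataset from an occurrence set and a stack
#'
#' Convenience wrapper: extract presence environments, filter them,
#' build the restricted hull, and draw matching pseudo-absences from the
#' ocean background.
#'
#' @param occ an `occurrence_set`.
#' @param stack contemporary `layer_stack`.
#' @param factors the FactorSet to model on.
#' @param q hull quantile pair.
#' @param bin_widths filtration bin widths.
#' @param seed integer seed for the pseudo-absence draw.
#' @return a `niche_dataset`.
#' @export
build_niche_dataset <- function(occ, stack, factors, q = c(10, 90),
                                bin_widths = default_bin_widths(),
                                seed = 1) {
  pres <- environmental_filter(env_points(stack, occ$cells, factors),
                               bin_widths)
  hull <- build_restricted_hull(pres, q)
  bg <- env_points(stack, ocean_cells(stack), factors)
  pa <- sample_pseudo_absences(bg, hull, n = nrow(pres),
                               bin_widths = bin_widths, seed = seed)
  nd <- niche_dataset(pres, pa, factors, q)
  attr(nd, "hull") <- hull
  nd
}
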