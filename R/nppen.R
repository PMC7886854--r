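# Non-Parametric Probabilistic Ecological Niche (NPPEN) model: a profile
# method that scores a test environment by its Mahalanobis distance to the
# reference (presence) cloud, converted to a probability by comparison with
# the reference distance distribution.

#' Fit an NPPEN model on filtered presences
#'
#' Stores the reference matrix `Z`, its mean `zbar` and covariance `V`
#' (ridged with `eps = 1e-6 * trace(V)/d` on the diagonal when
#' ill-conditioned), and the reference squared Mahalanobis distances
#' `D2_i = (z_i - zbar)' V^-1 (z_i - zbar)`.  By default distances are
#' computed against the full-sample mean/covariance; `leave_one_out = TRUE`
#' recomputes each reference distance against the cloud without that point.
#'
#' @param presences env-point data.frame or matrix of filtered presences
#'   (a `cell` column, if present, is ignored).
#' @param leave_one_out logical, see above (default `FALSE`).
#' @return an object of class `nppen_model`.
#' @export
fit_nppen <- function(presences, leave_one_out = FALSE) {
  df <- as.data.frame(presences)
  df$cell <- NULL
  Z <- as.matrix(df)
  n <- nrow(Z); d <- ncol(Z)
  if (n <= d)
    stop("NPPEN needs more reference points than factors (n = ", n,
         ", d = ", d, ")")
  sds <- apply(Z, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance factor(s): ",
         paste(colnames(Z)[sds == 0], collapse = ", "))
  zbar <- colMeans(Z)
  V <- stats::cov(Z)
  V <- ridge_spd(V)
  Vinv <- solve(V)
  D2 <- mahal_sq(Z, zbar, Vinv)
  structure(list(Z = Z, zbar = zbar, V = V, Vinv = Vinv,
                 D2_ref = if (leave_one_out) loo_distances(Z) else D2,
                 factors = colnames(Z), n = n, d = d,
                 leave_one_out = leave_one_out),
            class = "nppen_model")
}

# add a ridge when the covariance is singular or badly conditioned
ridge_spd <- function(V, kappa_max = 1e8) {
  d <- ncol(V)
  eps <- 1e-6 * sum(diag(V)) / d
  for (i in 0:40) {
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) < kappa_max) return(V)
    V <- V + eps * diag(d)
    eps <- eps * 2
  }
  stop("covariance could not be regularised")
}

mahal_sq <- function(X, center, Vinv) {
  Xc <- sweep(as.matrix(X), 2, center)
  rowSums((Xc %*% Vinv) * Xc)
}

loo_distances <- function(Z) {
  n <- nrow(Z)
  vapply(seq_len(n), function(i) {
    Zi <- Z[-i, , drop = FALSE]
    Vi <- ridge_spd(stats::cov(Zi))
    mahal_sq(Z[i, , drop = FALSE], colMeans(Zi), solve(Vi))
  }, numeric(1))
}

#' Predict the NPPEN environmental suitability index
#'
#' `ESI(x)` is the fraction of reference points at least as far from the
#' niche centre as `x`:
#' `ESI(x) = (1/n) * #\{i : D2_i >= D2(x)\}`, so `ESI(zbar) = 1`, points
#' beyond the farthest reference score 0, and ESI is non-increasing along
#' any ray from the centre.
#'
#' @param model an `nppen_model`.
#' @param newdata data.frame or matrix with the model's factor columns.
#' @return numeric vector of ESI values in `[0, 1]`.
#' @export
predict_nppen <- function(model, newdata) {
  df <- as.data.frame(newdata)
  miss <- setdiff(model$factors, names(df))
  if (length(miss))
    stop("newdata lacks factor(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(df[model$factors])
  D2 <- mahal_sq(X, model$zbar, model$Vinv)
  ref <- sort(model$D2_ref)
  # #\{ref >= d\} = n - #\{ref < d\}
  (model$n - findInterval(D2, ref, left.open = TRUE)) / model$n
}

#' @export
print.nppen_model <- function(x, ...) {
  cat(sprintf("<nppen_model> %d reference points, factors: %s\n",
              x$n, paste(x$factors, collapse = ", ")))
  invisible(x)
}
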