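# Classifier ensemble members fitted on presence / pseudo-absence niche
# datasets.  Members are standard algorithms behind a common prediction
# contract: any environmental point maps to a probability in [0, 1].
#
# Of the seven classifier families of the original ensemble design (GLM,
# GAM, GBM, ANN, FDA, MARS, RF), this installation provides GLM (stats),
# GAM (mgcv) and a self-contained single-hidden-layer ANN; the remaining
# algorithm ids are recognised but error with an informative message.

SUPPORTED_ALGORITHMS <- c("GLM", "GAM", "ANN")
KNOWN_ALGORITHMS <- c(SUPPORTED_ALGORITHMS, "GBM", "FDA", "MARS", "RF", "NPPEN")

#' Fit a classifier ensemble member
#'
#' Fits one algorithm on a presence / pseudo-absence dataset.  `"NPPEN"`
#' is accepted for convenience and dispatches to [fit_nppen()] on the
#' presence rows only (NPPEN needs no pseudo-absences).
#'
#' @param algorithm algorithm id: `"GLM"`, `"GAM"`, `"ANN"` or `"NPPEN"`
#'   (ids `"GBM"`, `"FDA"`, `"MARS"`, `"RF"` are recognised but not
#'   available in this installation).
#' @param data a `niche_dataset` (or data.frame with a `role` column and
#'   factor columns).
#' @param factors factor names to use (default: the dataset's FactorSet).
#' @param hyperparams named list of algorithm settings; defaults: GLM uses
#'   quadratic polynomials, GAM thin-plate splines with basis size
#'   `k = min(5, unique values - 1)`, ANN `hidden = 4`, `decay = 1e-3`,
#'   `maxit = 300`.
#' @param seed seed for stochastic initialisation (ANN).
#' @return an object of class `sdm_member` (or an `nppen_model`).
#' @export
fit_member <- function(algorithm, data, factors = NULL, hyperparams = list(),
                       seed = 1) {
  factors <- factors %||% attr(data, "factors") %||%
    setdiff(names(data), c("role", "cell"))
  if (!algorithm %in% KNOWN_ALGORITHMS)
    stop("unknown algorithm id '", algorithm, "'")
  if (algorithm == "NPPEN")
    return(fit_nppen(data[data$role == "presence", factors, drop = FALSE]))
  if (!algorithm %in% SUPPORTED_ALGORITHMS)
    stop("algorithm '", algorithm, "' is not available in this installation; ",
         "supported classifier members: ",
         paste(SUPPORTED_ALGORITHMS, collapse = ", "))
  if (!"role" %in% names(data)) stop("`data` must have a `role` column")
  y <- as.integer(data$role == "presence")
  if (length(unique(y)) < 2)
    stop("degenerate dataset: both presences and pseudo-absences required")
  X <- as.data.frame(data)[factors]
  fit <- switch(algorithm,
    GLM = fit_glm_member(X, y),
    GAM = fit_gam_member(X, y, hyperparams),
    ANN = fit_ann_member(X, y, hyperparams, seed))
  structure(list(algorithm = algorithm, fit = fit, factors = factors),
            class = "sdm_member")
}

fit_glm_member <- function(X, y) {
  terms <- vapply(names(X), function(f) {
    if (length(unique(X[[f]])) > 2) sprintf("poly(%s, 2)", f) else f
  }, character(1))
  df <- cbind(y = y, X)
  stats::glm(stats::reformulate(terms, "y"), family = stats::binomial(),
             data = df)
}

fit_gam_member <- function(X, y, hp) {
  terms <- vapply(names(X), function(f) {
    k <- min(hp$k %||% 5, length(unique(X[[f]])) - 1)
    if (k >= 3) sprintf("s(%s, k = %d)", f, k) else f
  }, character(1))
  df <- cbind(y = y, X)
  mgcv::gam(stats::reformulate(terms, "y"), family = stats::binomial(),
            data = df, method = "REML")
}

# Single-hidden-layer neural network (logistic activations) trained by
# BFGS on the ridge-penalised binomial log-loss.  Inputs are standardised;
# initial weights are small uniforms under `seed`, so the fit is
# deterministic given (data, hyperparams, seed).
fit_ann_member <- function(X, y, hp, seed) {
  H <- hp$hidden %||% 4L
  decay <- hp$decay %||% 1e-3
  maxit <- hp$maxit %||% 300L
  Xm <- as.matrix(X)
  mu <- colMeans(Xm); sdv <- pmax(apply(Xm, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(Xm, 2, mu), 2, sdv, "/")
  n <- nrow(Xs); d <- ncol(Xs)
  n_w1 <- (d + 1) * H
  unpack <- function(th) list(W1 = matrix(th[seq_len(n_w1)], d + 1, H),
                              w2 = th[n_w1 + seq_len(H + 1)])
  sigm <- function(z) 1 / (1 + exp(-z))
  fwd <- function(p, Xs) {
    A <- sigm(cbind(1, Xs) %*% p$W1)          # n x H
    list(A = A, p = sigm(cbind(1, A) %*% p$w2)[, 1])
  }
  loss <- function(th) {
    p <- unpack(th)
    pr <- pmin(pmax(fwd(p, Xs)$p, 1e-12), 1 - 1e-12)
    -mean(y * log(pr) + (1 - y) * log(1 - pr)) + decay * sum(th^2)
  }
  grad <- function(th) {
    p <- unpack(th); f <- fwd(p, Xs)
    err <- (f$p - y) / n                       # d loss / d (pre-sigmoid out)
    g_w2 <- crossprod(cbind(1, f$A), err)[, 1]
    dA <- tcrossprod(err, p$w2[-1]) * f$A * (1 - f$A)
    g_W1 <- crossprod(cbind(1, Xs), dA)
    c(as.vector(g_W1), g_w2) + 2 * decay * th
  }
  th0 <- with_seed(seed, stats::runif(n_w1 + H + 1, -0.5, 0.5))
  opt <- stats::optim(th0, loss, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  list(theta = opt$par, unpack = NULL, H = H, mu = mu, sd = sdv,
       decay = decay, value = opt$value)
}

predict_ann <- function(fit, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, fit$mu), 2, fit$sd, "/")
  d <- ncol(Xs); H <- fit$H
  W1 <- matrix(fit$theta[seq_len((d + 1) * H)], d + 1, H)
  w2 <- fit$theta[(d + 1) * H + seq_len(H + 1)]
  sigm <- function(z) 1 / (1 + exp(-z))
  A <- sigm(cbind(1, Xs) %*% W1)
  sigm(cbind(1, A) %*% w2)[, 1]
}

#' Predict from a fitted member
#'
#' @param member an `sdm_member`.
#' @param newdata data.frame with the member's factor columns.
#' @return numeric vector in `[0, 1]`.
#' @export
predict_member <- function(member, newdata) {
  X <- as.data.frame(newdata)[member$factors]
  p <- switch(member$algorithm,
    GLM = as.numeric(stats::predict(member$fit, X, type = "response")),
    GAM = as.numeric(mgcv::predict.gam(member$fit, X, type = "response")),
    ANN = predict_ann(member$fit, X))
  pmin(pmax(p, 0), 1)
}

#' @export
print.sdm_member <- function(x, ...) {
  cat(sprintf("<sdm_member> %s on factors: %s\n", x$algorithm,
              paste(x$factors, collapse = ", ")))
  invisible(x)
}

#' Model ESI prediction generic
#'
#' Common prediction surface over NPPEN models, classifier members and
#' ensembles: environmental points in, suitability in `[0, 1]` out.
#'
#' @param object fitted model object.
#' @param newdata data.frame of environmental points.
#' @return numeric vector in `[0, 1]`.
#' @export
predict_esi <- function(object, newdata) UseMethod("predict_esi")

#' @export
predict_esi.nppen_model <- function(object, newdata) predict_nppen(object, newdata)

#' @export
predict_esi.sdm_member <- function(object, newdata) predict_member(object, newdata)

model_factors <- function(object) {
  if (inherits(object, "ensemble_model")) object$factors else object$factors
}
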