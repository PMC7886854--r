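# Model evaluation and ensemble selection: repeated 70/30 cross-validation,
# the Continuous Boyce Index, response-curve screening, and the selection
# of the final ensemble (the Table-2-style report).

#' Stratified random cross-validation splits
#'
#' Ten (by default) independent random splits of a niche dataset into 70%
#' calibration / 30% evaluation, stratified by role so both presences and
#' pseudo-absences appear in both parts of every replicate.
#'
#' @param data a `niche_dataset`.
#' @param n_rep number of replicates (default 10).
#' @param frac calibration fraction (default 0.7).
#' @param seed integer seed.
#' @return list of splits, each with `replicate`, `cal`, `eval` row
#'   indices; per replicate `cal` and `eval` are disjoint and exhaustive.
#' @export
make_cv_splits <- function(data, n_rep = 10, frac = 0.7, seed = 1) {
  if (!nrow(data)) stop("empty dataset")
  roles <- split(seq_len(nrow(data)), data$role)
  if (any(vapply(roles, length, integer(1)) < 2))
    stop("every class needs at least 2 points for a stratified split")
  with_seed(seed, lapply(seq_len(n_rep), function(r) {
    cal <- unname(unlist(lapply(roles, function(idx)
      sample(idx, floor(frac * length(idx))))))
    list(replicate = r, cal = sort(cal),
         eval = sort(setdiff(seq_len(nrow(data)), cal)))
  }))
}

#' Continuous Boyce Index
#'
#' Moving-window comparison of the suitability values at evaluation
#' presences against the background suitability distribution.  For window
#' midpoints `m` on a regular grid in `[0, 1]`, `P(m)` is the fraction of
#' presence predictions and `E(m)` the fraction of background predictions
#' falling in `[m - w/2, m + w/2]`; windows with `E = 0` are dropped and
#' the CBI is the Spearman rank correlation between `m` and `P/E`.
#' A model that ranks habitat perfectly gives 1; a random one gives ~0.
#'
#' @param pred_presence suitability at evaluation presences, in `[0, 1]`.
#' @param pred_background suitability over the background (all ocean cells
#'   of the calibration domain).
#' @param w window width (default 0.1).
#' @param n_windows number of midpoints (default 101).
#' @return an object of class `cbi_result`: list with `cbi`, `w`,
#'   `midpoints`, `pe` (P/E ratios of the retained windows).
#' @export
continuous_boyce_index <- function(pred_presence, pred_background,
                                   w = 0.1, n_windows = 101) {
  if (!length(pred_presence)) stop("need at least one presence prediction")
  rng <- range(c(pred_presence, pred_background), na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("predictions must lie in [0, 1]")
  m <- seq(0, 1, length.out = n_windows)
  count_in <- function(x, mid) {
    vapply(mid, function(mm) sum(x >= mm - w / 2 & x <= mm + w / 2),
           numeric(1)) / length(x)
  }
  P <- count_in(pred_presence, m)
  E <- count_in(pred_background, m)
  keep <- E > 0
  if (!any(keep)) stop("all windows have zero expected (background) fraction")
  pe <- P[keep] / E[keep]
  cbi <- if (stats::sd(pe) == 0) 0 else
    suppressWarnings(stats::cor(m[keep], pe, method = "spearman"))
  structure(list(cbi = cbi, w = w, midpoints = m[keep], pe = pe),
            class = "cbi_result")
}

#' @export
print.cbi_result <- function(x, ...) {
  cat(sprintf("<cbi_result> CBI = %.3f over %d windows (w = %g)\n",
              x$cbi, length(x$midpoints), x$w))
  invisible(x)
}

#' Response curve of a fitted member along one factor
#'
#' Predictions along the factor's observed range over ocean cells, all
#' other factors held at their presence-cell medians.
#'
#' @param member fitted model (NPPEN, classifier member or ensemble).
#' @param factor factor name.
#' @param stack a `layer_stack` (provides the observed range).
#' @param presences presence env-points (provide the medians).
#' @param n_points curve length (default 100).
#' @return data.frame with columns `x` and `esi`.
#' @export
response_curve <- function(member, factor, stack, presences, n_points = 100) {
  fs <- model_factors(member)
  if (!factor %in% fs)
    stop("factor '", factor, "' is not in the member's factor set")
  rng <- range(stack$factors[[factor]], na.rm = TRUE)
  xs <- seq(rng[1], rng[2], length.out = n_points)
  env <- as.data.frame(lapply(fs, function(f) {
    if (f == factor) xs else rep(stats::median(presences[[f]]), n_points)
  }), col.names = fs)
  data.frame(x = xs, esi = predict_esi(member, env))
}

#' Screen a response curve for spurious shape
#'
#' Smooths the curve with a centred moving average and fails it when the
#' smoothed curve has two or more interior local maxima (a bimodal or
#' otherwise spurious response, e.g. to temperature).  Monotone or
#' unimodal curves pass.
#'
#' @param curve data.frame from [response_curve()].
#' @param smoothing_window moving-average window length (odd, default 5).
#' @return list with `pass` (logical), `n_peaks`, `reason`.
#' @export
screen_curve <- function(curve, smoothing_window = 5) {
  y <- curve$esi
  if (any(!is.finite(y))) stop("curve contains non-finite values")
  k <- max(1L, smoothing_window)
  if (k %% 2 == 0) k <- k + 1L
  if (k > 1 && length(y) >= k) {
    sm <- stats::filter(y, rep(1 / k, k), sides = 2)
    pad <- (k - 1) / 2
    sm[seq_len(pad)] <- sm[pad + 1]
    sm[length(y) - seq_len(pad) + 1] <- sm[length(y) - pad]
    y <- as.numeric(sm)
  }
  # collapse plateaus, then count sign changes +1 -> -1 (interior maxima)
  s <- sign(diff(y))
  s <- s[s != 0]
  n_peaks <- if (length(s) < 2) 0L else sum(s[-length(s)] == 1 & s[-1] == -1)
  if (n_peaks >= 2)
    list(pass = FALSE, n_peaks = n_peaks, reason = "bimodal")
  else list(pass = TRUE, n_peaks = n_peaks, reason = NA_character_)
}

#' Cross-validated CBI of one algorithm on one configuration
#'
#' For each CV replicate, fits the algorithm on the calibration part
#' (NPPEN on calibration presences only) and computes the CBI of its
#' predictions at the evaluation presences against the ocean background.
#'
#' @param algorithm algorithm id.
#' @param data a `niche_dataset`.
#' @param splits CV splits from [make_cv_splits()].
#' @param background env-point data.frame of all calibration-domain ocean
#'   cells (the CBI expectation).
#' @param seed base seed for stochastic members.
#' @return list with `mean_cbi`, `cbi` (per replicate), `members`
#'   (fitted per-replicate models).
#' @export
cv_evaluate_member <- function(algorithm, data, splits, background, seed = 1) {
  factors <- attr(data, "factors")
  bg_pred_of <- function(m) predict_esi(m, background)
  cbis <- numeric(length(splits))
  members <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    cal <- data[sp$cal, , drop = FALSE]
    attr(cal, "factors") <- factors
    m <- fit_member(algorithm, cal, factors,
                    seed = derive_seed(seed, paste0(algorithm, sp$replicate)))
    ev <- data[sp$eval, , drop = FALSE]
    ev_pres <- ev[ev$role == "presence", factors, drop = FALSE]
    cb <- continuous_boyce_index(predict_esi(m, ev_pres), bg_pred_of(m))
    cbis[i] <- cb$cbi
    members[[i]] <- m
  }
  list(mean_cbi = mean(cbis), cbi = cbis, members = members)
}

#' Select the ensemble model
#'
#' Evaluates every candidate (FactorSet x hull quantile x algorithm)
#' combination by mean cross-validated CBI and response-curve screening,
#' then retains, within the best configuration, every algorithm with mean
#' CBI above the threshold and all response curves passing.  The best
#' configuration is the (FactorSet, q) pair with the highest mean CBI over
#' its retained algorithms; ties are broken by fewer factors, then by the
#' wider hull quantile (10-90 first).
#'
#' @param occ an `occurrence_set`.
#' @param stack contemporary `layer_stack`.
#' @param factor_sets list of candidate FactorSets
#'   (default [candidate_factor_sets()] on SBT/SBTrange).
#' @param quantile_pairs list of hull quantile pairs (default the three
#'   study designs).
#' @param algorithms algorithm ids to try (default NPPEN + the available
#'   classifiers).
#' @param threshold CBI validation threshold (default 0.5: a member is
#'   statistically validated for CBI values over 0.5).
#' @param n_rep CV replicates (default 10).
#' @param bin_widths filtration bin widths.
#' @param filters hierarchical-filter settings stored on the ensemble.
#' @param seed integer seed.
#' @return list with `ensemble` (an `ensemble_model` of all retained
#'   algorithm x replicate members), `report` (one row per candidate
#'   configuration x algorithm: factors, algorithm, quantiles, mean CBI,
#'   curve screen, retained flag) and `selection` (the winning row
#'   summary).
#' @export
select_ensemble <- function(occ, stack,
                            factor_sets = candidate_factor_sets(c("SBT", "SBTrange")),
                            quantile_pairs = list(c(2.5, 97.5), c(5, 95), c(10, 90)),
                            algorithms = c("NPPEN", "GLM", "GAM", "ANN"),
                            threshold = 0.5, n_rep = 10,
                            bin_widths = default_bin_widths(),
                            filters = list(depth_max = 300,
                                           coast_enabled = FALSE,
                                           coast_km = 50),
                            seed = 1) {
  rows <- list(); fitted <- list()
  for (fi in seq_along(factor_sets)) {
    fs <- factor_sets[[fi]]
    for (qi in seq_along(quantile_pairs)) {
      q <- quantile_pairs[[qi]]
      cfg <- sprintf("fs%d_q%g", fi, q[1])
      nd <- tryCatch(
        build_niche_dataset(occ, stack, fs, q, bin_widths,
                            seed = derive_seed(seed, paste0("pa_", cfg))),
        error = function(e) e)
      if (inherits(nd, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          factors = paste(fs, collapse = "+"), q_low = q[1], q_high = q[2],
          algorithm = NA, mean_cbi = NA, curves_pass = NA, retained = FALSE,
          note = conditionMessage(nd))
        next
      }
      splits <- make_cv_splits(nd, n_rep = n_rep,
                               seed = derive_seed(seed, paste0("cv_", cfg)))
      background <- env_points(stack, ocean_cells(stack), fs)[fs]
      pres <- nd[nd$role == "presence", , drop = FALSE]
      for (alg in algorithms) {
        res <- tryCatch(
          cv_evaluate_member(alg, nd, splits, background,
                             seed = derive_seed(seed, paste0(alg, cfg))),
          error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1]] <- data.frame(
            factors = paste(fs, collapse = "+"), q_low = q[1], q_high = q[2],
            algorithm = alg, mean_cbi = NA, curves_pass = NA,
            retained = FALSE, note = conditionMessage(res))
          next
        }
        full_attr <- nd; attr(full_attr, "factors") <- fs
        full <- fit_member(alg, full_attr, fs,
                           seed = derive_seed(seed, paste0("full", alg, cfg)))
        curves_ok <- all(vapply(fs, function(f)
          screen_curve(response_curve(full, f, stack, pres))$pass, logical(1)))
        retained <- isTRUE(res$mean_cbi > threshold) && curves_ok
        key <- paste(fi, qi, alg, sep = "_")
        fitted[[key]] <- list(fs = fs, q = q, alg = alg, res = res,
                              retained = retained, fi = fi, qi = qi)
        rows[[length(rows) + 1]] <- data.frame(
          factors = paste(fs, collapse = "+"), q_low = q[1], q_high = q[2],
          algorithm = alg, mean_cbi = res$mean_cbi, curves_pass = curves_ok,
          retained = retained, note = "")
      }
    }
  }
  report <- do.call(rbind, rows)
  retained_keys <- names(fitted)[vapply(fitted, `[[`, logical(1), "retained")]
  if (!length(retained_keys))
    stop("empty selection: no candidate reached CBI > ", threshold,
         " with admissible response curves")
  # score each (FactorSet, q) configuration by the mean CBI of its
  # retained algorithms; break ties by fewer factors then wider quantile
  cfgs <- unique(t(vapply(fitted[retained_keys], function(f)
    c(f$fi, f$qi), numeric(2))))
  score <- apply(cfgs, 1, function(cg) {
    ks <- retained_keys[vapply(fitted[retained_keys], function(f)
      f$fi == cg[1] && f$qi == cg[2], logical(1))]
    mean(vapply(fitted[ks], function(f) f$res$mean_cbi, numeric(1)))
  })
  nfac <- vapply(cfgs[, 1], function(fi) length(factor_sets[[fi]]), numeric(1))
  qlow <- vapply(cfgs[, 2], function(qi) quantile_pairs[[qi]][1], numeric(1))
  best <- order(-round(score, 10), nfac, -qlow)[1]
  bi <- cfgs[best, 1]; bq <- cfgs[best, 2]
  win <- retained_keys[vapply(fitted[retained_keys], function(f)
    f$fi == bi && f$qi == bq, logical(1))]
  members <- list(); labels <- character(); cbi_rows <- list()
  for (k in win) {
    f <- fitted[[k]]
    for (r in seq_along(f$res$members)) {
      members[[length(members) + 1]] <- f$res$members[[r]]
      labels <- c(labels, sprintf("%s_rep%02d", f$alg, r))
      cbi_rows[[length(cbi_rows) + 1]] <-
        data.frame(algorithm = f$alg, replicate = r, cbi = f$res$cbi[r])
    }
  }
  ens <- ensemble_model(members, factor_sets[[bi]], quantile_pairs[[bq]],
                        filters = filters, cbi = do.call(rbind, cbi_rows),
                        member_labels = labels)
  selection <- data.frame(
    species = occ$species,
    factors = paste(factor_sets[[bi]], collapse = "+"),
    algorithms = paste(unique(vapply(fitted[win], `[[`, character(1), "alg")),
                       collapse = ", "),
    q_low = quantile_pairs[[bq]][1], q_high = quantile_pairs[[bq]][2],
    coast_km = if (isTRUE(filters$coast_enabled)) filters$coast_km else 0,
    depth_max = filters$depth_max,
    cbi = score[best])
  rownames(selection) <- NULL
  list(ensemble = ens, report = report, selection = selection)
}
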