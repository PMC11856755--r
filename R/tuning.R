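#' Candidate model space: RM ladder x feature-class subsets
#'
#' The Cartesian product of a regularization-multiplier ladder with every
#' non-empty subset of the five feature classes (31 subsets); the default
#' ladder 0.1, 0.2, ..., 5.0 gives 50 x 31 = 1550 candidates. The ladder
#' starts at 0.1 rather than 0: a fully unpenalized fit is degenerate for
#' hinge/threshold-rich designs.
#'
#' @param rm_min,rm_max,rm_step Ladder limits and step.
#' @param classes Feature classes to form subsets of.
#' @return Data.frame with columns `rm` and `fc`.
#' @export
candidate_space <- function(rm_min = 0.1, rm_max = 5.0, rm_step = 0.1,
                            classes = c("L", "Q", "H", "P", "T")) {
  if (rm_step <= 0) stop("`rm_step` must be positive")
  rms <- seq(rm_min, rm_max, by = rm_step)
  if (!length(rms)) stop("empty RM ladder")
  subsets <- unlist(lapply(seq_along(classes), function(k)
    utils::combn(classes, k, paste, collapse = "", simplify = FALSE)))
  out <- expand.grid(rm = rms, fc = unlist(subsets),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[order(out$fc, out$rm), c("rm", "fc")][seq_len(nrow(out)), ] ->
    out
  rownames(out) <- NULL
  out
}

#' Maxent log-likelihood over a scoring domain
#'
#' The raw suitability is renormalized over all unmasked cells of the
#' scoring stack (the full projection grid) and the log of that
#' probability is summed over the presence cells — the likelihood
#' convention of the ENM model-selection literature.
#'
#' @param model A `maxent_model`.
#' @param pres_lonlat Data.frame/matrix of presence `lon`, `lat`.
#' @param stack Scoring `suit_stack`.
#' @return Log-likelihood (a single number).
#' @export
maxent_log_lik <- function(model, pres_lonlat, stack) {
  stopifnot_stack(stack)
  tab <- stack_table(stack)
  eta_all <- maxent_eta(model, tab$values)
  logZ <- lse(eta_all)
  loc <- grid_locate(stack$layers[[1]], pres_lonlat[, "lon"],
                     pres_lonlat[, "lat"])
  pos <- match(loc$cell, tab$cells)
  if (any(is.na(pos)))
    stop(sprintf("presence(s) on masked/off-grid cells: rows %s",
                 paste(which(is.na(pos)), collapse = ", ")))
  sum(eta_all[pos] - logZ)
}

#' Corrected Akaike information criterion
#'
#' `AIC = 2k - 2 log L`; `AICc = AIC + 2k(k+1)/(n-k-1)`, undefined
#' (returned as `NA`, disqualifying the candidate) when `n <= k + 1`.
#'
#' @param log_lik Log-likelihood.
#' @param k Number of (nonzero) model parameters.
#' @param n Number of presences.
#' @return AICc, or `NA_real_` if undefined.
#' @export
aicc <- function(log_lik, k, n) {
  if (n <= k + 1) return(NA_real_)
  2 * k - 2 * log_lik + 2 * k * (k + 1) / (n - k - 1)
}

#' Omission rates of test presences
#'
#' `or_mtp`: fraction of test predictions strictly below the minimum
#' training prediction. `or_10`: fraction strictly below the nearest-rank
#' 10th percentile of the training predictions.
#'
#' @param train_preds,test_preds Numeric prediction vectors.
#' @return Named vector `c(or_mtp, or_10)`.
#' @export
omission_rates <- function(train_preds, test_preds) {
  if (!length(train_preds) || !length(test_preds))
    stop("both prediction sets must be non-empty")
  mtp <- min(train_preds)
  # nearest-rank percentile: smallest value with rank >= ceil(0.1 n)
  st <- sort(train_preds)
  q10 <- st[max(1L, ceiling(0.1 * length(st)))]
  c(or_mtp = mean(test_preds < mtp), or_10 = mean(test_preds < q10))
}

# sensitivity (y) vs proportion-of-area (x) curve over all thresholds
proc_curve <- function(pres, bg) {
  thr <- sort(unique(c(pres, bg)))
  sb <- sort(bg); sp <- sort(pres)
  # tail proportions: share of values >= t
  x <- (length(sb) - findInterval(thr, sb, left.open = TRUE)) / length(sb)
  y <- (length(sp) - findInterval(thr, sp, left.open = TRUE)) / length(sp)
  # add the (1,1) end (threshold below everything)
  x <- c(1, x); y <- c(1, y)
  ord <- order(x, y)
  list(x = x[ord], y = y[ord])
}

# trapezoid area under y(x) restricted to y >= 1 - E, with interpolation
# at the crossing; also the area under the diagonal over the same x-range
partial_areas <- function(x, y, E) {
  ymin <- 1 - E
  n <- length(x)
  x0 <- x[-n]; x1 <- x[-1]; y0 <- y[-n]; y1 <- y[-1]
  live <- x1 > x0 & !(y0 < ymin & y1 < ymin)
  x0 <- x0[live]; x1 <- x1[live]; y0 <- y0[live]; y1 <- y1[live]
  if (!length(x0)) return(c(keep = 0, null = 0))
  # clip segments crossing y = ymin at the intersection point
  cross_lo <- y0 < ymin & y1 >= ymin
  cross_hi <- y0 >= ymin & y1 < ymin
  t_lo <- (ymin - y0[cross_lo]) / (y1[cross_lo] - y0[cross_lo])
  x0[cross_lo] <- x0[cross_lo] + t_lo * (x1[cross_lo] - x0[cross_lo])
  y0[cross_lo] <- ymin
  t_hi <- (ymin - y0[cross_hi]) / (y1[cross_hi] - y0[cross_hi])
  x1[cross_hi] <- x0[cross_hi] + t_hi * (x1[cross_hi] - x0[cross_hi])
  y1[cross_hi] <- ymin
  c(keep = sum((x1 - x0) * (y0 + y1) / 2),
    null = sum((x1 - x0) * (x0 + x1) / 2))
}

#' Partial-ROC AUC ratio with bootstrap significance
#'
#' Restricts the ROC-like curve of sensitivity against proportion of
#' area predicted present to omission at most `E`, and divides its area
#' by the corresponding area under the random-prediction diagonal. The
#' ratio is averaged over bootstrap resamples of the test presences
#' (`boot_frac` of them, with replacement); the p-value is the fraction
#' of resamples with ratio <= 1.
#'
#' @param test_pres Predictions at test presences.
#' @param bg_preds Predictions at background cells (proportion-of-area
#'   reference).
#' @param E Tolerated omission (default 0.05).
#' @param n_boot Bootstrap resamples (default 500).
#' @param boot_frac Resample fraction (default 0.5).
#' @param seed Seed.
#' @return List `ratio`, `p`, `ratios` (per-resample).
#' @export
partial_roc <- function(test_pres, bg_preds, E = 0.05, n_boot = 500,
                        boot_frac = 0.5, seed = 1L) {
  if (E <= 0 || E >= 0.5) stop("`E` must be in (0, 0.5)")
  if (length(test_pres) < 5L) stop("need at least 5 test presences")
  set.seed(seed)
  k <- max(2L, round(boot_frac * length(test_pres)))
  ratios <- vapply(seq_len(n_boot), function(b) {
    ps <- test_pres[sample.int(length(test_pres), k, replace = TRUE)]
    cv <- proc_curve(ps, bg_preds)
    a <- partial_areas(cv$x, cv$y, E)
    if (a["null"] <= 0) return(NA_real_)
    unname(a["keep"] / a["null"])
  }, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  list(ratio = mean(ratios), p = mean(ratios <= 1), ratios = ratios)
}

#' Score one tuning candidate
#'
#' Fits the model at (`rm`, `fc`) on the training share, and records the
#' nonzero-coefficient count, full-grid log-likelihood, AICc, omission
#' rates, and partial-ROC result.
#'
#' @param rm,fc Candidate settings (`fc` like `"LQT"`).
#' @param train_values,test_values Presence matrices (variables in
#'   columns) for the training and held-out shares.
#' @param train_lonlat Training presence coordinates (for the AICc
#'   likelihood), data.frame with `lon`, `lat`; may be `NULL` when
#'   `stack` is `NULL`.
#' @param background A [sample_background()] result.
#' @param stack Scoring stack for the likelihood normalization; `NULL`
#'   normalizes over the background sample instead of the full grid.
#' @param hinge_knots,threshold_knots Knot counts for H/T features.
#' @param proc_seed Seed for the partial-ROC bootstrap.
#' @return One-row data.frame of candidate scores.
#' @export
score_candidate <- function(rm, fc, train_values, test_values, train_lonlat,
                            background, stack, hinge_knots = 10,
                            threshold_knots = 10, proc_seed = 1L) {
  spec <- feature_spec(fc, hinge_knots, threshold_knots)
  model <- fit_maxent(train_values, background, spec, rm)
  k <- sum(model$lambda != 0)
  ll <- if (is.null(stack)) {
    logZ <- lse(maxent_eta(model, background$values))
    sum(maxent_eta(model, as.matrix(train_values)) - logZ)
  } else maxent_log_lik(model, train_lonlat, stack)
  tr_pred <- predict(model, train_values)
  te_pred <- predict(model, test_values)
  or <- omission_rates(tr_pred, te_pred)
  pr <- partial_roc(te_pred, predict(model, background$values),
                    seed = proc_seed)
  data.frame(rm = rm, fc = fc, k = k, log_lik = ll,
             aicc = aicc(ll, k, nrow(train_values)),
             or_mtp = unname(or["or_mtp"]), or_10 = unname(or["or_10"]),
             proc_ratio = pr$ratio, proc_p = pr$p)
}

#' Select the champion candidate
#'
#' Filters to statistically significant candidates (`proc_p < 0.05`),
#' then to those with `or_10 <= or_cap`; if either filter empties the
#' set it is relaxed with a warning. Among survivors the lowest AICc
#' wins; ties go to fewer parameters, then smaller rm.
#'
#' @param scores Data.frame of candidate scores (see [score_candidate()]).
#' @param or_cap Omission cap on `or_10` (default 0.1).
#' @return The champion row (with attribute `selected_index`).
#' @export
select_champion <- function(scores, or_cap = 0.1) {
  if (!nrow(scores)) stop("no candidates to select from")
  pool <- scores
  sig <- pool$proc_p < 0.05 & !is.na(pool$proc_p)
  if (any(sig)) pool <- pool[sig, , drop = FALSE]
  else warning("no candidate is partial-ROC significant; relaxing the filter")
  lowom <- pool$or_10 <= or_cap & !is.na(pool$or_10)
  if (any(lowom)) pool <- pool[lowom, , drop = FALSE]
  else warning("no candidate meets the omission cap; relaxing the filter")
  ok <- !is.na(pool$aicc)
  if (any(ok)) pool <- pool[ok, , drop = FALSE]
  ord <- order(pool$aicc, pool$k, pool$rm)
  champ <- pool[ord[1], , drop = FALSE]
  attr(champ, "selected_index") <- as.integer(rownames(champ))
  champ
}

#' Tune over a candidate grid
#'
#' Scores every (rm, fc) candidate on a fixed train/test split and
#' selects the champion.
#'
#' @param candidates Data.frame from [candidate_space()].
#' @param pres_values Presence matrix.
#' @param pres_lonlat Presence coordinates (`lon`, `lat`).
#' @param background A [sample_background()] result.
#' @param stack Scoring stack.
#' @param test_fraction Held-out share for scoring (default 0.25).
#' @param seed Split / bootstrap seed.
#' @param hinge_knots,threshold_knots Knot counts.
#' @return List `scores` (data.frame with `selected` flag) and
#'   `champion` (row).
#' @export
tune_candidates <- function(candidates, pres_values, pres_lonlat, background,
                            stack, test_fraction = 0.25, seed = 1L,
                            hinge_knots = 10, threshold_knots = 10) {
  pv <- as.matrix(pres_values)
  n <- nrow(pv)
  set.seed(seed)
  test_idx <- sort(sample.int(n, round(n * test_fraction)))
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    score_candidate(candidates$rm[i], candidates$fc[i],
                    pv[-test_idx, , drop = FALSE],
                    pv[test_idx, , drop = FALSE],
                    pres_lonlat[-test_idx, , drop = FALSE],
                    background, stack, hinge_knots, threshold_knots,
                    proc_seed = seed + i)
  })
  scores <- do.call(rbind, rows)
  champ <- select_champion(scores)
  scores$selected <- seq_len(nrow(scores)) %in% attr(champ, "selected_index")
  list(scores = scores, champion = champ)
}
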