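#' Pseudo-absence points for threshold-based evaluation
#'
#' Draws exactly as many pseudo-absence points as there are evaluation
#' presences — a prevalence of 50% — uniformly from unmasked cells not
#' occupied by an evaluation presence.
#'
#' @param n_presences Number of evaluation presences.
#' @param region A `suit_grid` defining the candidate cells.
#' @param presence_cells Linear cell indices occupied by evaluation
#'   presences (excluded from the draw).
#' @param seed Seed.
#' @return Data.frame `lon`, `lat`, `cell`.
#' @export
pseudo_absences_for_eval <- function(n_presences, region,
                                     presence_cells = integer(0), seed = 1L) {
  stopifnot_grid(region)
  if (n_presences == 0L)
    return(data.frame(lon = numeric(0), lat = numeric(0), cell = integer(0)))
  avail <- setdiff(which(!is.na(region$values)), presence_cells)
  if (length(avail) < n_presences)
    stop(sprintf("only %d free cells for %d pseudo-absences",
                 length(avail), n_presences))
  set.seed(seed)
  pick <- sort(avail[sample.int(length(avail), n_presences)])
  nr <- nrow(region$values)
  row <- ((pick - 1L) %% nr) + 1L
  col <- ((pick - 1L) %/% nr) + 1L
  data.frame(lon = region$x_origin + (col - 0.5) * region$cell_size,
             lat = region$y_origin + (nr - row + 0.5) * region$cell_size,
             cell = pick)
}

#' Confusion table at a threshold
#'
#' A prediction at or above the threshold counts as "suitable".
#'
#' @param threshold Classification threshold.
#' @param presence_preds,absence_preds Numeric prediction vectors.
#' @return List `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at <- function(threshold, presence_preds, absence_preds) {
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  list(tp = sum(presence_preds >= threshold),
       fn = sum(presence_preds < threshold),
       fp = sum(absence_preds >= threshold),
       tn = sum(absence_preds < threshold))
}

#' Threshold-dependent accuracy metrics
#'
#' TSS = sensitivity + specificity - 1; Cohen's Kappa from the marginal
#' expected agreement; Jaccard = tp/(tp+fn+fp); Sorensen =
#' 2tp/(2tp+fn+fp) (identically `2J/(1+J)`). Undefined denominators give
#' `NA`.
#'
#' @param conf Confusion list from [confusion_at()].
#' @return Named vector `tss`, `kappa`, `jaccard`, `sorensen`.
#' @export
confusion_metrics <- function(conf) {
  tp <- conf$tp; fp <- conf$fp; fn <- conf$fn; tn <- conf$tn
  n <- tp + fp + fn + tn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tss <- sens + spec - 1
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - pe) > 1e-300) (po - pe) / (1 - pe) else NA_real_
  jac <- if (tp + fn + fp > 0) tp / (tp + fn + fp) else NA_real_
  sor <- if (2 * tp + fn + fp > 0) 2 * tp / (2 * tp + fn + fp) else NA_real_
  c(tss = tss, kappa = kappa, jaccard = jac, sorensen = sor)
}

#' Sorensen index from a Jaccard index
#'
#' The two overlap indices are linked algebraically:
#' `S = 2J / (1 + J)`.
#'
#' @param jaccard Jaccard index in [0, 1].
#' @return Sorensen index in [0, 1].
#' @export
sorensen_from_jaccard <- function(jaccard) {
  if (any(jaccard < 0 | jaccard > 1)) stop("`jaccard` must be in [0, 1]")
  2 * jaccard / (1 + jaccard)
}

#' Rank-based AUC
#'
#' Mann-Whitney AUC: the probability that a random presence outranks a
#' random absence, ties counted one half.
#'
#' @param presence_preds,absence_preds Numeric prediction vectors.
#' @return AUC in [0, 1].
#' @export
auc <- function(presence_preds, absence_preds) {
  n1 <- length(presence_preds); n0 <- length(absence_preds)
  if (!n1 || !n0) stop("both prediction sets must be non-empty")
  r <- rank(c(presence_preds, absence_preds), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximizing the true skill statistic
#'
#' Scans every unique predicted value plus a uniform ladder over [0, 1];
#' ties go to the lowest threshold.
#'
#' @param presence_preds,absence_preds Numeric prediction vectors.
#' @param step Ladder spacing (default 0.001).
#' @return List `threshold`, `tss`.
#' @export
max_tss_threshold <- function(presence_preds, absence_preds, step = 0.001) {
  if (!length(presence_preds) || !length(absence_preds))
    stop("both prediction sets must be non-empty")
  cand <- sort(unique(c(presence_preds, absence_preds,
                        seq(0, 1, by = step))))
  tss <- vapply(cand, function(t) {
    unname(confusion_metrics(confusion_at(t, presence_preds,
                                          absence_preds))["tss"])
  }, numeric(1))
  best <- which.max(tss)   # which.max returns the first (lowest) maximizer
  list(threshold = cand[best], tss = tss[best])
}

#' Continuous Boyce index
#'
#' Slides `n_windows` windows of width `window_frac` times the prediction
#' range across that range; in each, the predicted-to-expected ratio
#' P/E = (presence share in window)/(background share in window).
#' Windows with empty background are skipped. The index is the Spearman
#' rank correlation of P/E with the window midpoints.
#'
#' @param presence_preds Predictions at presences (>= 10).
#' @param background_preds Predictions over the background/region.
#' @param n_windows Number of windows (default 101).
#' @param window_frac Window width as a fraction of the range (default 0.1).
#' @return Boyce index in [-1, 1], or `NA` if every window is degenerate.
#' @export
boyce <- function(presence_preds, background_preds, n_windows = 101,
                  window_frac = 0.1) {
  if (length(presence_preds) < 10L) stop("need at least 10 presences")
  lo <- min(background_preds); hi <- max(background_preds)
  if (hi <= lo) return(NA_real_)
  w <- window_frac * (hi - lo)
  starts <- seq(lo, hi - w, length.out = n_windows)
  pe <- mid <- numeric(0)
  for (s in starts) {
    inb <- background_preds >= s & background_preds <= s + w
    if (!any(inb)) next
    inp <- presence_preds >= s & presence_preds <= s + w
    pe <- c(pe, mean(inp) / mean(inb))
    mid <- c(mid, s + w / 2)
  }
  if (length(pe) < 3L || stats::sd(pe) == 0) return(NA_real_)
  stats::cor(pe, mid, method = "spearman")
}

#' Full evaluation panel on held-out presences
#'
#' Generates pseudo-absences at 50% prevalence, finds the max-TSS
#' threshold, and assembles omission rates, AUC, partial-ROC AUC ratio,
#' TSS, Kappa, continuous Boyce, Jaccard and Sorensen — all computed on
#' the independent test share only.
#'
#' @param model A `maxent_model`.
#' @param test_values Held-out presence matrix (variables in columns).
#' @param train_values Training presence matrix (for omission rates).
#' @param region `suit_grid` of the evaluation region (for the
#'   pseudo-absence draw), typically the predicted suitability surface.
#' @param test_lonlat Optional `lon`/`lat` of the test presences, used to
#'   exclude their cells from the pseudo-absence draw.
#' @param seed Seed for pseudo-absences and the partial-ROC bootstrap.
#' @return List of class `evaluation_report`.
#' @export
evaluate_model <- function(model, test_values, train_values, region,
                           test_lonlat = NULL, seed = 1L) {
  stopifnot_grid(region)
  test_pred <- predict(model, test_values)
  train_pred <- predict(model, train_values)
  pres_cells <- if (!is.null(test_lonlat))
    grid_locate(region, test_lonlat[, "lon"], test_lonlat[, "lat"])$cell
  else integer(0)
  pa <- pseudo_absences_for_eval(length(test_pred), region,
                                 stats::na.omit(pres_cells), seed = seed)
  abs_pred <- grid_extract(region, pa$lon, pa$lat)
  bg_pred <- predict(model, model$background$values)
  mt <- max_tss_threshold(test_pred, abs_pred)
  conf <- confusion_at(mt$threshold, test_pred, abs_pred)
  cm <- confusion_metrics(conf)
  or <- omission_rates(train_pred, test_pred)
  pr <- partial_roc(test_pred, bg_pred, seed = seed)
  structure(list(
    auc = auc(test_pred, abs_pred),
    proc_ratio = pr$ratio, proc_p = pr$p,
    tss = unname(cm["tss"]), kappa = unname(cm["kappa"]),
    boyce = boyce(test_pred, bg_pred),
    jaccard = unname(cm["jaccard"]), sorensen = unname(cm["sorensen"]),
    or_mtp = unname(or["or_mtp"]), or_10 = unname(or["or_10"]),
    threshold = mt$threshold, confusion = conf,
    n_test = length(test_pred), n_absences = nrow(pa)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  OR_mtp %.3f  OR_10 %.3f\n", x$or_mtp, x$or_10))
  cat(sprintf("  AUC %.3f  AUC-ratio %.3f (p %.3f)  Boyce %.3f\n",
              x$auc, x$proc_ratio, x$proc_p, x$boyce))
  cat(sprintf("  max-TSS threshold %.3f: TSS %.3f  Kappa %.3f  Jaccard %.3f  Sorensen %.3f\n",
              x$threshold, x$tss, x$kappa, x$jaccard, x$sorensen))
  invisible(x)
}

#' Evaluation report as a one-row data.frame
#' @param report An `evaluation_report`.
#' @return One-row data.frame of the metric panel.
#' @export
report_row <- function(report) {
  data.frame(or_mtp = report$or_mtp, or_10 = report$or_10, auc = report$auc,
             auc_ratio = report$proc_ratio, tss = report$tss,
             kappa = report$kappa, boyce = report$boyce,
             jaccard = report$jaccard, sorensen = report$sorensen,
             threshold = report$threshold)
}
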