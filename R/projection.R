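#' Binarize a suitability surface
#'
#' A cell is suitable (1) when its suitability is at or above the
#' threshold; the nodata mask is preserved.
#'
#' @param suitability A `suit_grid` in [0, 1].
#' @param threshold Threshold in [0, 1].
#' @return A `suit_grid` of 0/1 values.
#' @export
binarize <- function(suitability, threshold) {
  stopifnot_grid(suitability)
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  grid_like(suitability, (suitability$values >= threshold) * 1)
}

check_aligned <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      abs(a$x_origin - b$x_origin) > 1e-9 ||
      abs(a$y_origin - b$y_origin) > 1e-9 ||
      abs(a$cell_size - b$cell_size) > 1e-12)
    stop("grids are not aligned")
  invisible(TRUE)
}

#' Suitable/unsuitable area budget
#'
#' Latitude-weighted areas of the suitable and unsuitable classes of a
#' binary map, and the suitable percentage of the total unmasked area.
#'
#' @param binary A 0/1 `suit_grid`.
#' @param areas Cell-area grid from [cell_area_km2()] (computed from
#'   `binary` when omitted).
#' @return List `suitable_km2`, `unsuitable_km2`, `total_km2`,
#'   `suitable_pct`.
#' @export
area_budget <- function(binary, areas = cell_area_km2(binary)) {
  stopifnot_grid(binary); stopifnot_grid(areas)
  check_aligned(binary, areas)
  b <- binary$values; a <- areas$values
  keep <- !is.na(b)
  suit <- sum(a[keep & b == 1])
  unsuit <- sum(a[keep & b == 0])
  list(suitable_km2 = suit, unsuitable_km2 = unsuit,
       total_km2 = suit + unsuit,
       suitable_pct = 100 * suit / (suit + unsuit))
}

#' Percent change of a suitable-area budget
#'
#' The relative change, in percent, from a baseline area to the baseline
#' plus an increment: `100 * delta / baseline`.
#'
#' @param baseline_km2 Baseline suitable area.
#' @param delta_km2 Area increment (negative for a loss).
#' @return Percent change.
#' @export
area_change_pct <- function(baseline_km2, delta_km2) {
  if (any(baseline_km2 <= 0)) stop("`baseline_km2` must be positive")
  100 * delta_km2 / baseline_km2
}

#' Change map between two binary suitability maps
#'
#' Classifies every unmasked cell as unchanged-suitable,
#' unchanged-unsuitable, gained (unsuitable to suitable) or lost, with
#' latitude-weighted per-class areas. The accounting identities
#' `unchanged_suitable + lost = current suitable` and
#' `unchanged_suitable + gained = future suitable` hold exactly.
#'
#' @param current,future Aligned 0/1 `suit_grid`s.
#' @param areas Cell-area grid (default from `current`).
#' @return List `map` (a `suit_grid` coded 0 = unchanged-unsuitable,
#'   1 = unchanged-suitable, 2 = gained, 3 = lost) and `areas_km2`
#'   (named per-class vector).
#' @export
change_map <- function(current, future, areas = cell_area_km2(current)) {
  stopifnot_grid(current); stopifnot_grid(future)
  check_aligned(current, future); check_aligned(current, areas)
  cv <- current$values; fv <- future$values
  cls <- matrix(NA_real_, nrow(cv), ncol(cv))
  keep <- !is.na(cv) & !is.na(fv)
  cls[keep & cv == 0 & fv == 0] <- 0
  cls[keep & cv == 1 & fv == 1] <- 1
  cls[keep & cv == 0 & fv == 1] <- 2
  cls[keep & cv == 1 & fv == 0] <- 3
  a <- areas$values
  tot <- vapply(0:3, function(k) sum(a[keep & cls == k]), numeric(1))
  names(tot) <- c("unchanged_unsuitable", "unchanged_suitable",
                  "gained", "lost")
  list(map = grid_like(current, cls), areas_km2 = tot)
}

#' Combine per-GCM suitability surfaces
#'
#' Per-cell mean suitability across the ensemble, and the per-cell
#' fraction of GCMs whose binarized map calls the cell suitable (the
#' "proportion of models predicting suitability"). Generalizes to any
#' ensemble size, warning when it is not the canonical five.
#'
#' @param per_gcm List of aligned suitability `suit_grid`s.
#' @param threshold Binarization threshold.
#' @return List `mean` and `agreement` (`suit_grid`s).
#' @export
multi_gcm_combine <- function(per_gcm, threshold) {
  if (!length(per_gcm)) stop("empty GCM list")
  if (length(per_gcm) != 5L)
    warning(sprintf("expected 5 GCMs, got %d", length(per_gcm)))
  ref <- per_gcm[[1]]
  for (g in per_gcm) { stopifnot_grid(g); check_aligned(ref, g) }
  acc <- ref$values * 0; agr <- acc
  for (g in per_gcm) {
    acc <- acc + g$values
    agr <- agr + (g$values >= threshold)
  }
  list(mean = grid_like(ref, acc / length(per_gcm)),
       agreement = grid_like(ref, agr / length(per_gcm)))
}

#' Replicate-consistency map
#'
#' A cell is "consistent" when at least `agreement_level` of the
#' replicate models agree on its binary class at the given threshold.
#'
#' @param replicate_grids List of aligned suitability `suit_grid`s (>= 2).
#' @param threshold Binarization threshold.
#' @param agreement_level Agreement fraction required (default 0.95).
#' @return List `map` (1 = consistent, 0 = inconsistent),
#'   `consistent_pct`, `inconsistent_pct` (of unmasked cells, area-
#'   weighted).
#' @export
consistency_map <- function(replicate_grids, threshold,
                            agreement_level = 0.95) {
  if (length(replicate_grids) < 2L) stop("need at least 2 replicates")
  ref <- replicate_grids[[1]]
  for (g in replicate_grids) { stopifnot_grid(g); check_aligned(ref, g) }
  votes <- ref$values * 0
  for (g in replicate_grids) votes <- votes + (g$values >= threshold)
  frac_suit <- votes / length(replicate_grids)
  agree <- pmax(frac_suit, 1 - frac_suit)
  cons <- (agree >= agreement_level) * 1
  a <- cell_area_km2(ref)$values
  keep <- !is.na(cons)
  pc <- 100 * sum(a[keep & cons == 1]) / sum(a[keep])
  list(map = grid_like(ref, cons), consistent_pct = pc,
       inconsistent_pct = 100 - pc)
}

#' Per-cell standard deviation across replicate surfaces
#'
#' Sample standard deviation (n - 1 denominator) of the replicate
#' suitability values at each cell.
#'
#' @param replicate_grids List of aligned `suit_grid`s (>= 2).
#' @return A `suit_grid` of standard deviations.
#' @export
sd_map <- function(replicate_grids) {
  if (length(replicate_grids) < 2L) stop("need at least 2 replicates")
  ref <- replicate_grids[[1]]
  for (g in replicate_grids) { stopifnot_grid(g); check_aligned(ref, g) }
  n <- length(replicate_grids)
  acc <- ref$values * 0; acc2 <- acc
  for (g in replicate_grids) { acc <- acc + g$values; acc2 <- acc2 + g$values^2 }
  mu <- acc / n
  grid_like(ref, sqrt(pmax(acc2 - n * mu^2, 0) / (n - 1)))
}
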