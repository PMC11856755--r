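#' Recipe for a synthetic study world
#'
#' Describes the synthetic world every downstream stage can be exercised
#' on: spatially autocorrelated, cross-correlated climate layers over a
#' lat/lon grid, a known truth suitability surface, occurrence records
#' drawn from it (optionally contaminated with greenhouse / summer-only
#' records placed outside the climate envelope), and five perturbed "GCM"
#' future stacks whose warming magnitudes follow the equilibrium climate
#' sensitivity spread of a CMIP6 five-model ensemble (5.4, 4.6, 3.1, 3.0,
#' 2.7 for UKESM1-0-LL, IPSL-CM6A-LR, MRI-ESM2-0, MPI-ESM1-2-HR and
#' GFDL-ESM4).
#'
#' @param layer_names Character codes of the climate layers; codes
#'   starting with `tas` or matching `bio1`..`bio11`/`bio2` are treated as
#'   temperature-like, the rest as precipitation-like.
#' @param n_rows,n_cols Grid shape.
#' @param x_origin,y_origin Lower-left corner (degrees).
#' @param cell_size Cell size (degrees).
#' @param spatial_range Autocorrelation length of the Gaussian fields, in
#'   cells (kernel standard deviation).
#' @param cross_correlation Target pairwise Pearson correlation matrix
#'   (symmetric PSD, unit diagonal). For the default seven-layer panel a
#'   canonical climate-like structure is used (moderately correlated
#'   precipitation indices including one strongly collinear pair, weakly
#'   coupled temperature indices); otherwise the identity.
#' @param lat_gradient Weight in [0, 1) of the shared latitudinal
#'   gradient mixed into every layer (temperature-like layers decrease
#'   away from the equator).
#' @param truth_coefficients Named list with elements `linear` and
#'   optionally `quadratic`: named numeric vectors of truth coefficients
#'   on standardized layers.
#' @param n_presences Number of occurrence records to draw.
#' @param contamination_fraction Fraction in [0, 1) of records flagged
#'   greenhouse or summer-only and placed where truth < `contamination_floor`.
#' @param contamination_floor Suitability ceiling for contaminant cells.
#' @param recent_fraction Fraction of natural records dated 2011-2024;
#'   the rest are dated 1981-2010.
#' @param gcm_shift_scales Five relative warming magnitudes for the
#'   future stacks.
#' @param warming_per_unit Temperature shift (layer SD units) per unit of
#'   shift scale.
#' @param seed Integer seed; fixed seed gives bit-identical worlds.
#' @return A `world_recipe` list.
#' @export
world_recipe <- function(layer_names = c("tas2", "bio15", "prec2", "bio19",
                                         "prec7", "bio13", "bio2"),
                         n_rows = 100, n_cols = 100,
                         x_origin = -30, y_origin = -25, cell_size = 0.5,
                         spatial_range = 6,
                         cross_correlation = NULL,
                         lat_gradient = 0.2,
                         truth_coefficients = list(
                           linear = c(tas2 = 2.0, bio15 = 1.0, prec2 = -0.8),
                           quadratic = c(tas2 = -1.2)),
                         n_presences = 1000,
                         contamination_fraction = 0.1,
                         contamination_floor = 0.05,
                         recent_fraction = 0.35,
                         gcm_shift_scales = c(UK = 5.4, IP = 4.6, MR = 3.1,
                                              MP = 3.0, GF = 2.7),
                         warming_per_unit = 0.25,
                         seed = 20250209) {
  k <- length(layer_names)
  if (k < 1L) stop("need at least one layer")
  if (is.null(cross_correlation))
    cross_correlation <- default_cross_correlation(layer_names)
  cross_correlation <- as.matrix(cross_correlation)
  if (!isTRUE(all.equal(cross_correlation, t(cross_correlation))) ||
      any(abs(diag(cross_correlation) - 1) > 1e-9))
    stop("`cross_correlation` must be symmetric with unit diagonal")
  ev <- eigen(cross_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("`cross_correlation` must be positive semi-definite")
  if (contamination_fraction < 0 || contamination_fraction >= 1)
    stop("`contamination_fraction` must be in [0, 1)")
  if (lat_gradient < 0 || lat_gradient >= 1)
    stop("`lat_gradient` must be in [0, 1)")
  structure(list(
    layer_names = layer_names, n_rows = n_rows, n_cols = n_cols,
    x_origin = x_origin, y_origin = y_origin, cell_size = cell_size,
    spatial_range = spatial_range, cross_correlation = cross_correlation,
    lat_gradient = lat_gradient, truth_coefficients = truth_coefficients,
    n_presences = n_presences,
    contamination_fraction = contamination_fraction,
    contamination_floor = contamination_floor,
    recent_fraction = recent_fraction,
    gcm_shift_scales = gcm_shift_scales,
    warming_per_unit = warming_per_unit, seed = as.integer(seed)),
    class = "world_recipe")
}

# canonical climate-like correlation structure for the default 7-layer
# panel: precipitation indices moderately correlated (0.4) with one
# strongly collinear pair (bio19-bio13, 0.85) that the predictor screen
# should break up; temperature indices weakly coupled (0.3) and nearly
# independent of precipitation (0.1). Identity for any other panel.
default_cross_correlation <- function(layer_names) {
  canonical <- c("tas2", "bio15", "prec2", "bio19", "prec7", "bio13", "bio2")
  if (!identical(layer_names, canonical)) return(diag(length(layer_names)))
  C <- diag(7); rownames(C) <- colnames(C) <- canonical
  temp <- c("tas2", "bio2"); prec <- setdiff(canonical, temp)
  C[temp, prec] <- 0.1; C[prec, temp] <- 0.1
  C["tas2", "bio2"] <- C["bio2", "tas2"] <- 0.3
  for (a in prec) for (b in prec) if (a != b) C[a, b] <- 0.4
  C["bio19", "bio13"] <- C["bio13", "bio19"] <- 0.85
  C
}

# temperature-like layer codes: monthly air temperature and the
# temperature-derived bioclim indices bio1..bio11
is_temperature_code <- function(codes) {
  grepl("^tas", codes) | grepl("^bio([1-9]|1[01])$", codes)
}

# smooth white noise with a separable Gaussian kernel (reflecting edges)
# and standardize to zero mean / unit sd
smooth_field <- function(nr, nc, range_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  half <- max(1L, ceiling(3 * range_cells))
  k <- stats::dnorm(seq(-half, half), sd = range_cells)
  k <- k / sum(k)
  pad_reflect <- function(n) c(pmin(pmax(seq(1 - half, n + half), 1), n))
  Kr <- matrix(0, nr, nr + 2L * half)
  for (i in seq_len(nr)) Kr[i, i:(i + 2L * half)] <- k
  Kc <- matrix(0, nc, nc + 2L * half)
  for (j in seq_len(nc)) Kc[j, j:(j + 2L * half)] <- k
  zp <- z[pad_reflect(nr), pad_reflect(nc)]
  s <- Kr %*% zp %*% t(Kc)
  s <- s[, seq_len(nc), drop = FALSE][seq_len(nr), , drop = FALSE]
  (s - mean(s)) / stats::sd(s)
}

#' Generate the synthetic climate layers
#'
#' Each layer is a smoothed Gaussian random field plus a shared
#' latitudinal gradient. Cross-correlation between layers is imposed by
#' mixing independent smoothed fields through the Cholesky factor of the
#' target correlation matrix; for grids of 100 x 100 cells or more the
#' empirical pairwise correlations land within about 0.1 of the target.
#'
#' @param recipe A [world_recipe()].
#' @return A `suit_stack` of `length(recipe$layer_names)` layers.
#' @export
make_layers <- function(recipe) {
  stopifnot(inherits(recipe, "world_recipe"))
  k <- length(recipe$layer_names)
  nr <- recipe$n_rows; nc <- recipe$n_cols
  set.seed(recipe$seed)
  fields <- lapply(seq_len(k), function(i)
    smooth_field(nr, nc, recipe$spatial_range))
  Z <- vapply(fields, as.vector, numeric(nr * nc))
  # shared latitudinal gradient: warm equator, cold poles
  lat <- recipe$y_origin + (nr - seq_len(nr) + 0.5) * recipe$cell_size
  gvec <- -abs(lat)
  gvec <- (gvec - mean(gvec)) / stats::sd(gvec)
  gfield <- as.vector(matrix(rep(gvec, nc), nr, nc))
  # empirically orthogonalize the smooth fields against each other and
  # the gradient (QR with an intercept), so the Cholesky-style mixing
  # reproduces the target correlations regardless of the spatial
  # autocorrelation of any one realization
  qr_dec <- qr(cbind(1, gfield, Z))
  Q <- qr.Q(qr_dec)[, 2L + seq_len(k), drop = FALSE]
  Q <- sweep(Q, 2, apply(Q, 2, stats::sd), "/")
  ev <- eigen(recipe$cross_correlation, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)
  M <- Q %*% L
  g <- recipe$lat_gradient
  layers <- vector("list", k)
  for (i in seq_len(k)) {
    f <- matrix(sqrt(1 - g^2) * M[, i] + g * gfield, nr, nc)
    layers[[i]] <- suit_grid(f, recipe$x_origin, recipe$y_origin,
                             recipe$cell_size)
  }
  names(layers) <- recipe$layer_names
  suit_stack(layers)
}

#' Known-truth suitability surface
#'
#' Builds the truth as a logistic transform of a standardized linear
#' predictor in the (standardized) layers: linear terms plus optional
#' quadratic terms. All-zero coefficients give a constant 0.5 surface;
#' negating every coefficient reflects the surface about 0.5.
#'
#' @param stack A `suit_stack`.
#' @param coefficients List with named numeric vectors `linear` and
#'   optionally `quadratic`; names must be layer codes.
#' @return A `suit_grid` with values in (0, 1).
#' @export
make_truth <- function(stack, coefficients) {
  stopifnot_stack(stack)
  lin <- coefficients$linear
  quad <- coefficients$quadratic
  unknown <- setdiff(c(names(lin), names(quad)), names(stack$layers))
  if (length(unknown))
    stop(sprintf("unknown layer(s) in truth coefficients: %s",
                 paste(unknown, collapse = ", ")))
  tab <- stack_table(stack)
  std <- scale(tab$values)
  lp <- rep(0, nrow(std))
  for (nm in names(lin)) lp <- lp + lin[[nm]] * std[, nm]
  for (nm in names(quad)) lp <- lp + quad[[nm]] * std[, nm]^2
  if (stats::sd(lp) > 0) lp <- (lp - mean(lp)) / stats::sd(lp) * 2
  ref <- stack$layers[[1]]
  v <- ref$values
  v[tab$cells] <- stats::plogis(lp)
  grid_like(ref, v)
}

#' Sample occurrence records from a truth surface
#'
#' Presence cells are drawn (with replacement) with probability
#' proportional to truth, then jittered uniformly within the cell.
#' Natural records are dated 1981-2010 or 2011-2024 according to
#' `recipe$recent_fraction`; a `contamination_fraction` of records is
#' flagged greenhouse or summer-only and placed uniformly among cells
#' whose truth is below `recipe$contamination_floor`, emulating records
#' that persist outside the climate envelope only under protected
#' cultivation or transient summer warmth.
#'
#' @param truth A `suit_grid` of suitability in [0, 1].
#' @param recipe A [world_recipe()].
#' @return A data.frame of occurrence records (`lon`, `lat`, `year`,
#'   `elevation`, `greenhouse_flag`, `summer_only_flag`, `source`).
#' @export
sample_occurrences <- function(truth, recipe) {
  stopifnot_grid(truth)
  stopifnot(inherits(recipe, "world_recipe"))
  set.seed(recipe$seed + 1L)
  n <- recipe$n_presences
  keep <- which(!is.na(truth$values))
  if (!length(keep)) stop("truth surface is fully masked")
  w <- truth$values[keep]
  if (any(w < 0 | w > 1)) stop("truth must lie in [0, 1]")
  n_cont <- round(n * recipe$contamination_fraction)
  n_nat <- n - n_cont
  draw_cells <- function(pool, weights, size) {
    pool[sample.int(length(pool), size, replace = TRUE, prob = weights)]
  }
  nat_cells <- draw_cells(keep, w, n_nat)
  cont_cells <- integer(0)
  if (n_cont > 0) {
    low <- keep[truth$values[keep] < recipe$contamination_floor]
    if (!length(low))
      stop("no cells below the contamination floor; lower the floor or the fraction")
    cont_cells <- low[sample.int(length(low), n_cont, replace = TRUE)]
  }
  cells <- c(nat_cells, cont_cells)
  nr <- nrow(truth$values)
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  cs <- truth$cell_size
  lon <- truth$x_origin + (col - 1L) * cs + stats::runif(length(cells)) * cs
  lat <- truth$y_origin + (nr - row) * cs + stats::runif(length(cells)) * cs
  recent <- c(stats::runif(n_nat) < recipe$recent_fraction, rep(TRUE, n_cont))
  year <- ifelse(recent, sample(2011:2024, length(cells), replace = TRUE),
                 sample(1981:2010, length(cells), replace = TRUE))
  greenhouse <- c(rep(FALSE, n_nat), stats::runif(n_cont) < 0.5)
  summer <- c(rep(FALSE, n_nat), rep(FALSE, n_cont))
  summer[seq_along(cells) > n_nat] <- !greenhouse[seq_along(cells) > n_nat]
  elev <- round(pmax(0, 400 + 150 * abs(lat) / 45 + stats::rnorm(length(cells), 0, 120)))
  elev[greenhouse | summer] <- elev[greenhouse | summer] + 400
  data.frame(lon = lon, lat = lat, year = year, elevation = elev,
             greenhouse_flag = greenhouse, summer_only_flag = summer,
             source = ifelse(greenhouse, "greenhouse_survey",
                             ifelse(summer, "summer_survey", "field_survey")),
             stringsAsFactors = FALSE)
}

#' Perturbed future climate stacks for a five-GCM ensemble
#'
#' Produces one future stack per shift scale. Temperature-like layers are
#' shifted additively by `warming_per_unit * scale` (in layer SD units)
#' plus a smooth spatial anomaly proportional to the scale;
#' precipitation-like layers are rescaled multiplicatively with a smooth
#' spatial modulation, again proportional to the scale. A scale of zero
#' reproduces the input stack exactly, and the per-GCM mean temperature
#' shifts preserve the ordering of the scales.
#'
#' @param stack A `suit_stack` of near-current layers.
#' @param recipe A [world_recipe()]; uses `gcm_shift_scales`,
#'   `warming_per_unit`, `spatial_range`, and `seed`.
#' @return Named list of `suit_stack`s, one per GCM.
#' @export
make_future <- function(stack, recipe) {
  stopifnot_stack(stack)
  stopifnot(inherits(recipe, "world_recipe"))
  scales <- recipe$gcm_shift_scales
  if (length(scales) != 5L) stop("expected exactly 5 GCM shift scales")
  if (is.null(names(scales))) names(scales) <- paste0("GCM", seq_along(scales))
  temp <- is_temperature_code(names(stack$layers))
  nr <- nrow(stack$layers[[1]]$values); nc <- ncol(stack$layers[[1]]$values)
  set.seed(recipe$seed + 2L)
  out <- vector("list", length(scales))
  names(out) <- names(scales)
  for (gi in seq_along(scales)) {
    sc <- scales[[gi]]
    layers <- vector("list", length(stack$layers))
    names(layers) <- names(stack$layers)
    for (li in seq_along(stack$layers)) {
      g <- stack$layers[[li]]
      anom <- smooth_field(nr, nc, recipe$spatial_range)
      s <- stats::sd(g$values[!is.na(g$values)])
      if (temp[li]) {
        v <- g$values + sc * (recipe$warming_per_unit * s +
                                0.05 * s * anom)
      } else {
        v <- g$values * (1 + 0.03 * sc + 0.01 * sc * anom)
      }
      layers[[li]] <- grid_like(g, v)
    }
    out[[gi]] <- suit_stack(layers)
  }
  out
}

#' Build a complete synthetic world
#'
#' Convenience wrapper: layers, truth, occurrences, and the five future
#' stacks in one call.
#'
#' @param recipe A [world_recipe()].
#' @return List with `recipe`, `stack`, `truth`, `occurrences`, `future`.
#' @export
make_world <- function(recipe = world_recipe()) {
  stack <- make_layers(recipe)
  truth <- make_truth(stack, recipe$truth_coefficients)
  occ <- sample_occurrences(truth, recipe)
  fut <- make_future(stack, recipe)
  list(recipe = recipe, stack = stack, truth = truth, occurrences = occ,
       future = fut)
}
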