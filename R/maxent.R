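#' Feature-class specification
#'
#' The five classic maxent feature classes built from the raw
#' environmental variables: linear (L), quadratic (Q), hinge (H), product
#' (P), and threshold (T).
#'
#' @param classes Character vector, subset of `c("L","Q","H","P","T")`,
#'   or a compact string like `"LQT"`.
#' @param hinge_knots Forward-hinge knots per variable (default 50).
#' @param threshold_knots Step-function knots per variable (default 20).
#' @return A `feature_spec`.
#' @export
feature_spec <- function(classes = c("L", "Q", "H", "P", "T"),
                         hinge_knots = 50, threshold_knots = 20) {
  if (length(classes) == 1L && nchar(classes) > 1L)
    classes <- strsplit(classes, "")[[1]]
  classes <- toupper(classes)
  bad <- setdiff(classes, c("L", "Q", "H", "P", "T"))
  if (length(bad)) stop(sprintf("unknown feature class(es): %s",
                                paste(bad, collapse = ", ")))
  if (!length(classes)) stop("feature classes must be non-empty")
  structure(list(classes = sort(unique(classes)),
                 hinge_knots = as.integer(hinge_knots),
                 threshold_knots = as.integer(threshold_knots)),
            class = "feature_spec")
}

fc_code <- function(spec) paste(spec$classes, collapse = "")

#' Feature scaling bounds from a background sample
#'
#' Per-variable min/max over the background (used to scale every feature
#' to [0, 1] and to clamp projections) plus hinge and threshold knots at
#' interior background quantiles.
#'
#' @param bg_values Background matrix (cells x variables, named columns).
#' @param spec A [feature_spec()].
#' @return A `feature_bounds` list.
#' @export
feature_bounds <- function(bg_values, spec) {
  m <- as.matrix(bg_values)
  if (is.null(colnames(m))) stop("background columns must be named")
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  knots <- function(n) {
    if (n < 1L) return(numeric(0))
    seq(0, 1, length.out = n + 2L)[-c(1L, n + 2L)]
  }
  hq <- lapply(seq_len(ncol(m)), function(j) {
    q <- stats::quantile(m[, j], probs = knots(spec$hinge_knots), names = FALSE,
                         type = 7)
    (q - lo[j]) / ifelse(hi[j] > lo[j], hi[j] - lo[j], 1)
  })
  tq <- lapply(seq_len(ncol(m)), function(j) {
    q <- stats::quantile(m[, j], probs = knots(spec$threshold_knots),
                         names = FALSE, type = 7)
    (q - lo[j]) / ifelse(hi[j] > lo[j], hi[j] - lo[j], 1)
  })
  names(hq) <- names(tq) <- colnames(m)
  structure(list(vars = colnames(m), lo = lo, hi = hi,
                 hinge = hq, threshold = tq, spec = spec),
            class = "feature_bounds")
}

#' Build the maxent feature matrix
#'
#' Raw values are clamped to the background bounds (projection clamping),
#' scaled to [0, 1], and expanded into the requested feature classes:
#' L = scaled value, Q = scaled value squared, P = all pairwise products,
#' H = forward hinges `(s - k)/(1 - k)` above each knot, T = indicator
#' steps `s >= k`. Every feature lies in [0, 1] over the background.
#'
#' @param values Matrix (rows = points, named columns = variables).
#' @param bounds A [feature_bounds()].
#' @return Numeric feature matrix with descriptive column names.
#' @export
build_features <- function(values, bounds) {
  v <- as.matrix(values)
  if (is.null(colnames(v))) colnames(v) <- bounds$vars
  v <- v[, bounds$vars, drop = FALSE]
  spec <- bounds$spec
  n <- nrow(v)
  S <- v
  for (j in seq_along(bounds$vars)) {
    lo <- bounds$lo[j]; hi <- bounds$hi[j]
    x <- pmin(pmax(v[, j], lo), hi)
    S[, j] <- if (hi > lo) (x - lo) / (hi - lo) else 0
  }
  cols <- list(); nms <- character(0)
  vars <- bounds$vars
  if ("L" %in% spec$classes) {
    cols <- c(cols, lapply(seq_along(vars), function(j) S[, j]))
    nms <- c(nms, paste0("L:", vars))
  }
  if ("Q" %in% spec$classes) {
    cols <- c(cols, lapply(seq_along(vars), function(j) S[, j]^2))
    nms <- c(nms, paste0("Q:", vars))
  }
  if ("P" %in% spec$classes && length(vars) >= 2L) {
    for (a in seq_len(length(vars) - 1L)) for (b in seq.int(a + 1L, length(vars))) {
      cols <- c(cols, list(S[, a] * S[, b]))
      nms <- c(nms, paste0("P:", vars[a], "*", vars[b]))
    }
  }
  if ("H" %in% spec$classes) {
    for (j in seq_along(vars)) {
      for (k in bounds$hinge[[j]]) {
        h <- pmax(S[, j] - k, 0) / max(1 - k, 1e-12)
        cols <- c(cols, list(h))
        nms <- c(nms, sprintf("H:%s:%.6g", vars[j], k))
      }
    }
  }
  if ("T" %in% spec$classes) {
    for (j in seq_along(vars)) {
      for (k in bounds$threshold[[j]]) {
        cols <- c(cols, list(as.numeric(S[, j] >= k)))
        nms <- c(nms, sprintf("T:%s:%.6g", vars[j], k))
      }
    }
  }
  F <- do.call(cbind, cols)
  colnames(F) <- nms
  F
}

# per-feature class of a feature matrix from its column names
feature_classes_of <- function(feature_names) substr(feature_names, 1, 1)

# Default per-class regularization bases, interpolated on presence count,
# following the published defaults of the reference maxent implementation
# (linear/quadratic/product share one schedule; hinge is constant 0.5;
# threshold interpolates from 2 to 1).
default_beta_base <- function(class, n) {
  interp <- function(xs, ys) stats::approx(xs, ys, xout = min(max(n, xs[1]),
                                                             xs[length(xs)]),
                                           rule = 2)$y
  switch(class,
         L = , Q = , P = interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
         H = 0.5,
         T = interp(c(0, 100), c(2, 1)),
         stop("unknown feature class"))
}

#' Sample background (pseudo-absence) cells within a presence buffer
#'
#' Draws `m` cells uniformly without replacement from the unmasked cells
#' whose center lies within `buffer_km` (great-circle) of at least one
#' presence. If fewer than `m` cells are eligible, all are taken with a
#' warning.
#'
#' @param occ Occurrence data.frame (`lon`, `lat`).
#' @param stack A `suit_stack`.
#' @param buffer_km Buffer radius in km (default 500).
#' @param m Background size (default 10000).
#' @param seed Integer seed.
#' @return List of class `background_sample`: `lon`, `lat`, `cells`
#'   (linear indices), `values` (cells x variables), `buffer_km`, `seed`.
#' @export
sample_background <- function(occ, stack, buffer_km = 500, m = 10000, seed = 1L) {
  stopifnot_stack(stack)
  if (buffer_km <= 0) stop("`buffer_km` must be positive")
  tab <- stack_table(stack)
  pres <- cbind(occ$lon, occ$lat)
  cells <- cbind(tab$lon, tab$lat)
  # nearest-presence distance per cell, chunked to bound memory
  nearest <- rep(Inf, nrow(cells))
  chunk <- 2000L
  for (s in seq(1L, nrow(cells), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(cells))
    d <- geosphere::distm(cells[s:e, , drop = FALSE], pres,
                          fun = geosphere::distHaversine) / 1000
    nearest[s:e] <- apply(d, 1, min)
  }
  elig <- which(nearest <= buffer_km)
  if (!length(elig)) stop("no unmasked cells within the buffer")
  if (length(elig) < m) {
    warning(sprintf("only %d eligible cells for m = %d; taking all",
                    length(elig), m))
    pick <- elig
  } else {
    set.seed(seed)
    pick <- sort(elig[sample.int(length(elig), m)])
  }
  structure(list(lon = tab$lon[pick], lat = tab$lat[pick],
                 cells = tab$cells[pick],
                 values = tab$values[pick, , drop = FALSE],
                 buffer_km = buffer_km, seed = as.integer(seed)),
            class = "background_sample")
}

# stable log-sum-exp
lse <- function(x) { M <- max(x); M + log(sum(exp(x - M))) }

#' Fit the penalized maximum-entropy model
#'
#' Maximizes the L1-penalized presence-background maxent log-likelihood
#' `mean_presence(eta) - log sum_background(exp(eta)) - sum_j beta_j |lambda_j|`
#' by cyclic coordinate-wise proximal Newton updates with per-coordinate
#' backtracking. The per-feature penalty is
#' `beta_j = rm * base(class, n) * s_j / sqrt(n)` where `base` is the
#' class-default regularization schedule interpolated on presence count
#' and `s_j` is the feature's standard deviation over the presences.
#'
#' @param pres_values Presence matrix (points x variables, named columns).
#' @param background A [sample_background()] result (or a list with a
#'   `values` matrix).
#' @param spec A [feature_spec()].
#' @param rm Regularization multiplier (>= 0); `rm = 1` reproduces the
#'   class defaults.
#' @param max_iter Maximum coordinate-descent sweeps.
#' @param tol Convergence tolerance on the penalized objective change
#'   between sweeps.
#' @return A `maxent_model`: `lambda`, `beta`, `bounds`, `spec`, `rm`,
#'   `log_z` (log partition over background), `entropy` (of the raw
#'   background distribution), `n_presences`, `m_background`,
#'   `background`, `objective`, `converged`, `iterations`.
#' @export
fit_maxent <- function(pres_values, background, spec = feature_spec("LQ"),
                       rm = 1, max_iter = 2000L, tol = 1e-7) {
  if (rm < 0) stop("`rm` must be non-negative")
  pv <- as.matrix(pres_values)
  n <- nrow(pv)
  if (n < 2L) stop("need at least 2 presences")
  bounds <- feature_bounds(background$values, spec)
  Fp <- build_features(pv, bounds)
  Fb <- build_features(background$values, bounds)
  J <- ncol(Fp); m <- nrow(Fb)
  s_pres <- apply(Fp, 2, stats::sd)
  base <- vapply(feature_classes_of(colnames(Fp)), default_beta_base,
                 numeric(1), n = n)
  beta <- rm * base * pmax(s_pres, 1e-3) / sqrt(n)
  pmean <- colMeans(Fp)
  lambda <- rep(0, J)
  eta_b <- rep(0, m)
  obj <- function() {
    -sum(pmean * lambda) + lse(eta_b) + sum(beta * abs(lambda))
  }
  f_cur <- obj()
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    f_prev <- f_cur
    for (j in seq_len(J)) {
      w <- exp(eta_b - max(eta_b)); w <- w / sum(w)
      Ef <- sum(w * Fb[, j])
      Vf <- sum(w * Fb[, j]^2) - Ef^2
      g <- pmean[j] - Ef
      h <- max(Vf, 1e-6)
      z <- lambda[j] + g / h
      new <- sign(z) * max(abs(z) - beta[j] / h, 0)
      d <- new - lambda[j]
      if (d == 0) next
      # backtracking on the true objective
      for (half in 0:12) {
        cand <- lambda[j] + d
        eta_try <- eta_b + d * Fb[, j]
        f_try <- -sum(pmean * (replace(lambda, j, cand))) + lse(eta_try) +
          sum(beta * abs(replace(lambda, j, cand)))
        if (f_try <= f_cur + 1e-12) {
          lambda[j] <- cand; eta_b <- eta_try; f_cur <- f_try
          break
        }
        d <- d / 2
      }
    }
    if (abs(f_prev - f_cur) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("coordinate descent stopped at %d sweeps (last change %.3g)",
                    it, abs(f_prev - f_cur)))
  log_z <- lse(eta_b)
  q <- exp(eta_b - log_z)
  entropy <- -sum(q * ifelse(q > 0, log(q), 0))
  structure(list(lambda = stats::setNames(lambda, colnames(Fp)), beta = beta,
                 bounds = bounds, spec = spec, rm = rm, log_z = log_z,
                 entropy = entropy, n_presences = n, m_background = m,
                 background = background, objective = f_cur,
                 converged = converged, iterations = it),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> FC %s, rm %.2g: %d/%d nonzero features, H = %.4f\n",
              fc_code(x$spec), x$rm, sum(x$lambda != 0), length(x$lambda),
              x$entropy))
  invisible(x)
}

# linear predictor at raw variable values
maxent_eta <- function(model, values) {
  F <- build_features(values, model$bounds)
  as.numeric(F %*% model$lambda)
}

#' Predict suitability from a fitted maxent model
#'
#' Output modes: `raw` is `exp(eta) / Z` with Z the partition function
#' over the training background (so raw sums to 1 over that background);
#' `cumulative` is the percentage of total raw mass on background cells
#' with raw value at or below the point's; `cloglog` is
#' `1 - exp(-exp(H) * raw)` with H the entropy of the background raw
#' distribution. A model with all-zero coefficients gives a uniform raw
#' distribution and a cloglog of `1 - exp(-1)` everywhere.
#'
#' @param object A `maxent_model`.
#' @param newdata A `suit_stack`, or a matrix/data.frame of variable
#'   values (named columns).
#' @param type `"cloglog"` (default), `"raw"`, or `"cumulative"`.
#' @param ... Unused.
#' @return A `suit_grid` when `newdata` is a stack, else a numeric vector.
#' @export
predict.maxent_model <- function(object, newdata, type = "cloglog", ...) {
  if (!type %in% c("raw", "cumulative", "cloglog"))
    stop(sprintf("unknown output mode '%s'", type))
  as_stack <- is_stack(newdata)
  vals <- if (as_stack) stack_table(newdata)$values else as.matrix(newdata)
  eta <- maxent_eta(object, vals)
  raw <- exp(eta - object$log_z)
  out <- switch(type,
    raw = raw,
    cloglog = 1 - exp(-exp(object$entropy) * raw),
    cumulative = {
      bg_raw <- exp(maxent_eta(object, object$background$values) - object$log_z)
      ord <- order(bg_raw)
      cum <- cumsum(bg_raw[ord])
      idx <- findInterval(raw * (1 + 1e-9), bg_raw[ord])
      100 * c(0, cum)[idx + 1L] / sum(bg_raw)
    })
  if (as_stack) {
    ref <- newdata$layers[[1]]
    v <- ref$values
    v[stack_table(newdata)$cells] <- out
    grid_like(ref, v)
  } else out
}

#' Response curve of one variable
#'
#' Sweeps the variable across its background range while every other
#' variable is held at its background mean, returning the cloglog
#' response.
#'
#' @param model A `maxent_model`.
#' @param variable Variable code.
#' @param n_points Sweep resolution (default 100).
#' @return Data.frame with columns `value` and `cloglog`.
#' @export
response_curve <- function(model, variable, n_points = 100) {
  vars <- model$bounds$vars
  if (!variable %in% vars) stop(sprintf("variable '%s' not in model", variable))
  mu <- colMeans(model$background$values)
  sweep_vals <- seq(model$bounds$lo[variable], model$bounds$hi[variable],
                    length.out = n_points)
  newdata <- matrix(rep(mu, each = n_points), n_points, length(vars),
                    dimnames = list(NULL, vars))
  newdata[, variable] <- sweep_vals
  data.frame(value = sweep_vals,
             cloglog = predict(model, newdata, type = "cloglog"))
}

#' Permutation percent contribution of each variable
#'
#' Permutes each variable over the combined presence + background rows,
#' measures the drop in training AUC (presence vs background cloglog
#' predictions), floors negative drops at zero, and rescales to sum
#' to 100.
#'
#' @param model A `maxent_model`.
#' @param pres_values Presence matrix used in fitting.
#' @param seed Seed for the permutations.
#' @return Named percent vector summing to 100.
#' @export
percent_contribution <- function(model, pres_values, seed = 1L) {
  pv <- as.matrix(pres_values)[, model$bounds$vars, drop = FALSE]
  bv <- model$background$values[, model$bounds$vars, drop = FALSE]
  n <- nrow(pv)
  base_auc <- auc(predict(model, pv), predict(model, bv))
  set.seed(seed)
  drops <- vapply(model$bounds$vars, function(v) {
    comb <- c(pv[, v], bv[, v])
    perm <- sample(comb)
    pv2 <- pv; bv2 <- bv
    pv2[, v] <- perm[seq_len(n)]
    bv2[, v] <- perm[-seq_len(n)]
    base_auc - auc(predict(model, pv2), predict(model, bv2))
  }, numeric(1))
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) drops <- rep(1, length(drops))
  stats::setNames(100 * drops / sum(drops), model$bounds$vars)
}

# training gain: mean presence log raw probability above the uniform floor
training_gain <- function(model, pres_values) {
  raw <- predict(model, as.matrix(pres_values), type = "raw")
  mean(log(pmax(raw, 1e-300))) + log(model$m_background)
}

#' Jackknife variable-importance gains
#'
#' For each variable, the training gain of a model fitted with only that
#' variable and of a model fitted with all variables but that one, plus
#' the full-model gain.
#'
#' @param pres_values Presence matrix (points x variables).
#' @param background A [sample_background()] result.
#' @param spec A [feature_spec()].
#' @param rm Regularization multiplier.
#' @return List: `table` (data.frame variable / with_only / without) and
#'   `full_gain`.
#' @export
jackknife_gain <- function(pres_values, background, spec = feature_spec("LQ"),
                           rm = 1) {
  pv <- as.matrix(pres_values)
  vars <- colnames(pv)
  if (length(vars) < 2L) stop("jackknife needs at least 2 variables")
  sub_bg <- function(keep) {
    b <- background
    b$values <- b$values[, keep, drop = FALSE]
    b
  }
  fit_gain <- function(keep) {
    m <- fit_maxent(pv[, keep, drop = FALSE], sub_bg(keep), spec, rm)
    training_gain(m, pv[, keep, drop = FALSE])
  }
  with_only <- vapply(vars, function(v) fit_gain(v), numeric(1))
  without <- vapply(vars, function(v) fit_gain(setdiff(vars, v)), numeric(1))
  full <- fit_gain(vars)
  list(table = data.frame(variable = vars, with_only = unname(with_only),
                          without = unname(without)),
       full_gain = full)
}

#' Replicated maxent runs with random test splits
#'
#' Runs the model `n_reps` times; each replicate draws a fresh random
#' 75/25 presence split (seed = `base_seed + rep`), fits on the training
#' share, and predicts the cloglog surface. Returns per-cell mean and
#' standard deviation grids plus the per-replicate pieces needed for
#' evaluation.
#'
#' @param pres_values Presence matrix (points x variables).
#' @param background A [sample_background()] result.
#' @param stack Stack to project onto.
#' @param spec A [feature_spec()].
#' @param rm Regularization multiplier.
#' @param n_reps Replicates (default 20).
#' @param test_fraction Held-out share (default 0.25).
#' @param base_seed Base seed for the splits.
#' @return List: `mean` and `sd` grids, `replicates` (per-rep list with
#'   `model`, `test_idx`, `train_pred`, `test_pred`, `grid`).
#' @export
replicate_runs <- function(pres_values, background, stack,
                           spec = feature_spec("LQ"), rm = 1,
                           n_reps = 20, test_fraction = 0.25, base_seed = 100L) {
  pv <- as.matrix(pres_values)
  n <- nrow(pv)
  n_test <- round(n * test_fraction)
  if (n_test < 1L || n - n_test < 2L)
    stop("too few presences to split")
  reps <- vector("list", n_reps)
  acc <- NULL; acc2 <- NULL
  for (r in seq_len(n_reps)) {
    set.seed(base_seed + r)
    test_idx <- sort(sample.int(n, n_test))
    fit <- fit_maxent(pv[-test_idx, , drop = FALSE], background, spec, rm)
    g <- predict(fit, stack, type = "cloglog")
    reps[[r]] <- list(model = fit, test_idx = test_idx,
                      train_pred = predict(fit, pv[-test_idx, , drop = FALSE]),
                      test_pred = predict(fit, pv[test_idx, , drop = FALSE]),
                      grid = g)
    if (is.null(acc)) { acc <- g$values * 0; acc2 <- acc }
    acc <- acc + g$values
    acc2 <- acc2 + g$values^2
  }
  meanv <- acc / n_reps
  sdv <- if (n_reps > 1) sqrt(pmax(acc2 - n_reps * meanv^2, 0) / (n_reps - 1))
         else meanv * 0
  ref <- stack$layers[[1]]
  list(mean = grid_like(ref, meanv), sd = grid_like(ref, sdv),
       replicates = reps)
}
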