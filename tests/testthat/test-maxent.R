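# independent penalized-likelihood oracle: minimize
#   -mean_p(eta) + log sum_b exp(eta) + sum(beta |lambda|)
# via L-BFGS-B on the split-positive parameterization lambda = a - b
oracle_fit_objective <- function(Fp, Fb, beta) {
  J <- ncol(Fp)
  pmean <- colMeans(Fp)
  obj <- function(par) {
    lam <- par[1:J] - par[J + 1:J]
    eta <- as.vector(Fb %*% lam)
    -sum(pmean * lam) + max(eta) + log(sum(exp(eta - max(eta)))) +
      sum(beta * (par[1:J] + par[J + 1:J]))
  }
  gr <- function(par) {
    lam <- par[1:J] - par[J + 1:J]
    eta <- as.vector(Fb %*% lam)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    g <- -pmean + as.vector(t(Fb) %*% w)
    c(g + beta, -g + beta)
  }
  fit <- stats::optim(rep(0, 2 * J), obj, gr, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = 2000, factr = 1e4))
  fit$value
}

test_that("feature construction matches the combinatorial layout", {
  set.seed(11)
  bg <- cbind(x = runif(200, 0, 10), y = rnorm(200))
  spec <- feature_spec("LQHPT", hinge_knots = 5, threshold_knots = 3)
  b <- feature_bounds(bg, spec)
  F <- build_features(bg, b)
  expect_equal(ncol(F), 2 + 2 + 1 + 10 + 6)  # 2L + 2Q + 1P + 10H + 6T
  expect_true(all(F >= 0 & F <= 1))
  # L-only spec gives one feature per variable
  bL <- feature_bounds(bg, feature_spec("L"))
  expect_equal(ncol(build_features(bg, bL)), 2L)
  # scaling endpoints
  FL <- build_features(rbind(c(min(bg[, 1]), 0), c(max(bg[, 1]), 0)), bL)
  expect_equal(FL[, "L:x"], c(0, 1))
  # projection clamping: values beyond bounds pin to 0/1
  Fc <- build_features(rbind(c(-99, 0), c(99, 0)), bL)
  expect_equal(Fc[, "L:x"], c(0, 1))
})

test_that("a dominant penalty drives all coefficients to zero and the cloglog limit", {
  fit <- small_fit()
  m <- fit_maxent(fit$pres_values, fit$background, feature_spec("LQ"),
                  rm = 1e7)
  expect_true(all(m$lambda == 0))
  raw <- predict(m, fit$background$values, type = "raw")
  expect_equal(raw, rep(1 / m$m_background, length(raw)), tolerance = 1e-12)
  cl <- predict(m, fit$background$values, type = "cloglog")
  expect_equal(cl, rep(1 - exp(-1), length(cl)), tolerance = 1e-9)
  expect_equal(m$entropy, log(m$m_background), tolerance = 1e-9)
})

test_that("raw distribution is normalized and entropy is in range after every fit", {
  fit <- small_fit()
  for (fc in c("L", "LQ", "LT")) {
    m <- fit_maxent(fit$pres_values, fit$background, feature_spec(fc, 5, 5),
                    rm = 1)
    raw <- predict(m, fit$background$values, type = "raw")
    expect_equal(sum(raw), 1, tolerance = 1e-9)
    expect_gte(m$entropy, 0)
    expect_lte(m$entropy, log(m$m_background) + 1e-9)
  }
})

test_that("at rm -> 0 the fitted distribution matches presence feature means", {
  fit <- small_fit()
  m <- fit_maxent(fit$pres_values, fit$background, feature_spec("LQ"),
                  rm = 0, tol = 1e-10, max_iter = 5000L)
  bgF <- build_features(fit$background$values, m$bounds)
  q <- predict(m, fit$background$values, type = "raw")
  presF <- build_features(fit$pres_values, m$bounds)
  Ep <- as.vector(t(bgF) %*% q)
  expect_lt(max(abs(Ep - colMeans(presF))), 1e-3)
})

test_that("the fit reaches the oracle objective on a small design", {
  fit <- small_fit()
  set.seed(12)
  idx <- sample(nrow(fit$pres_values), 50)
  bg <- fit$background
  bsub <- sample(nrow(bg$values), 500)
  bg$values <- bg$values[bsub, , drop = FALSE]
  pv <- fit$pres_values[idx, , drop = FALSE]
  m <- fit_maxent(pv, bg, feature_spec("LQ"), rm = 1, tol = 1e-10)
  Fp <- build_features(pv, m$bounds)
  Fb <- build_features(bg$values, m$bounds)
  oracle <- oracle_fit_objective(Fp, Fb, m$beta)
  expect_equal(m$objective, oracle, tolerance = 1e-4)
})

test_that("nonzero-coefficient count is nonincreasing in the penalty", {
  fit <- small_fit()
  ks <- vapply(c(0.1, 0.5, 1, 2, 5, 20), function(rm)
    sum(fit_maxent(fit$pres_values, fit$background, feature_spec("LQ"),
                   rm = rm, max_iter = 3000L)$lambda != 0), numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("cumulative and cloglog predictions follow their definitions", {
  fit <- small_fit()
  m <- fit$model
  bg <- fit$background$values
  cum <- predict(m, bg, type = "cumulative")
  raw <- predict(m, bg, type = "raw")
  expect_equal(cum[which.max(raw)], 100, tolerance = 1e-9)
  expect_true(all(cum >= 0 & cum <= 100))
  # direct formula oracle on 10 points
  pts <- bg[1:10, , drop = FALSE]
  raw10 <- predict(m, pts, type = "raw")
  expect_equal(predict(m, pts, type = "cloglog"),
               1 - exp(-exp(m$entropy) * raw10), tolerance = 1e-12)
  expect_error(predict(m, bg, type = "nope"), "output mode")
})

test_that("response curves reflect the fitted shape", {
  fit <- small_fit()
  # all-zero model: flat curve
  m0 <- fit_maxent(fit$pres_values, fit$background, feature_spec("L"),
                   rm = 1e7)
  rc0 <- response_curve(m0, "tas2")
  expect_equal(length(unique(round(rc0$cloglog, 12))), 1L)
  # the truth is unimodal in tas2 (positive linear + negative quadratic):
  # the fitted response has an interior optimum
  rc <- response_curve(fit$model, "tas2", n_points = 200)
  peak <- which.max(rc$cloglog)
  expect_gt(peak, 5); expect_lt(peak, 196)
  # a pure positive linear model is monotone nondecreasing
  set.seed(13)
  bgv <- cbind(a = runif(400), b = runif(400))
  bgl <- list(values = bgv)
  pres <- cbind(a = runif(60, 0.6, 1), b = runif(60))
  ml <- fit_maxent(pres, bgl, feature_spec("L"), rm = 1)
  rcl <- response_curve(ml, "a")
  expect_true(all(diff(rcl$cloglog) >= -1e-12))
})

test_that("percent contributions are normalized and identify the driver", {
  fit <- small_fit()
  pc <- percent_contribution(fit$model, fit$pres_values, seed = 5)
  expect_equal(sum(pc), 100, tolerance = 0.1)
  # tas2 dominates the truth, so it dominates the contributions
  expect_equal(names(which.max(pc)), "tas2")
  # single-variable model: 100% by construction
  bg1 <- fit$background
  bg1$values <- bg1$values[, "tas2", drop = FALSE]
  m1 <- fit_maxent(fit$pres_values[, "tas2", drop = FALSE], bg1,
                   feature_spec("LQ"), rm = 1)
  pc1 <- percent_contribution(m1, fit$pres_values[, "tas2", drop = FALSE])
  expect_equal(unname(pc1), 100)
})

test_that("exchangeable variables share the contribution evenly", {
  set.seed(14)
  n <- 2000
  bgv <- cbind(a = rnorm(n), b = rnorm(n))
  w <- exp(1.5 * bgv[, 1] + 1.5 * bgv[, 2])
  pres_idx <- sample(n, 150, prob = w)
  pres <- bgv[pres_idx, , drop = FALSE]
  m <- fit_maxent(pres, list(values = bgv), feature_spec("L"), rm = 1)
  pc <- percent_contribution(m, pres, seed = 6)
  expect_lt(abs(pc["a"] - 50), 10)
})

test_that("jackknife gains single out the dominant variable", {
  fit <- small_fit()
  set.seed(15)
  pv <- cbind(fit$pres_values,
              noise = rnorm(nrow(fit$pres_values)))
  bg <- fit$background
  bg$values <- cbind(bg$values, noise = rnorm(nrow(bg$values)))
  jk <- jackknife_gain(pv, bg, feature_spec("LQ"), rm = 1)
  tb <- jk$table
  expect_equal(tb$variable[which.max(tb$with_only)], "tas2")
  expect_equal(tb$variable[which.min(tb$without)], "tas2")
  # a pure-noise variable carries (almost) no gain on its own
  expect_lt(tb$with_only[tb$variable == "noise"], 0.05)
  # the full model gains at least as much as any leave-one-out model
  expect_true(all(jk$full_gain >= tb$without - 1e-3))
})

test_that("replicated runs average and spread as expected", {
  fit <- small_fit()
  w <- fit$world
  reps <- replicate_runs(fit$pres_values, fit$background, w$stack,
                         feature_spec("LQ"), rm = 1, n_reps = 1,
                         base_seed = 21)
  expect_true(all(reps$sd$values == 0, na.rm = TRUE))
  reps3 <- replicate_runs(fit$pres_values, fit$background, w$stack,
                          feature_spec("LQ"), rm = 1, n_reps = 3,
                          base_seed = 21)
  expect_true(any(reps3$sd$values > 0))
  # the ensemble mean tracks truth at least as well as the worst replicate
  tab <- stack_table(w$stack)
  truth_v <- w$truth$values[tab$cells]
  rho_mean <- cor(reps3$mean$values[tab$cells], truth_v, method = "spearman")
  rho_reps <- vapply(reps3$replicates, function(r)
    cor(r$grid$values[tab$cells], truth_v, method = "spearman"), numeric(1))
  expect_gte(rho_mean, min(rho_reps))
  # deterministic under the same base seed
  reps3b <- replicate_runs(fit$pres_values, fit$background, w$stack,
                           feature_spec("LQ"), rm = 1, n_reps = 3,
                           base_seed = 21)
  expect_identical(reps3$mean$values, reps3b$mean$values)
})

test_that("background sampling respects the buffer and the seed", {
  fit <- small_fit()
  w <- fit$world
  occ1 <- fit$occ[1, , drop = FALSE]
  bg <- sample_background(occ1, w$stack, buffer_km = 150, m = 15, seed = 4)
  d <- geosphere::distHaversine(cbind(bg$lon, bg$lat),
                                c(occ1$lon, occ1$lat)) / 1000
  expect_true(all(d <= 150))
  bg2 <- sample_background(occ1, w$stack, buffer_km = 150, m = 15, seed = 4)
  expect_identical(bg$cells, bg2$cells)
  # a buffer covering the whole grid samples the grid uniformly
  expect_warning(
    bg_all <- sample_background(occ1, w$stack, buffer_km = 1e5,
                                m = 1e6, seed = 4),
    "taking all")
  expect_equal(length(bg_all$cells), sum(!is.na(w$stack$layers[[1]]$values)))
})
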