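# Shared fixtures, built in code. The small world is used by several
# test files; heavier objects are memoized so they are built once per
# test run.

tiny_grid <- function(values = matrix(1:6, 2, 3, byrow = TRUE),
                      x0 = -10, y0 = 40, cs = 0.5) {
  suit_grid(values, x0, y0, cs)
}

small_recipe <- function(...) {
  args <- utils::modifyList(
    list(layer_names = c("tas2", "bio15", "prec2"),
         n_rows = 40, n_cols = 40, n_presences = 150,
         contamination_fraction = 0.1, seed = 7,
         truth_coefficients = list(linear = c(tas2 = 2, bio15 = 1),
                                   quadratic = c(tas2 = -1))),
    list(...))
  do.call(world_recipe, args)
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

small_world <- function() memo("small_world", make_world(small_recipe()))

# a fitted LQ model on the small world, with its background and presences
small_fit <- function() memo("small_fit", {
  w <- small_world()
  occ <- dedupe_to_cells(modeling_records(partition_datasets(w$occurrences)),
                         w$stack$layers[[1]])
  bg <- sample_background(occ, w$stack, buffer_km = 3000, m = 800, seed = 3)
  pv <- stack_extract(w$stack, occ$lon, occ$lat)
  model <- fit_maxent(pv, bg, feature_spec("LQ"), rm = 1)
  list(world = w, occ = occ, background = bg, pres_values = pv,
       model = model)
})

# the study-scale world: default recipe (100 x 100 grid, 7 layers,
# 1000 presences), deduplicated occurrences, background and presence
# values — shared by the recovery/screening acceptance checks
study_objects <- function() memo("study", {
  w <- make_world(world_recipe())
  occ <- dedupe_to_cells(modeling_records(partition_datasets(w$occurrences)),
                         w$stack$layers[[1]])
  bg <- sample_background(occ, w$stack, buffer_km = 10000, m = 10000,
                          seed = 31)
  pv <- stack_extract(w$stack, occ$lon, occ$lat)
  list(world = w, occ = occ, background = bg, pres_values = pv)
})

# independent brute-force Moran's I (O(n^2) double sum, fresh distances)
oracle_morans_i <- function(lon, lat, values, w_max = 100) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0; sw <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- geosphere::distHaversine(c(lon[i], lat[i]), c(lon[j], lat[j])) / 1000
    w <- if (d == 0) w_max else min(1 / d, w_max)
    num <- num + w * z[i] * z[j]
    sw <- sw + w
  }
  (n / sw) * num / sum(z^2)
}

# independent pair-counting AUC
oracle_auc <- function(pres, abs) {
  tot <- 0
  for (p in pres) for (a in abs)
    tot <- tot + (p > a) + 0.5 * (p == a)
  tot / (length(pres) * length(abs))
}
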