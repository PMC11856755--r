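rec_df <- function(lon, lat, year = 2000, elevation = NA_real_,
                   greenhouse = FALSE, summer = FALSE) {
  data.frame(lon = lon, lat = lat, year = year, elevation = elevation,
             greenhouse_flag = greenhouse, summer_only_flag = summer,
             source = "t")
}

test_that("partition follows the window and flag rules and is exhaustive", {
  rec <- rbind(rec_df(0, 0, 1995), rec_df(1, 0, 2018),
               rec_df(2, 0, 2000, greenhouse = TRUE),
               rec_df(3, 0, 1979), rec_df(4, 0, 2024, summer = TRUE))
  p <- partition_datasets(rec)
  expect_equal(as.character(p$partition),
               c("basic", "expanded_only", "excluded", "excluded", "excluded"))
  expect_equal(sum(table(p$partition)), nrow(rec))
  # idempotent
  p2 <- partition_datasets(as.data.frame(p)[names(rec)])
  expect_equal(p2$partition, p$partition)
  # missing years go to excluded with a warning
  expect_warning(p3 <- partition_datasets(rec_df(0, 0, NA)), "without a year")
  expect_equal(as.character(p3$partition), "excluded")
})

test_that("modeling_records selects the right windows", {
  rec <- rbind(rec_df(0, 0, 1990), rec_df(1, 0, 2020),
               rec_df(2, 0, 2005, greenhouse = TRUE))
  p <- partition_datasets(rec)
  expect_equal(nrow(modeling_records(p, "basic")), 1L)
  expect_equal(nrow(modeling_records(p, "expanded")), 2L)
})

test_that("cell deduplication keeps the earliest record per cell", {
  g <- suit_grid(matrix(0, 4, 4), 0, 0, 1)
  rec <- rbind(rec_df(0.2, 0.2, 2005), rec_df(0.8, 0.7, 1998),  # same cell
               rec_df(2.5, 2.5, 2010))
  out <- dedupe_to_cells(rec, g)
  expect_equal(nrow(out), 2L)
  expect_true(1998 %in% out$year && !(2005 %in% out$year))
  # all-distinct input unchanged
  rec2 <- rec_df(c(0.5, 1.5, 2.5), c(0.5, 1.5, 2.5))
  expect_equal(nrow(dedupe_to_cells(rec2, g)), 3L)
  # 5 records in 3 cells -> 3 survive (brute-force cell indexing)
  rec3 <- rec_df(c(0.1, 0.9, 1.1, 1.2, 3.5), c(0.1, 0.9, 1.5, 1.4, 3.5),
                 year = c(2001, 2002, 2003, 2004, 2005))
  out3 <- dedupe_to_cells(rec3, g)
  cells <- paste(floor(rec3$lon), floor(rec3$lat))
  expect_equal(nrow(out3), length(unique(cells)))
  # off-grid records are dropped with a warning
  expect_warning(out4 <- dedupe_to_cells(rec_df(c(0.5, 9.5), c(0.5, 0.5)), g),
                 "outside the grid")
  expect_equal(nrow(out4), 1L)
})

test_that("Moran's I matches closed forms and the brute-force oracle", {
  # two points, values (0, 1): I = -1 exactly
  r <- morans_i(c(0, 1), c(0, 0), c(0, 1))
  expect_equal(r$morans_i, -1.0, tolerance = 1e-12)
  expect_equal(r$n_points, 2L)
  # random values over many points: near zero
  set.seed(9)
  n <- 200
  lon <- runif(n, -5, 5); lat <- runif(n, -5, 5); v <- rnorm(n)
  expect_lt(abs(morans_i(lon, lat, v)$morans_i), 0.1)
  # 4 points on a unit square, values (1,1,0,0): O(n^2) oracle
  lon4 <- c(0, 1, 0, 1); lat4 <- c(0, 0, 1, 1); v4 <- c(1, 1, 0, 0)
  expect_equal(morans_i(lon4, lat4, v4)$morans_i,
               oracle_morans_i(lon4, lat4, v4), tolerance = 1e-12)
  # randomized fixtures agree with the oracle to 1e-12
  for (k in 1:5) {
    set.seed(100 + k)
    m <- 12
    lo <- runif(m, -20, 20); la <- runif(m, -20, 20); vv <- rnorm(m)
    expect_equal(morans_i(lo, la, vv)$morans_i,
                 oracle_morans_i(lo, la, vv), tolerance = 1e-12)
  }
  expect_error(morans_i(c(0, 1), c(0, 0), c(2, 2)), "constant")
  # duplicate coordinates: weight capped, statistic still finite
  expect_message(rd <- morans_i(c(0, 0, 1), c(0, 0, 0), c(0, 1, 2)), "capped")
  expect_true(is.finite(rd$morans_i))
})

test_that("thinning reaches the Moran's I target on a clustered fixture", {
  w <- small_world()
  occ <- dedupe_to_cells(modeling_records(partition_datasets(w$occurrences)),
                         w$stack$layers[[1]])
  thin <- thin_by_morans(occ, w$stack, target = 0.2, floor = 20)
  expect_lt(max(thin$morans_i, na.rm = TRUE), 0.2)
  # output is a subset of the input
  key <- function(d) paste(d$lon, d$lat)
  expect_true(all(key(thin$records) %in% key(occ)))
  # the reported I matches the from-scratch oracle statistic
  vals <- stack_extract(w$stack, thin$records$lon, thin$records$lat)
  for (j in seq_len(ncol(vals))) {
    expect_equal(unname(thin$morans_i[j]),
                 oracle_morans_i(thin$records$lon, thin$records$lat,
                                 vals[, j]),
                 tolerance = 1e-10)
  }
  # max I decreases monotonically along the removal trace
  if (length(thin$trace) > 1)
    expect_lt(thin$trace[length(thin$trace)], thin$trace[1] + 1e-9)
})

test_that("thinning is a no-op below target and errors at the floor", {
  w <- small_world()
  # four far-apart points are spatially uncorrelated
  occ <- rec_df(c(-28, -22, -16, -11), c(-23, -17, -11, -6), 2000)
  thin <- thin_by_morans(occ, w$stack, target = 0.99, floor = 2)
  expect_equal(nrow(thin$records), 4L)
  expect_equal(length(thin$removed), 0L)
  # unreachable target hits the floor with a diagnosis
  occ2 <- dedupe_to_cells(modeling_records(partition_datasets(w$occurrences)),
                          w$stack$layers[[1]])
  expect_error(thin_by_morans(occ2, w$stack, target = 1e-6,
                              floor = nrow(occ2) - 3),
               "thinning failed")
})

test_that("a duplicated tight cluster is depleted before scattered points", {
  w <- small_world()
  scatter <- rec_df(seq(-29, -11, length.out = 8),
                    seq(-24, -6, length.out = 8), 2000)
  cluster <- rec_df(-20 + 0.45 * (0:4), rep(-10, 5), 2001)
  occ <- rbind(scatter, cluster)
  thin <- thin_by_morans(occ, w$stack, target = 0.2, floor = 5)
  if (length(thin$removed)) {
    # every removal must come from the cluster (rows 9..13)
    expect_true(all(thin$removed > 8))
  }
  succeed()
})

test_that("boundary shifts equal brute-force extent differences", {
  a <- rec_df(c(0, 5, 10), c(-10, 0, 10), elevation = c(100, 900, 500))
  expect_true(all(boundary_summary(a, a)$delta == 0))
  b <- rbind(a, rec_df(20, 0, elevation = 10))
  bs <- boundary_summary(a, b)
  expect_equal(bs$delta[bs$boundary == "east"], 10)
  expect_equal(bs$delta[bs$boundary == "north"], 0)
  # synthetic basic vs expanded: deltas equal direct min/max scans
  w <- small_world()
  p <- partition_datasets(w$occurrences)
  basic <- p[p$partition == "basic", ]
  expanded <- p[p$partition %in% c("basic", "expanded_only"), ]
  bs2 <- boundary_summary(basic, expanded)
  expect_equal(bs2$delta[bs2$boundary == "west"],
               min(expanded$lon) - min(basic$lon))
  expect_equal(bs2$delta[bs2$boundary == "north"],
               max(expanded$lat) - max(basic$lat))
  expect_equal(bs2$delta[bs2$boundary == "max_elevation"],
               max(expanded$elevation) - max(basic$elevation))
})

test_that("occurrence CSV round-trips", {
  w <- small_world()
  f <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(w$occurrences, f)
  back <- read_occurrences(f)
  expect_equal(back$lon, w$occurrences$lon)
  expect_equal(back$greenhouse_flag, w$occurrences$greenhouse_flag)
})
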