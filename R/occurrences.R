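#' Validate occurrence records
#'
#' @param records Data.frame with columns `lon`, `lat`, `year`, and
#'   optionally `elevation`, `greenhouse_flag`, `summer_only_flag`,
#'   `source`. Missing flag columns default to `FALSE`.
#' @return The records with all columns present, invisibly checked.
#' @keywords internal
normalize_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("lon", "lat")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop(sprintf("records lack column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (!"year" %in% names(records)) records$year <- NA_integer_
  if (!"elevation" %in% names(records)) records$elevation <- NA_real_
  if (!"greenhouse_flag" %in% names(records)) records$greenhouse_flag <- FALSE
  if (!"summer_only_flag" %in% names(records)) records$summer_only_flag <- FALSE
  if (!"source" %in% names(records)) records$source <- ""
  if (any(records$lon < -180 | records$lon > 180, na.rm = TRUE) ||
      any(records$lat < -90 | records$lat > 90, na.rm = TRUE))
    stop("coordinates outside [-180,180] x [-90,90]")
  bad_year <- !is.na(records$year) & (records$year < 1900 | records$year > 2100)
  if (any(bad_year)) stop("year outside 1900-2100")
  records
}

#' Partition occurrence records into basic / expanded / excluded datasets
#'
#' Natural (unflagged) records dated 1981-2010 form the basic dataset,
#' the fixed-niche snapshot matching the near-current climatology window.
#' Natural records dated 2011-2024 extend it to the expanding-niche
#' dataset. Records flagged greenhouse or summer-only are excluded from
#' modeling regardless of year — they persist outside the open-air
#' climate envelope and would bias a climatic niche estimate — as are
#' natural records with no usable year (with a warning) or a year outside
#' both windows.
#'
#' @param records Occurrence data.frame (see [normalize_records()]).
#' @return The records with an added factor column `partition` with
#'   levels `basic`, `expanded_only`, `excluded`; class `occ_dataset`.
#' @export
partition_datasets <- function(records) {
  rec <- normalize_records(records)
  flagged <- rec$greenhouse_flag | rec$summer_only_flag
  no_year <- is.na(rec$year)
  if (any(no_year & !flagged))
    warning(sprintf("%d natural record(s) without a year sent to 'excluded'",
                    sum(no_year & !flagged)))
  part <- rep("excluded", nrow(rec))
  part[!flagged & !no_year & rec$year >= 1981 & rec$year <= 2010] <- "basic"
  part[!flagged & !no_year & rec$year >= 2011 & rec$year <= 2024] <- "expanded_only"
  rec$partition <- factor(part, levels = c("basic", "expanded_only", "excluded"))
  class(rec) <- c("occ_dataset", "data.frame")
  rec
}

#' Subset of a partitioned dataset used for modeling
#' @param dataset An `occ_dataset`.
#' @param which `"basic"` (1981-2010 only) or `"expanded"` (1981-2024).
#' @return Data.frame of modeling records.
#' @export
modeling_records <- function(dataset, which = c("expanded", "basic")) {
  which <- match.arg(which)
  keep <- if (which == "basic") dataset$partition == "basic"
          else dataset$partition %in% c("basic", "expanded_only")
  dataset[keep, , drop = FALSE]
}

#' Deduplicate occurrences to one record per grid cell
#'
#' Within each grid cell, keeps the earliest-year record (ties broken by
#' input order), so each occupied environmental cell contributes exactly
#' one point. Records falling outside the grid extent are dropped with a
#' warning.
#'
#' @param dataset Occurrence data.frame.
#' @param grid A `suit_grid` defining the cells.
#' @return The retained records, same columns, original order.
#' @export
dedupe_to_cells <- function(dataset, grid) {
  stopifnot_grid(grid)
  rec <- as.data.frame(dataset)
  idx <- grid_locate(grid, rec$lon, rec$lat)
  off <- is.na(idx$cell)
  if (any(off))
    warning(sprintf("%d record(s) outside the grid extent dropped", sum(off)))
  rec <- rec[!off, , drop = FALSE]
  cell <- idx$cell[!off]
  yr <- rec$year
  yr[is.na(yr)] <- .Machine$integer.max
  ord <- order(cell, yr, seq_len(nrow(rec)))
  keep_rows <- ord[!duplicated(cell[ord])]
  out <- rec[sort(keep_rows), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Moran's I spatial autocorrelation for point values
#'
#' Global Moran's I with inverse great-circle-distance weights:
#' `I = (n / sum(w)) * sum_ij(w_ij z_i z_j) / sum_i(z_i^2)` with
#' `z = value - mean`, `w_ij = 1 / d_ij` for `i != j`. Coincident points
#' (zero distance) get their weight capped at `w_max`, with a message.
#'
#' @param lon,lat Point coordinates in decimal degrees.
#' @param values Numeric vector of the variable observed at each point.
#' @param w_max Weight cap for (near-)duplicate coordinates, per km^-1.
#' @return List with `morans_i`, `n_points`, `weighting`.
#' @export
morans_i <- function(lon, lat, values, w_max = 100) {
  n <- length(values)
  if (n < 2L) stop("Moran's I needs at least 2 points")
  if (stats::sd(values) == 0)
    stop("Moran's I is undefined for constant values")
  d <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) / 1000
  w <- 1 / d
  diag(w) <- 0
  capped <- is.infinite(w) | w > w_max
  if (any(capped)) {
    w[capped] <- w_max
    diag(w) <- 0
    message(sprintf("capped %d duplicate/near-duplicate weight(s) at %g",
                    sum(capped) - 0L, w_max))
  }
  z <- values - mean(values)
  I <- (n / sum(w)) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
  list(morans_i = I, n_points = n, weighting = "inverse great-circle distance (km)")
}

# Moran's I across several variables; returns the per-variable vector
morans_i_panel <- function(lon, lat, value_matrix, w_max = 100) {
  apply(value_matrix, 2, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    suppressMessages(morans_i(lon, lat, v, w_max = w_max)$morans_i)
  })
}

#' Thin occurrences until spatial autocorrelation falls below a target
#'
#' Iteratively removes one member of the current closest pair of points
#' until the maximum Moran's I across the screened environmental
#' variables drops below `target` (default 0.2). Of the two closest
#' points, the one whose removal lowers that maximum most is removed
#' (ties: the later-year record). Stops with an error if the record count
#' would fall below `floor` first.
#'
#' @param dataset Cell-deduplicated occurrence data.frame.
#' @param stack A `suit_stack` of screened environmental variables.
#' @param target Moran's I ceiling (default 0.2).
#' @param floor Minimum records retained (default 30).
#' @param w_max Duplicate-distance weight cap passed to [morans_i()].
#' @return List with `records` (the thinned data.frame), `morans_i`
#'   (final per-variable values), `removed` (row indices of the input
#'   removed, in order), and `trace` (max I after each removal).
#' @export
thin_by_morans <- function(dataset, stack, target = 0.2, floor = 30,
                           w_max = 100) {
  stopifnot_stack(stack)
  rec <- as.data.frame(dataset)
  vals <- stack_extract(stack, rec$lon, rec$lat)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(rec))
  ok <- stats::complete.cases(vals)
  if (any(!ok)) {
    warning(sprintf("%d record(s) on nodata cells dropped before thinning",
                    sum(!ok)))
    rec <- rec[ok, , drop = FALSE]; vals <- vals[ok, , drop = FALSE]
  }
  alive <- seq_len(nrow(rec))
  D <- geosphere::distm(cbind(rec$lon, rec$lat),
                        fun = geosphere::distHaversine) / 1000
  diag(D) <- Inf
  W <- 1 / D
  W[W > w_max] <- w_max
  diag(W) <- 0
  # Moran's I per variable on the precomputed weight matrix (same
  # statistic as morans_i(), which recomputes distances from scratch)
  cur_I <- function(idx) {
    Ws <- W[idx, idx, drop = FALSE]
    sw <- sum(Ws)
    n_i <- length(idx)
    apply(vals[idx, , drop = FALSE], 2, function(v) {
      z <- v - mean(v)
      s2 <- sum(z^2)
      if (s2 == 0) return(NA_real_)
      (n_i / sw) * as.numeric(t(z) %*% Ws %*% z) / s2
    })
  }
  removed <- integer(0); trace <- numeric(0)
  I <- cur_I(alive)
  maxI <- max(I, na.rm = TRUE)
  while (maxI >= target) {
    if (length(alive) - 1L < floor)
      stop(sprintf(paste0("thinning failed: Moran's I still %.3f (target %g) ",
                          "at the floor of %d records"), maxI, target, floor))
    sub <- D[alive, alive, drop = FALSE]
    pair <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    cand <- alive[c(pair[1], pair[2])]
    drop_scores <- vapply(cand, function(ci) {
      max(cur_I(setdiff(alive, ci)), na.rm = TRUE)
    }, numeric(1))
    if (abs(diff(drop_scores)) < 1e-12) {
      yrs <- rec$year[cand]; yrs[is.na(yrs)] <- -Inf
      drop <- cand[which.max(yrs)]
    } else drop <- cand[which.min(drop_scores)]
    alive <- setdiff(alive, drop)
    removed <- c(removed, drop)
    I <- cur_I(alive)
    maxI <- max(I, na.rm = TRUE)
    trace <- c(trace, maxI)
  }
  out <- rec[alive, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, morans_i = I, removed = removed, trace = trace)
}

#' Range-boundary shift between two occurrence datasets
#'
#' Deltas (b minus a) of the west/east/south/north boundaries and of the
#' maximum elevation — the summary used to ask whether an expanding
#' dataset has pushed into new latitudes, longitudes, or altitudes.
#'
#' @param a,b Occurrence data.frames.
#' @return Data.frame with the boundary values of each dataset and their
#'   deltas (degrees; meters for elevation).
#' @export
boundary_summary <- function(a, b) {
  if (!nrow(a) || !nrow(b)) stop("both datasets must be non-empty")
  f <- function(d) c(west = min(d$lon), east = max(d$lon),
                     south = min(d$lat), north = max(d$lat),
                     max_elevation = if (all(is.na(d$elevation))) NA_real_
                                     else max(d$elevation, na.rm = TRUE))
  va <- f(a); vb <- f(b)
  data.frame(boundary = names(va), a = unname(va), b = unname(vb),
             delta = unname(vb - va))
}

#' Write / read occurrence CSV
#' @param dataset Occurrence data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_occurrences <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  normalize_records(utils::read.csv(path, stringsAsFactors = FALSE))
}
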