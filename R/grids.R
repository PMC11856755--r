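#' Construct a geographic grid
#'
#' A `suit_grid` is a rectangular lat/lon raster: a numeric matrix whose
#' first row is the northernmost row, together with the lower-left corner
#' of the extent and a square cell size in degrees. Nodata cells are `NA`.
#' Cell ownership is half-open, `[x, x + cell_size)`, matching the ESRI
#' ASCII convention.
#'
#' @param values Numeric matrix; row 1 is the northernmost row. `NA`
#'   marks nodata cells.
#' @param x_origin,y_origin Longitude/latitude of the lower-left corner of
#'   the extent, in decimal degrees.
#' @param cell_size Cell edge length in decimal degrees (> 0).
#' @return An object of class `suit_grid`.
#' @examples
#' g <- suit_grid(matrix(1:6, 2, 3, byrow = TRUE), -10, 40, 0.5)
#' grid_dim(g)
#' @export
suit_grid <- function(values, x_origin, y_origin, cell_size) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (any(!is.finite(values) & !is.na(values)))
    stop("unmasked values must be finite (use NA for nodata)")
  xmax <- x_origin + ncol(values) * cell_size
  ymax <- y_origin + nrow(values) * cell_size
  if (x_origin < -180 - 1e-9 || xmax > 180 + 1e-9 ||
      y_origin < -90 - 1e-9 || ymax > 90 + 1e-9)
    stop("grid extent must lie within [-180,180] x [-90,90]")
  structure(
    list(values = values, x_origin = as.numeric(x_origin),
         y_origin = as.numeric(y_origin), cell_size = as.numeric(cell_size)),
    class = "suit_grid")
}

#' @export
print.suit_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<suit_grid> %d x %d cells, %g deg, origin (%g, %g), %d nodata\n",
              d[1], d[2], x$cell_size, x$x_origin, x$y_origin,
              sum(is.na(x$values))))
  invisible(x)
}

#' Grid dimensions
#' @param grid A `suit_grid`.
#' @return Integer vector `c(n_rows, n_cols)`.
#' @export
grid_dim <- function(grid) dim(grid$values)

is_grid <- function(x) inherits(x, "suit_grid")

stopifnot_grid <- function(x) {
  if (!is_grid(x)) stop("expected a `suit_grid` object")
  invisible(x)
}

#' Cell-center coordinates
#'
#' Longitude/latitude of every cell center, in the row-major order of the
#' value matrix (row 1 = northernmost).
#'
#' @param grid A `suit_grid`.
#' @return A data.frame with columns `lon`, `lat`, `row`, `col`.
#' @export
grid_centers <- function(grid) {
  stopifnot_grid(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  lon <- grid$x_origin + (seq_len(nc) - 0.5) * grid$cell_size
  lat <- grid$y_origin + (nr - seq_len(nr) + 0.5) * grid$cell_size
  data.frame(lon = rep(lon, each = nr), lat = rep(lat, times = nc),
             row = rep(seq_len(nr), times = nc),
             col = rep(seq_len(nc), each = nr))[order(rep(seq_len(nr), nc)), ,
                                                drop = FALSE]
}

#' Locate points on a grid
#'
#' Maps lon/lat points to row/column indices under half-open cell
#' ownership `[x, x + cell_size)`. Points outside the extent get `NA`.
#'
#' @param grid A `suit_grid`.
#' @param lon,lat Numeric vectors of coordinates in decimal degrees.
#' @return A data.frame with columns `row`, `col`, and `cell` (row-major
#'   linear index, `NA` off-grid).
#' @export
grid_locate <- function(grid, lon, lat) {
  stopifnot_grid(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - grid$x_origin) / grid$cell_size) + 1
  row_from_bottom <- floor((lat - grid$y_origin) / grid$cell_size) + 1
  row <- nr - row_from_bottom + 1
  bad <- col < 1 | col > nc | row < 1 | row > nr | !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((col - 1L) * nr + row))
}

#' Extract grid values at points
#' @param grid A `suit_grid`.
#' @param lon,lat Coordinates in decimal degrees.
#' @return Numeric vector of cell values (`NA` off-grid or nodata).
#' @export
grid_extract <- function(grid, lon, lat) {
  idx <- grid_locate(grid, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(idx$row)
  out[ok] <- grid$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-key header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`; the nodata key is optional and
#' case-insensitive) followed by `nrows` rows of `ncols` whitespace-
#' separated values, northernmost row first.
#'
#' @param path Path to a `.asc` file.
#' @return A `suit_grid` with nodata cells masked as `NA`.
#' @seealso [write_ascii_grid()]
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list(); i <- 0L
  header_keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value", "xllcenter", "yllcenter")
  while (i < length(lines)) {
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(tok) == 2L && tolower(tok[1]) %in% header_keys) {
      key <- tolower(tok[1])
      if (!is.null(hdr[[key]]))
        stop(sprintf("duplicate header key '%s' in %s", key, path))
      hdr[[key]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop(sprintf("missing header key(s) %s in %s",
                 paste(miss, collapse = ", "), path))
  if (is.null(hdr$xllcorner)) {
    if (is.null(hdr$xllcenter)) stop(sprintf("missing header key xllcorner in %s", path))
    hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
  }
  if (is.null(hdr$yllcorner)) {
    if (is.null(hdr$yllcenter)) stop(sprintf("missing header key yllcorner in %s", path))
    hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- lines[seq.int(i + 1L, length(lines))]
  vals <- vector("list", length(body))
  for (k in seq_along(body)) {
    row <- as.numeric(strsplit(trimws(body[k]), "\\s+")[[1]])
    if (length(row) != nc)
      stop(sprintf("row %d has %d values, expected %d (%s)",
                   k, length(row), nc, path))
    vals[[k]] <- row
  }
  if (length(vals) != nr)
    stop(sprintf("found %d data rows, expected %d (%s)", length(vals), nr, path))
  m <- do.call(rbind, vals)
  m[m == nodata] <- NA_real_
  suit_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with 17 significant digits so that a read/write
#' round trip preserves the numeric payload bit-for-bit.
#'
#' @param grid A `suit_grid`.
#' @param path Output path.
#' @param nodata Token written for masked cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot_grid(grid)
  if (any(!is.finite(grid$values) & !is.na(grid$values)))
    stop("refusing to write non-finite unmasked values")
  v <- grid$values
  fmt <- function(x) {
    s <- vapply(x, function(e) {
      if (is.na(e)) format(nodata) else sprintf("%.17g", e)
    }, character(1))
    paste(s, collapse = " ")
  }
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.17g", grid$x_origin),
           sprintf("yllcorner %.17g", grid$y_origin),
           sprintf("cellsize %.17g", grid$cell_size),
           sprintf("NODATA_value %s", format(nodata)))
  body <- vapply(seq_len(nrow(v)), function(i) fmt(v[i, ]), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Block-aggregate a grid to a coarser resolution
#'
#' Each output cell is the mean (or nearest-neighbor pick) of its
#' `factor` x `factor` block of input cells; masked cells are ignored and
#' a fully masked block stays masked. When the grid dimensions are not
#' divisible by `factor`, the south and east edges are padded with nodata
#' (with a warning) rather than erroring, so a 30 arc-second grid
#' aggregates to 2.5 arc-minutes with `factor = 5`.
#'
#' @param grid A `suit_grid`.
#' @param factor Positive integer block edge.
#' @param method `"mean"` (block average of unmasked values) or
#'   `"nearest"` (value of the block's northwest cell).
#' @return A `suit_grid` with `cell_size * factor`.
#' @export
aggregate_resample <- function(grid, factor, method = c("mean", "nearest")) {
  stopifnot_grid(grid)
  method <- match.arg(method)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  pr <- (factor - nr %% factor) %% factor
  pc <- (factor - nc %% factor) %% factor
  if (pr > 0L || pc > 0L) {
    warning(sprintf("padding %d row(s) south, %d col(s) east with nodata", pr, pc))
    v <- rbind(v, matrix(NA_real_, pr, nc))
    v <- cbind(v, matrix(NA_real_, nr + pr, pc))
    nr <- nr + pr; nc <- nc + pc
  }
  onr <- nr %/% factor; onc <- nc %/% factor
  out <- matrix(NA_real_, onr, onc)
  if (method == "mean") {
    # fold each factor x factor block with colSums over a reshaped array
    ri <- rep(seq_len(onr), each = factor)
    ci <- rep(seq_len(onc), each = factor)
    sums <- rowsum(v, ri, na.rm = TRUE)
    cnts <- rowsum(1 - is.na(v) * 1, ri)
    sums <- t(rowsum(t(sums), ci, na.rm = TRUE))
    cnts <- t(rowsum(t(cnts), ci))
    out <- sums / cnts
    out[cnts == 0] <- NA_real_
  } else {
    out <- v[seq(1L, nr, by = factor), seq(1L, nc, by = factor), drop = FALSE]
  }
  # padded grids keep the original lower-left x; y origin drops by the pad
  suit_grid(out, grid$x_origin, grid$y_origin - pr * grid$cell_size,
            grid$cell_size * factor)
}

#' Per-cell spherical area in km^2
#'
#' Area of each cell on the authalic sphere (R = 6371.0088 km):
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`. Depends only on the
#' latitude band, never on longitude; the mask is ignored (every cell gets
#' an area) so callers can subset as needed.
#'
#' @param grid A `suit_grid`.
#' @return A `suit_grid` of cell areas in km^2 (no nodata).
#' @export
cell_area_km2 <- function(grid) {
  stopifnot_grid(grid)
  R <- 6371.0088
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  lat_bottom <- grid$y_origin + (nr - seq_len(nr)) * cs
  lat_top <- lat_bottom + cs
  band <- R^2 * (cs * pi / 180) * (sin(lat_top * pi / 180) - sin(lat_bottom * pi / 180))
  suit_grid(matrix(band, nr, nc), grid$x_origin, grid$y_origin, cs)
}

#' Bundle aligned grids into a named stack
#'
#' A `suit_stack` is an ordered named list of `suit_grid` layers sharing
#' origin, cell size, shape, and nodata mask — the carrier for a set of
#' climate variables.
#'
#' @param layers Named list of `suit_grid` objects.
#' @return A `suit_stack`.
#' @export
suit_stack <- function(layers) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("`layers` must be a non-empty list of grids")
  if (is.null(names(layers)) || any(!nzchar(names(layers))) ||
      anyDuplicated(names(layers)))
    stop("layers must have unique non-empty names")
  for (g in layers) stopifnot_grid(g)
  ref <- layers[[1]]
  for (g in layers[-1]) {
    if (!identical(dim(g$values), dim(ref$values)) ||
        abs(g$x_origin - ref$x_origin) > 1e-9 ||
        abs(g$y_origin - ref$y_origin) > 1e-9 ||
        abs(g$cell_size - ref$cell_size) > 1e-12)
      stop("all layers must share origin, cell size and shape")
    if (!identical(is.na(g$values), is.na(ref$values)))
      stop("all layers must share the same nodata mask")
  }
  structure(list(layers = layers), class = "suit_stack")
}

#' @export
print.suit_stack <- function(x, ...) {
  d <- dim(x$layers[[1]]$values)
  cat(sprintf("<suit_stack> %d layer(s) [%s], %d x %d cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              d[1], d[2]))
  invisible(x)
}

#' @export
names.suit_stack <- function(x) names(x$layers)

is_stack <- function(x) inherits(x, "suit_stack")

stopifnot_stack <- function(x) {
  if (!is_stack(x)) stop("expected a `suit_stack` object")
  invisible(x)
}

#' Stack values as a matrix
#'
#' Unmasked cells of every layer as a cells-by-layers matrix, plus the
#' row-major linear indices of those cells.
#'
#' @param stack A `suit_stack`.
#' @return List with `values` (matrix), `cells` (linear indices into the
#'   value matrix), `lon`, `lat` (cell centers).
#' @export
stack_table <- function(stack) {
  stopifnot_stack(stack)
  ref <- stack$layers[[1]]
  keep <- which(!is.na(ref$values))
  vals <- vapply(stack$layers, function(g) g$values[keep],
                 numeric(length(keep)))
  if (length(keep) == 1L) vals <- matrix(vals, nrow = 1L,
                                         dimnames = list(NULL, names(stack$layers)))
  nr <- nrow(ref$values)
  row <- ((keep - 1L) %% nr) + 1L
  col <- ((keep - 1L) %/% nr) + 1L
  lon <- ref$x_origin + (col - 0.5) * ref$cell_size
  lat <- ref$y_origin + (nr - row + 0.5) * ref$cell_size
  list(values = vals, cells = keep, lon = lon, lat = lat)
}

#' Extract stack values at points
#' @param stack A `suit_stack`.
#' @param lon,lat Coordinates in decimal degrees.
#' @return Matrix of per-layer values, one row per point.
#' @export
stack_extract <- function(stack, lon, lat) {
  stopifnot_stack(stack)
  vapply(stack$layers, function(g) grid_extract(g, lon, lat),
         numeric(length(lon)))
}

#' Read a directory of .asc layers as a stack
#' @param paths Named character vector of file paths; names become layer codes.
#' @return A `suit_stack`.
#' @export
read_ascii_stack <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.asc$", "", basename(paths))
  suit_stack(lapply(paths, read_ascii_grid))
}

#' Write a stack as .asc files
#' @param stack A `suit_stack`.
#' @param dir Output directory (created if absent).
#' @return Named vector of written paths, invisibly.
#' @export
write_ascii_stack <- function(stack, dir) {
  stopifnot_stack(stack)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(names(stack$layers), ".asc"))
  names(paths) <- names(stack$layers)
  for (i in seq_along(paths)) write_ascii_grid(stack$layers[[i]], paths[i])
  invisible(paths)
}

# mutate a grid's values keeping geometry
grid_like <- function(grid, values) {
  suit_grid(values, grid$x_origin, grid$y_origin, grid$cell_size)
}
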