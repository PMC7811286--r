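#' Create a raster grid
#'
#' The basic gridded data container used throughout the package: a regular
#' lattice of square cells in geographic (longitude/latitude) coordinates.
#' Cell `[1, 1]` is the upper-left (north-west) cell; cell centers lie at
#' `origin + (index - 0.5) * cell_size`. Missing cells are stored as `NA`
#' internally; a numeric nodata sentinel is only used on disk.
#'
#' @param values numeric matrix (rows = latitude bands, top row first).
#' @param origin_lon,origin_lat coordinates of the grid's upper-left corner,
#'   in decimal degrees.
#' @param cell_size cell edge length in degrees (square cells).
#' @param nodata numeric sentinel written to/read from disk for `NA` cells.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin_lon = 0, origin_lat = 0,
                        cell_size = 1, nodata = -9999) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("cell_size must be a single positive number")
  }
  storage.mode(values) <- "double"
  g <- list(
    n_rows = nrow(values), n_cols = ncol(values),
    origin_lon = as.numeric(origin_lon), origin_lat = as.numeric(origin_lat),
    cell_size = as.numeric(cell_size), nodata = as.numeric(nodata),
    values = values
  )
  class(g) <- "raster_grid"
  g
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "<raster_grid> %d x %d cells, %.6g deg/cell, UL corner (%.4f, %.4f)\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat
  ))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat(sprintf("  values: [%.4g, %.4g], %d NA cells\n",
                min(v), max(v), sum(is.na(x$values))))
  } else {
    cat("  values: all NA\n")
  }
  invisible(x)
}

#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

# geometry equality used by every multi-layer operation
same_geometry <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a, b)) stop("raster geometries do not match")
  invisible(TRUE)
}

#' Cell center coordinates
#'
#' @param grid a `raster_grid`.
#' @param cells integer cell ids (row-major, `id = (row-1)*n_cols + col`);
#'   default all cells.
#' @return data.frame with columns `cell`, `row`, `col`, `lon`, `lat`.
#' @export
cell_centers <- function(grid, cells = seq_len(grid$n_rows * grid$n_cols)) {
  row <- (cells - 1L) %/% grid$n_cols + 1L
  col <- (cells - 1L) %% grid$n_cols + 1L
  data.frame(
    cell = cells, row = row, col = col,
    lon = grid$origin_lon + (col - 0.5) * grid$cell_size,
    lat = grid$origin_lat - (row - 0.5) * grid$cell_size
  )
}

#' Locate points on a grid
#'
#' Maps longitude/latitude points to row-major cell ids using half-open cell
#' intervals (a point on a shared edge belongs to the cell to its south-east
#' in index space). Points outside the grid extent get `NA`.
#'
#' @param grid a `raster_grid`.
#' @param lon,lat numeric vectors of coordinates.
#' @return integer vector of cell ids (`NA` outside the extent).
#' @export
cell_from_lonlat <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1
  row <- floor((grid$origin_lat - lat) / grid$cell_size) + 1
  ok <- !is.na(col) & !is.na(row) &
    col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- rep(NA_integer_, length(lon))
  out[ok] <- as.integer((row[ok] - 1) * grid$n_cols + col[ok])
  out
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Plain-text georeferenced raster format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows of values, northernmost row
#' first). Values are written with 17 significant digits so doubles
#' round-trip exactly.
#'
#' @param grid a `raster_grid`.
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(is_raster_grid(grid))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %s", formatC(grid$origin_lon, digits = 17, format = "g")),
    sprintf("yllcorner %s", formatC(grid$origin_lat - grid$n_rows * grid$cell_size,
                                    digits = 17, format = "g")),
    sprintf("cellsize %s", formatC(grid$cell_size, digits = 17, format = "g")),
    sprintf("NODATA_value %s", formatC(grid$nodata, digits = 17, format = "g"))
  )
  body <- apply(v, 1L, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Inverse of [write_raster()]: geometry fields and values round-trip to full
#' double precision. Cells equal to the file's nodata value become `NA`.
#'
#' @param path path to an `.asc` file.
#' @return a `raster_grid`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- suppressWarnings(as.numeric(kv[2L]))
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not a valid ASCII grid header in: ", path)
  }
  if (!is.null(hdr$dx) || !is.null(hdr$dy)) {
    stop("non-square cells are not supported: ", path)
  }
  n_cols <- as.integer(hdr$ncols)
  n_rows <- as.integer(hdr$nrows)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != n_rows * n_cols) {
    stop(sprintf("expected %d values, found %d in %s",
                 n_rows * n_cols, length(vals), path))
  }
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  xll <- if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner
  yll <- if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner
  raster_grid(m,
              origin_lon = xll,
              origin_lat = yll + n_rows * hdr$cellsize,
              cell_size = hdr$cellsize, nodata = nodata)
}

#' Create an environmental stack
#'
#' A named list of `raster_grid` layers sharing one geometry: the predictor
#' container for model fitting and projection.
#'
#' @param layers named list of `raster_grid` objects with identical geometry.
#' @return object of class `env_stack`.
#' @export
env_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("layers must be uniquely named")
  }
  for (l in layers) stopifnot(is_raster_grid(l))
  for (l in layers[-1L]) stop_if_geometry_mismatch(layers[[1L]], l)
  s <- list(layers = layers, names = nm)
  class(s) <- "env_stack"
  s
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers (%s), %d x %d cells\n",
              length(x$layers), paste(x$names, collapse = ", "),
              x$layers[[1L]]$n_rows, x$layers[[1L]]$n_cols))
  invisible(x)
}

# template grid of a stack (geometry carrier)
stack_template <- function(stack) stack$layers[[1L]]

#' Extract stack values as a cells-by-variables matrix
#'
#' @param stack an `env_stack`.
#' @param cells row-major cell ids; default all cells.
#' @return numeric matrix, one row per cell, one named column per layer.
#' @export
stack_values <- function(stack, cells = NULL) {
  tpl <- stack_template(stack)
  if (is.null(cells)) cells <- seq_len(tpl$n_rows * tpl$n_cols)
  out <- vapply(stack$layers, function(l) {
    as.vector(t(l$values))[cells]
  }, numeric(length(cells)))
  out <- matrix(out, nrow = length(cells),
                dimnames = list(NULL, stack$names))
  out
}

# rebuild a grid from a row-major value vector
grid_from_vector <- function(template, v) {
  raster_grid(matrix(v, nrow = template$n_rows, ncol = template$n_cols,
                     byrow = TRUE),
              origin_lon = template$origin_lon,
              origin_lat = template$origin_lat,
              cell_size = template$cell_size,
              nodata = template$nodata)
}

#' Buffer occurrence points into a region mask
#'
#' Rasterizes a fixed-radius buffer around a set of points: a cell belongs to
#' the mask iff its center lies within `radius_km` great-circle kilometers of
#' at least one point. This is how the model calibration area (the accessible
#' area M) is derived from occurrence records, e.g. with a 500-km radius.
#' Distances use the haversine formula on a sphere of radius 6371 km.
#'
#' @param points an occurrence set (see [occurrence_set()]) or a data.frame
#'   with `lon`/`lat` columns.
#' @param radius_km buffer radius in kilometers (> 0).
#' @param template `raster_grid` defining the output geometry.
#' @return a binary `raster_grid` (1 inside the buffer, 0 outside).
#' @export
buffer_mask <- function(points, radius_km, template) {
  pts <- as.data.frame(points)
  if (nrow(pts) == 0L) stop("cannot buffer an empty point set")
  stopifnot(radius_km > 0)
  cc <- cell_centers(template)
  inside <- rep(FALSE, nrow(cc))
  centers <- cbind(cc$lon, cc$lat)
  for (i in seq_len(nrow(pts))) {
    d <- geosphere::distHaversine(c(pts$lon[i], pts$lat[i]), centers,
                                  r = 6371)
    inside <- inside | (d <= radius_km)
  }
  grid_from_vector(template, as.numeric(inside))
}

#' Count cells set in a binary mask
#'
#' @param mask a binary `raster_grid` (values 0/1, `NA` allowed).
#' @return integer count of cells equal to 1.
#' @export
count_mask_cells <- function(mask) {
  v <- mask$values
  bad <- !is.na(v) & !(v %in% c(0, 1))
  if (any(bad)) stop("mask is not binary")
  sum(v == 1, na.rm = TRUE)
}

#' Row-major ids of cells set in a binary mask
#'
#' @param mask a binary `raster_grid`.
#' @return integer vector of cell ids where the mask equals 1.
#' @export
mask_cells <- function(mask) {
  which(as.vector(t(mask$values)) == 1)
}
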