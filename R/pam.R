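#' Build a presence-absence matrix on a coarse grid
#'
#' Bins multi-species occurrence records into grid cells (half-open
#' `[west, east) x [south, north)` intervals, so a point on a shared grid
#' line is counted once) and records, per cell and species, whether at
#' least one record falls there. The conventional resolution for
#' continental richness summaries is one degree.
#'
#' @param occ an `occ_set` (or data.frame) with `species`, `lon`, `lat`.
#' @param cell_size cell edge in degrees (default 1).
#' @param extent named numeric vector `c(west, east, south, north)`;
#'   records outside are dropped (count logged in the attribute
#'   `n_dropped`).
#' @return object of class `pam`: `grid` (template `raster_grid`),
#'   `species_names`, `matrix` (sites x species, binary), `site_cells`
#'   (row-major cell id per matrix row).
#' @export
build_pam <- function(occ, cell_size = 1,
                      extent = c(west = floor(min(occ$lon)),
                                 east = ceiling(max(occ$lon)),
                                 south = floor(min(occ$lat)),
                                 north = ceiling(max(occ$lat)))) {
  df <- as.data.frame(occ)
  if (nrow(df) == 0L) stop("empty occurrence set")
  w <- unname(extent["west"]); e <- unname(extent["east"])
  s <- unname(extent["south"]); n <- unname(extent["north"])
  n_cols <- ceiling(round((e - w) / cell_size, 9))
  n_rows <- ceiling(round((n - s) / cell_size, 9))
  tpl <- raster_grid(matrix(0, n_rows, n_cols),
                     origin_lon = w, origin_lat = n, cell_size = cell_size)
  south <- n - n_rows * cell_size
  inside <- !is.na(df$lon) & !is.na(df$lat) &
    df$lon >= w & df$lon < w + n_cols * cell_size &
    df$lat >= south & df$lat < n
  n_dropped <- sum(!inside)
  df <- df[inside, , drop = FALSE]
  if (nrow(df) == 0L) stop("all records fall outside the extent")
  # half-open [west, east) x [south, north) binning
  col <- floor((df$lon - w) / cell_size) + 1L
  row <- n_rows - floor((df$lat - south) / cell_size)
  cells <- as.integer((row - 1L) * n_cols + col)
  species <- sort(unique(df$species))
  site_cells <- sort(unique(cells))
  m <- matrix(0L, length(site_cells), length(species),
              dimnames = list(NULL, species))
  ri <- match(cells, site_cells)
  ci <- match(df$species, species)
  m[cbind(ri, ci)] <- 1L
  structure(list(grid = tpl, species_names = species, matrix = m,
                 site_cells = site_cells, n_dropped = n_dropped),
            class = "pam")
}

#' @export
print.pam <- function(x, ...) {
  cat(sprintf("<pam> %d occupied sites x %d species (%d records dropped)\n",
              nrow(x$matrix), ncol(x$matrix), x$n_dropped))
  invisible(x)
}

#' Species richness from a presence-absence matrix
#'
#' Per-cell richness is the row sum of the PAM; cells with no records get 0.
#'
#' @param pam a `pam` from [build_pam()].
#' @return a `raster_grid` of species counts.
#' @export
pam_richness <- function(pam) {
  v <- numeric(pam$grid$n_rows * pam$grid$n_cols)
  v[pam$site_cells] <- rowSums(pam$matrix)
  grid_from_vector(pam$grid, v)
}

#' Write a PAM as CSV
#'
#' One row per occupied site (cell id plus center coordinates), one column
#' per species.
#'
#' @param pam a `pam`.
#' @param path CSV path.
#' @export
write_pam <- function(pam, path) {
  cc <- cell_centers(pam$grid, pam$site_cells)
  out <- cbind(data.frame(cell = pam$site_cells, lon = cc$lon, lat = cc$lat),
               as.data.frame(pam$matrix))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
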