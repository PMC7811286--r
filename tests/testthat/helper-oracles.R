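# Shared fixtures and independent oracles used across test files.

# quick grid builder (geometry defaults chosen so cells are ~1 km for
# distance tests when cell_size = 0.01 at the equator)
tiny_grid <- function(values, lon = 0, lat = 10, cs = 0.01) {
  raster_grid(as.matrix(values), origin_lon = lon, origin_lat = lat,
              cell_size = cs)
}

# independent connected-component oracle for the dispersal automaton:
# steady-state occupancy = the igraph components (edges between suitable
# cells at Chebyshev distance <= d) containing the seeds
flood_fill_oracle <- function(suitable, seeds, d) {
  v <- as.vector(t(suitable$values))
  v[is.na(v)] <- 0
  cells <- which(v == 1)
  cc <- cell_centers(suitable, cells)
  idx <- seq_along(cells)
  el <- do.call(rbind, lapply(idx, function(i) {
    near <- idx[abs(cc$row - cc$row[i]) <= d &
                  abs(cc$col - cc$col[i]) <= d & idx > i]
    if (length(near)) cbind(i, near) else NULL
  }))
  g <- igraph::make_empty_graph(length(cells), directed = FALSE)
  if (!is.null(el)) g <- igraph::add_edges(g, as.vector(t(el)))
  comp <- igraph::components(g)$membership
  seed_idx <- match(seeds, cells)
  seed_idx <- seed_idx[!is.na(seed_idx)]
  sort(cells[comp %in% unique(comp[seed_idx])])
}

occupied_cells <- function(sim) {
  sort(which(as.vector(t(sim$occupied$values)) == 1))
}

# independent full-curve trapezoid AUC of sensitivity vs area fraction,
# built directly from step functions (used as the partial-AUC oracle in the
# no-restriction limit)
full_auc_oracle <- function(test_vals, land_vals) {
  ths <- sort(unique(c(land_vals, test_vals)))
  x <- vapply(ths, function(t) mean(land_vals >= t), numeric(1))
  y <- vapply(ths, function(t) mean(test_vals >= t), numeric(1))
  x <- c(1, x, 0)
  y <- c(1, y, 0)
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# pairwise haversine distance matrix in km (R = 6371 km)
pairwise_km <- function(lon, lat) {
  n <- length(lon)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(c(lon[i], lat[i]),
                                       cbind(lon, lat), r = 6371)
  }
  m
}
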