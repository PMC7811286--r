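#' One step of the cellular-automaton invasion model
#'
#' Given the currently occupied cells and a binary suitability layer, every
#' suitable cell within Chebyshev distance `d` of an occupied cell becomes
#' occupied (a generalized Moore neighborhood of radius `d` — the model's
#' single connectivity parameter). Occupation is permanent: there is no
#' extinction, carrying capacity or stochastic colonization. Nodata cells
#' are unsuitable and non-traversable.
#'
#' @param occupied binary `raster_grid` of currently occupied cells.
#' @param suitable binary `raster_grid` (a `binary_map`) of suitability.
#' @param d neighborhood Chebyshev radius in cells (integer >= 1).
#' @return binary `raster_grid` of the newly occupied set.
#' @export
ca_step <- function(occupied, suitable, d = 1L) {
  stop_if_geometry_mismatch(occupied, suitable)
  stopifnot(d >= 1L)
  occ <- occupied$values == 1
  occ[is.na(occ)] <- FALSE
  # Chebyshev dilation is separable: max-filter rows, then columns
  dil <- dilate_1d(occ, d, along = "rows")
  dil <- dilate_1d(dil, d, along = "cols")
  suit <- suitable$values == 1
  suit[is.na(suit)] <- FALSE
  new_occ <- occ | (dil & suit)
  grid_from_vector(occupied, as.numeric(t(new_occ)))
}

# binary max-filter with window radius d along one axis
dilate_1d <- function(m, d, along = c("rows", "cols")) {
  along <- match.arg(along)
  if (along == "cols") return(t(dilate_1d(t(m), d, "rows")))
  out <- m
  nr <- nrow(m)
  for (k in seq_len(d)) {
    if (k < nr) {
      out[seq_len(nr - k), ] <- out[seq_len(nr - k), ] | m[(k + 1):nr, ]
      out[(k + 1):nr, ] <- out[(k + 1):nr, ] | m[seq_len(nr - k), ]
    }
  }
  out
}

#' Run the automaton to a fixed point (or a step cap)
#'
#' Iterates [ca_step()] from a set of seed cells until no new cell is
#' colonized or `steps` iterations have run, whichever comes first. Because
#' growth is monotone and the grid finite, a fixed point always exists; at
#' the fixed point the occupied set equals the connected components (in the
#' radius-`d` Chebyshev adjacency of suitable cells) containing the seeds.
#'
#' @param suitable binary `raster_grid` of suitability.
#' @param seeds row-major cell ids of initially occupied cells; seeds on
#'   unsuitable cells are dropped with a warning.
#' @param d neighborhood radius.
#' @param steps step cap (200 is ample for any grid smaller than its
#'   diameter in `d`-cell jumps).
#' @return list: `occupied` (binary `raster_grid`), `converged` (logical),
#'   `convergence_step` (first step with no change; `NA` if the cap hit).
#' @export
ca_simulate <- function(suitable, seeds, d = 1L, steps = 200L) {
  suit_v <- as.vector(t(suitable$values))
  ok <- !is.na(suit_v[seeds]) & suit_v[seeds] == 1
  if (any(!ok)) {
    warning(sum(!ok), " seed(s) on unsuitable cells dropped")
  }
  seeds <- seeds[ok]
  if (length(seeds) == 0L) stop("no seeds on suitable cells")
  v <- numeric(length(suit_v))
  v[seeds] <- 1
  occ <- grid_from_vector(suitable, v)
  converged <- FALSE
  conv_step <- NA_integer_
  for (s in seq_len(steps)) {
    nxt <- ca_step(occ, suitable, d)
    if (identical(nxt$values, occ$values)) {
      converged <- TRUE
      conv_step <- s
      break
    }
    occ <- nxt
  }
  list(occupied = occ, converged = converged, convergence_step = conv_step)
}

#' Scenario sweep: connectivity x binarization threshold
#'
#' Runs the automaton across a grid of scenarios — every combination of
#' neighborhood radius `d` and binarization level `E` — and aggregates the
#' final occupied layers into a percent-reached map: 100 means the cell was
#' colonized in every scenario, 0 in none. The canonical sweep uses
#' `d_list = c(1, 2, 4, 8, 10, 12)` and 10 equidistant `E` levels from 0.03
#' to 0.10 (60 scenarios).
#'
#' @param continuous `raster_grid` of continuous suitability.
#' @param calib_suit calibration-occurrence suitabilities (for the
#'   `E`-threshold of [binarize()]).
#' @param seeds row-major cell ids where the invasion starts.
#' @param d_list neighborhood radii.
#' @param E_levels binarization levels.
#' @param steps per-scenario step cap.
#' @return list: `occupancy` (`raster_grid`, percent of scenarios reaching
#'   each cell), `log` (data.frame of per-scenario E, d, convergence step,
#'   cells occupied).
#' @export
ca_sweep <- function(continuous, calib_suit, seeds,
                     d_list = c(1, 2, 4, 8, 10, 12),
                     E_levels = seq(0.03, 0.10, length.out = 10L),
                     steps = 200L) {
  stopifnot(length(d_list) >= 1L, length(E_levels) >= 1L)
  n_cells <- continuous$n_rows * continuous$n_cols
  reached <- numeric(n_cells)
  logs <- list()
  n_scen <- 0L
  for (E in E_levels) {
    bin <- binarize(continuous, calib_suit, E = E)
    for (d in d_list) {
      sim <- ca_simulate(bin, seeds, d = d, steps = steps)
      occ_v <- as.vector(t(sim$occupied$values))
      occ_v[is.na(occ_v)] <- 0
      reached <- reached + occ_v
      n_scen <- n_scen + 1L
      logs[[n_scen]] <- data.frame(
        E = E, d = d, converged = sim$converged,
        convergence_step = sim$convergence_step,
        cells_occupied = sum(occ_v)
      )
    }
  }
  list(
    occupancy = grid_from_vector(continuous, 100 * reached / n_scen),
    log = do.call(rbind, logs)
  )
}
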