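#' Generate spatially autocorrelated environmental surfaces
#'
#' Seeded virtual predictor layers: each is a mixture of low-frequency
#' sinusoids plus white noise smoothed with a Gaussian kernel of standard
#' deviation `smoothness` (in cells), then standardized to zero mean and
#' unit variance. Larger `smoothness` gives stronger neighboring-cell
#' correlation, emulating the smooth spatial structure of bioclimatic
#' variables. Layers are pairwise distinct and bit-reproducible per seed.
#'
#' @param seed integer seed.
#' @param n_rows,n_cols grid dimensions (>= 8 each).
#' @param n_vars number of layers (>= 2).
#' @param smoothness Gaussian smoothing length scale in cells (0 = none).
#' @param origin_lon,origin_lat,cell_size geometry of the layers.
#' @return an `env_stack` of layers `env1..envK`.
#' @export
generate_env <- function(seed, n_rows = 60L, n_cols = 60L, n_vars = 3L,
                         smoothness = 4, origin_lon = 0, origin_lat = 50,
                         cell_size = 1 / 6) {
  if (n_rows < 8L || n_cols < 8L) stop("grid must be at least 8 x 8")
  if (n_vars < 2L) stop("need at least 2 variables")
  layers <- local_rng(seed, "generate_env", function() {
    lapply(seq_len(n_vars), function(v) {
      rr <- matrix(rep(seq_len(n_rows), n_cols), n_rows, n_cols)
      cc <- matrix(rep(seq_len(n_cols), each = n_rows), n_rows, n_cols)
      base <- matrix(0, n_rows, n_cols)
      for (k in 1:3) {
        fr <- stats::runif(1, 0.5, 2.5) / n_rows
        fc <- stats::runif(1, 0.5, 2.5) / n_cols
        ph <- stats::runif(1, 0, 2 * pi)
        amp <- stats::runif(1, 0.3, 0.6)
        base <- base + amp * sin(2 * pi * (fr * rr + fc * cc) + ph)
      }
      noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
      if (smoothness > 0) noise <- gauss_smooth(noise, smoothness)
      f <- base * 0.45 + noise * sqrt(1 - 0.45^2)
      f <- (f - mean(f)) / stats::sd(f)
      raster_grid(f, origin_lon = origin_lon, origin_lat = origin_lat,
                  cell_size = cell_size)
    })
  })
  names(layers) <- paste0("env", seq_len(n_vars))
  env_stack(layers)
}

# separable Gaussian smoothing with reflecting edges
gauss_smooth <- function(m, sd_cells) {
  half <- max(1L, ceiling(3 * sd_cells))
  k <- stats::dnorm(-half:half, sd = sd_cells)
  k <- k / sum(k)
  smooth_axis <- function(m) {
    nr <- nrow(m)
    idx <- vapply(-half:half, function(o) {
      i <- seq_len(nr) + o
      i[i < 1L] <- 1L - (i[i < 1L] - 1L)   # reflect
      i[i > nr] <- 2L * nr - i[i > nr] + 1L
      i
    }, integer(nr))
    out <- matrix(0, nr, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(smooth_axis(t(smooth_axis(m))))
}

#' True suitability of a virtual species
#'
#' The generating response: a logistic function of a quadratic in each
#' predictor, `suitability = logistic(sum_j (a_j x_j + b_j x_j^2) + c)`.
#' With negative `b_j` the niche is unimodal with optimum at
#' `x_j = -a_j / (2 b_j)`, the usual virtual-species shape that a
#' linear+quadratic model class can recover.
#'
#' @param env an `env_stack`.
#' @param params list with numeric vectors `a` and `b` (one entry per
#'   variable, in stack order) and scalar `c`.
#' @return a `raster_grid` with values in (0, 1).
#' @export
true_response <- function(env, params) {
  if (length(params$a) != length(env$names) ||
      length(params$b) != length(env$names)) {
    stop("params$a and params$b must cover every variable")
  }
  x <- stack_values(env)
  eta <- x %*% params$a + x^2 %*% params$b + params$c
  grid_from_vector(stack_template(env), stats::plogis(as.vector(eta)))
}

#' Synthetic country partition of a grid
#'
#' Seeded Voronoi partition in cell-index space: `n_countries` seed cells
#' are drawn and every land cell is assigned to its nearest seed. A
#' seeded smooth field below its `sea_fraction` quantile becomes sea
#' (`NA`), so cleaning rules (at-sea records, country mismatches) can be
#' exercised.
#'
#' @param template `raster_grid` giving the geometry.
#' @param n_countries number of countries (>= 1).
#' @param seed integer seed.
#' @param sea_fraction fraction of cells assigned to sea (default 0.1).
#' @return `raster_grid` of integer country ids 1..n_countries, `NA` = sea.
#' @export
voronoi_countries <- function(template, n_countries = 5L, seed = 1L,
                              sea_fraction = 0.1) {
  nr <- template$n_rows
  nc <- template$n_cols
  local_rng(seed, "voronoi_countries", function() {
    sr <- stats::runif(n_countries, 1, nr)
    sc <- stats::runif(n_countries, 1, nc)
    rr <- rep(seq_len(nr), each = nc)
    cc <- rep(seq_len(nc), times = nr)
    id <- vapply(seq_along(rr), function(i) {
      which.min((rr[i] - sr)^2 + (cc[i] - sc)^2)
    }, integer(1L))
    if (sea_fraction > 0) {
      field <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 3)
      fv <- as.vector(t(field))
      id[fv < stats::quantile(fv, sea_fraction)] <- NA_integer_
    }
    grid_from_vector(template, as.numeric(id))
  })
}

#' Sample biased occurrence records from a true suitability surface
#'
#' Draws occurrence cells with probability proportional to
#' `true suitability x country sampling weight`, emulating uneven survey
#' effort among countries, then jitters each point uniformly within its
#' cell (so sub-cell geometry, e.g. distance thinning, is exercised).
#' Cells at sea (no country) are never sampled.
#'
#' @param truth `raster_grid` of true suitability.
#' @param n number of records (>= 1).
#' @param countries country-id `raster_grid` (as [voronoi_countries()]).
#' @param bias named numeric vector of per-country sampling weights
#'   (country id -> weight); countries not listed get weight 1.
#' @param seed integer seed.
#' @param species species name for the records.
#' @param role record role tag.
#' @return an `occ_set`.
#' @export
sample_occurrences <- function(truth, n, countries, bias = NULL, seed = 1L,
                               species = "virtual_species",
                               role = "calibration") {
  stopifnot(n >= 1L)
  tv <- as.vector(t(truth$values))
  cid <- as.vector(t(countries$values))
  w <- ifelse(is.na(tv) | is.na(cid), 0, tv)
  if (!is.null(bias)) {
    bw <- rep(1, length(w))
    listed <- !is.na(cid) & as.character(cid) %in% names(bias)
    bw[listed] <- bias[as.character(cid[listed])]
    w <- w * bw
  }
  if (all(w <= 0)) stop("no cell has positive sampling weight")
  local_rng(seed, "sample_occurrences", function() {
    cells <- sample.int(length(w), n, replace = TRUE, prob = w)
    cc <- cell_centers(truth, cells)
    half <- truth$cell_size / 2
    occurrence_set(data.frame(
      species = species,
      lon = cc$lon + stats::runif(n, -half, half),
      lat = cc$lat + stats::runif(n, -half, half),
      country = cid[cells],
      role = role
    ), provenance = sprintf("sampled %d biased records (seed %d)", n, seed))
  })
}

#' A complete seeded virtual species
#'
#' Bundles everything the pipeline consumes: predictor stack, true
#' suitability, generating coefficients, country partition, biased
#' calibration occurrences and a handful of independent invaded-region
#' records placed in suitable cells.
#'
#' @param seed integer seed (drives every component).
#' @param n_rows,n_cols,n_vars,smoothness passed to [generate_env()].
#' @param n_occ number of calibration records.
#' @param n_invasion number of independent records.
#' @param optima,widths per-variable niche optima and widths (on the
#'   standardized predictor scale); recycled to `n_vars`. The response is
#'   `logistic(intercept - sum_j ((x_j - optimum_j) / width_j)^2)`.
#' @param intercept response intercept (controls prevalence).
#' @param bias per-country sampling weights (see [sample_occurrences()]).
#' @return object of class `virtual_species`: `env`, `truth`,
#'   `response_params`, `countries`, `occurrences`, `invasion_records`,
#'   `seed`.
#' @export
virtual_species <- function(seed, n_rows = 60L, n_cols = 60L, n_vars = 3L,
                            smoothness = 4, n_occ = 200L, n_invasion = 5L,
                            optima = c(0.5, -0.3, 0), widths = 1.2,
                            intercept = 2, bias = NULL) {
  env <- generate_env(seed, n_rows, n_cols, n_vars, smoothness)
  opt <- rep_len(optima, n_vars)
  wid <- rep_len(widths, n_vars)
  # expand logistic(int - sum ((x - o)/w)^2) into a, b, c form
  b <- -1 / wid^2
  a <- 2 * opt / wid^2
  cst <- intercept - sum(opt^2 / wid^2)
  params <- list(a = a, b = b, c = cst)
  truth <- true_response(env, params)
  countries <- voronoi_countries(stack_template(env), n_countries = 5L,
                                 seed = seed)
  occ <- sample_occurrences(truth, n_occ, countries, bias = bias,
                            seed = seed)
  inv <- sample_occurrences(truth, n_invasion, countries, seed = seed + 1L,
                            role = "independent")
  structure(list(env = env, truth = truth, response_params = params,
                 countries = countries, occurrences = occ,
                 invasion_records = inv, seed = seed),
            class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf(
    "<virtual_species> seed %d: %d x %d grid, %d predictors, %d + %d records\n",
    x$seed, x$truth$n_rows, x$truth$n_cols, length(x$env$names),
    nrow(x$occurrences), nrow(x$invasion_records)))
  invisible(x)
}

#' Invasion fixture with a known bridging radius
#'
#' A landscape whose suitable area consists of two vertical bands separated
#' by an unsuitable gap: at radius-1 connectivity the bands are two
#' components; only a neighborhood radius of at least the documented
#' `bridging_d` (the Chebyshev width of the gap plus one... precisely, the
#' distance between the bands' facing columns) lets the automaton jump the
#' gap. Independent invasion records are placed in the left band. The
#' environment is constructed so the true response is an exact quadratic
#' of the first variable, keeping the fixture consistent with the
#' virtual-species model.
#'
#' @param seed integer seed (jitter of the invasion records).
#' @param n_rows,n_cols grid size.
#' @return a `virtual_species` with extra fields `bridging_d` (minimum
#'   radius connecting the bands) and `binary_truth` (the 0.5-threshold
#'   binary map).
#' @export
make_invasion_fixture <- function(seed = 1L, n_rows = 40L, n_cols = 40L) {
  c1 <- 14; c2 <- 26
  half_width <- 2           # suitable where quadratic response >= 0.5
  cc <- matrix(rep(seq_len(n_cols), each = n_rows), n_rows, n_cols)
  dist_band <- pmin(abs(cc - c1), abs(cc - c2))
  # x = distance to nearest band center; response = logistic(k*(hw^2 - x^2))
  # crosses 0.5 exactly at x = half_width (+0.5 cell margin for jitter)
  x <- dist_band
  env1 <- raster_grid(x / 4, origin_lon = 0, origin_lat = 50,
                      cell_size = 1 / 6)
  env2 <- generate_env(seed + 7L, n_rows, n_cols, 2L,
                       smoothness = 3)$layers[[1L]]
  env <- env_stack(list(env1 = env1, env2 = env2))
  # eta = c + b1 * env1^2 = k * ((hw + 0.5)^2 - x^2) with env1 = x / 4,
  # so truth >= 0.5 exactly on the two bands |col - center| <= hw
  kk <- 2.5
  params <- list(a = c(0, 0), b = c(-kk * 16, 0),
                 c = kk * (half_width + 0.5)^2)
  truth <- true_response(env, params)
  binary_truth <- binarize(truth, calib_suit = 0.5, E = 0)
  bridging_d <- (c2 - half_width) - (c1 + half_width)
  countries <- voronoi_countries(stack_template(env), n_countries = 3L,
                                 seed = seed, sea_fraction = 0)
  cmat <- as.vector(t(cc))
  left_cells <- which(as.vector(t(binary_truth$values)) == 1 &
                        cmat <= c1 + half_width)
  inv_cells <- local_rng(seed, "invasion_records", function() {
    sample(left_cells, 4L)
  })
  ctr <- cell_centers(truth, inv_cells)
  inv <- occurrence_set(data.frame(
    species = "virtual_species", lon = ctr$lon, lat = ctr$lat,
    country = NA_character_, role = "independent"
  ), provenance = "invasion fixture records (left band)")
  occ <- sample_occurrences(truth, 60L, countries, seed = seed)
  structure(list(env = env, truth = truth, response_params = params,
                 countries = countries, occurrences = occ,
                 invasion_records = inv, seed = seed,
                 bridging_d = bridging_d, binary_truth = binary_truth),
            class = "virtual_species")
}
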