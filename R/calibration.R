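#' Enumerate the candidate-model grid
#'
#' Builds the full factorial candidate list: every subset of the predictors
#' of size >= `min_subset`, crossed with every regularization multiplier and
#' every feature-class set, in deterministic lexicographic order. With 6
#' predictors, 10 multipliers and 8 class sets this yields the canonical
#' 4,560 candidates ((2^6 - 6 - 1) = 57 subsets x 80); with 4 principal
#' components, 880.
#'
#' @param variable_names predictor names (or an integer count).
#' @param rms numeric vector of regularization multipliers; the customary
#'   grid is `c(0.10, 0.25, 0.50, 0.75, 1, 2, 3, 4, 5, 6)`.
#' @param class_sets character vector of feature-class labels; the customary
#'   eight are `c("lq","lp","lqp","qp","q","lqpt","lqpth","lqph")`.
#' @param min_subset minimum variable-subset size (default 2).
#' @return data.frame with columns `rm`, `classes`, `variables`
#'   (comma-separated subset), one row per candidate.
#' @export
enumerate_candidates <- function(variable_names,
                                 rms = default_rms(),
                                 class_sets = default_class_sets(),
                                 min_subset = 2L) {
  if (is.numeric(variable_names) && length(variable_names) == 1L) {
    variable_names <- paste0("v", seq_len(variable_names))
  }
  p <- length(variable_names)
  if (p < min_subset) stop("need at least min_subset variables")
  subsets <- unlist(lapply(seq.int(min_subset, p), function(k) {
    utils::combn(variable_names, k, paste, collapse = ",", simplify = FALSE)
  }))
  out <- expand.grid(variables = subsets, classes = class_sets, rm = rms,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$variables, subsets),
                   match(out$classes, class_sets), out$rm), ]
  rownames(out) <- NULL
  out[, c("rm", "classes", "variables")]
}

#' @rdname enumerate_candidates
#' @export
default_rms <- function() c(0.10, 0.25, 0.50, 0.75, 1, 2, 3, 4, 5, 6)

#' @rdname enumerate_candidates
#' @export
default_class_sets <- function() {
  c("lq", "lp", "lqp", "qp", "q", "lqpt", "lqpth", "lqph")
}

#' Random 50/50 evaluation splits
#'
#' Draws `k` independent random splits of the occurrence records, each using
#' half the records for calibration and the other half for testing (random
#' k-fold evaluation; the splits are independent draws, not a partition).
#'
#' @param occ an `occ_set` (or anything with rows).
#' @param k number of splits (default 5).
#' @param train_fraction fraction used for calibration (default 0.5).
#' @param seed integer seed.
#' @return list of `k` lists with integer vectors `train` and `test`.
#' @export
kfold_splits <- function(occ, k = 5L, train_fraction = 0.5, seed = 1L) {
  n <- nrow(occ)
  if (is.null(n) || n < 4L) stop("need at least 4 records to split")
  n_train <- round(train_fraction * n)
  local_rng(seed, "kfold", function() {
    lapply(seq_len(k), function(i) {
      tr <- sort(sample.int(n, n_train))
      list(train = tr, test = setdiff(seq_len(n), tr))
    })
  })
}

#' Partial ROC test for presence-only predictions
#'
#' Compares the model's partial area under the ROC-like curve of sensitivity
#' versus proportion-of-area-predicted-present, restricted to the high
#' sensitivity band `sensitivity >= 1 - E`, against the 1:1 random line over
#' the same band. Bootstrap resamples of the test occurrences give a
#' distribution of AUC ratios; the p-value is the fraction of bootstrap
#' ratios <= 1 (i.e. no better than random). Sensitivity along the curve is
#' estimated by a smoothed (interpolated) sample CDF rather than the raw
#' step ECDF, which keeps the test at its nominal size when the number of
#' test records is small relative to `1/E` (see the methods vignette).
#'
#' @param test_suit suitability values at the test occurrences (>= 5).
#' @param landscape_suit suitability values over the prediction region.
#' @param E tolerated omission (default 0.05).
#' @param n_boot bootstrap replicates (default 500).
#' @param boot_fraction fraction of test points resampled with replacement
#'   per bootstrap (default 0.5).
#' @param seed integer seed.
#' @return list: `mean_auc_ratio`, `p_value`, `auc_ratios`, `degenerate`.
#' @export
partial_roc <- function(test_suit, landscape_suit, E = 0.05,
                        n_boot = 500L, boot_fraction = 0.5, seed = 1L) {
  stopifnot(length(test_suit) >= 5L, length(landscape_suit) >= 1L)
  if (stats::sd(landscape_suit) == 0 || stats::sd(test_suit) == 0) {
    if (stats::sd(landscape_suit) == 0) {
      return(list(mean_auc_ratio = 1, p_value = 1,
                  auc_ratios = rep(1, n_boot), degenerate = TRUE))
    }
  }
  land <- sort(landscape_suit)
  N <- length(land)
  # distinct candidate thresholds and the area fraction >= each threshold
  thr <- unique(land)
  area_ge <- 1 - (findInterval(thr, land, left.open = TRUE)) / N

  m <- max(1L, round(boot_fraction * length(test_suit)))
  samples <- local_rng(seed, "partial_roc", function() {
    lapply(seq_len(n_boot), function(i) {
      sample(test_suit, m, replace = TRUE)
    })
  })
  land_range <- c(land[1L], land[N])
  ratios <- vapply(samples, function(s) {
    pauc_ratio(s, thr, area_ge, E, land_range)
  }, numeric(1L))
  ratios <- ratios[is.finite(ratios)]
  if (!length(ratios)) {
    return(list(mean_auc_ratio = 1, p_value = 1, auc_ratios = numeric(0),
                degenerate = TRUE))
  }
  list(mean_auc_ratio = mean(ratios),
       p_value = mean(ratios <= 1),
       auc_ratios = ratios,
       degenerate = FALSE)
}

# Partial AUC ratio for one set of test values over precomputed thresholds.
# Curve points: x = fraction of area with suitability >= t (1 at t = -Inf,
# decreasing), y = sensitivity at t. Sensitivity is a continuity-corrected
# estimate: 1 minus the linearly interpolated sample CDF with plotting
# positions (i + 1/2)/(m + 1), anchored at the landscape extremes. (The raw
# step-function ECDF makes the band endpoint the sample minimum, which
# systematically inflates the ratio at small samples; the smoothed estimator
# restores the test's nominal size.) The curve is restricted to
# y >= 1 - E (with linear interpolation of the band boundary); the ratio is
# the trapezoid area under the model curve over the area under the 1:1
# random line on the same x-interval.
pauc_ratio <- function(test_vals, thr, area_ge, E, land_range) {
  m <- length(test_vals)
  st <- sort(test_vals)
  kx <- c(land_range[1L] - 1e-12, st, land_range[2L] + 1e-12)
  ky <- c(0, (seq_len(m) + 0.5) / (m + 1), 1)
  fhat <- stats::approx(kx, ky, xout = thr, rule = 2, ties = "ordered")$y
  x <- c(1, area_ge)
  y <- c(1, 1 - fhat)
  keep <- y >= (1 - E)
  if (sum(keep) < 1L) return(NA_real_)
  xb <- x[keep]
  yb <- y[keep]
  # interpolate the boundary crossing (first dropped point, if any)
  first_out <- which(!keep)[1L]
  if (!is.na(first_out) && first_out > 1L) {
    x0 <- x[first_out - 1L]; y0 <- y[first_out - 1L]
    x1 <- x[first_out]; y1 <- y[first_out]
    if (y0 > y1) {
      f <- (y0 - (1 - E)) / (y0 - y1)
      xb <- c(xb, x0 + f * (x1 - x0))
      yb <- c(yb, 1 - E)
    }
  }
  ord <- order(xb)
  xb <- xb[ord]; yb <- yb[ord]
  if (length(xb) < 2L || xb[length(xb)] - xb[1L] <= 0) return(NA_real_)
  pauc <- sum(diff(xb) * (utils::head(yb, -1L) + utils::tail(yb, -1L)) / 2)
  rand <- (xb[length(xb)]^2 - xb[1L]^2) / 2
  if (rand <= 0) return(NA_real_)
  pauc / rand
}

#' @rdname partial_roc
#' @details `partial_auc()` exposes the single-curve partial AUC ratio
#'   (no bootstrap) for a given set of test values; with `E = 1` the band is
#'   the whole curve and the statistic reduces to the full trapezoid
#'   AUC divided by 1/2.
#' @export
partial_auc <- function(test_suit, landscape_suit, E = 0.05) {
  land <- sort(landscape_suit)
  N <- length(land)
  thr <- unique(land)
  area_ge <- 1 - (findInterval(thr, land, left.open = TRUE)) / N
  pauc_ratio(test_suit, thr, area_ge, E, c(land[1L], land[N]))
}

#' Omission rate at a threshold
#'
#' Fraction of evaluation suitability values strictly below the threshold
#' (consistent with [binarize()]'s `>= threshold` suitability rule).
#'
#' @param test_suit suitability values at evaluation occurrences.
#' @param threshold suitability threshold.
#' @return fraction in `[0, 1]`.
#' @export
omission_rate <- function(test_suit, threshold) {
  stopifnot(length(test_suit) >= 1L)
  mean(test_suit < threshold)
}

#' AICc of a fitted model
#'
#' Small-sample-corrected Akaike information criterion for a
#' presence-background model: the likelihood of the occurrence cells under
#' the raw output normalized to sum to one over the prediction landscape,
#' with `k` = the number of nonzero feature weights.
#' `AICc = 2k - 2lnL + 2k(k+1)/(n-k-1)`; returns `Inf` when `n - k - 1 <= 0`
#' or when any occurrence cell has zero (or nodata) raw suitability.
#'
#' @param model a `maxent_model` (used for its nonzero-weight count); or
#'   supply `k` directly.
#' @param occ_cells row-major occurrence cell ids into `landscape_raw`.
#' @param landscape_raw `raster_grid` of raw output over the landscape.
#' @param k parameter count override.
#' @return AICc value (possibly `Inf`).
#' @export
aicc <- function(model, occ_cells, landscape_raw,
                 k = sum(model$lambdas != 0)) {
  v <- as.vector(t(landscape_raw$values))
  tot <- sum(v, na.rm = TRUE)
  n <- length(occ_cells)
  if (n - k - 1 <= 0) return(Inf)
  p <- v[occ_cells] / tot
  if (anyNA(p) || any(p <= 0)) return(Inf)
  lnL <- sum(log(p))
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Select candidate models
#'
#' Applies the three-criterion selection rule: keep candidates that are
#' statistically significant (partial ROC p < `alpha`) and have omission
#' rate below `E`; then, within that filtered set, recompute delta AICc from
#' the set's minimum AICc and keep candidates with delta <= `delta_max`.
#' The result may be empty (not every calibration identifies models meeting
#' all three criteria).
#'
#' @param records data.frame with columns `proc_p`, `omission_rate`, `aicc`
#'   (one row per candidate, e.g. from [calibrate_grid()]).
#' @param alpha significance level (default 0.05).
#' @param E tolerated omission (default 0.05).
#' @param delta_max maximum delta AICc (default 2).
#' @return the selected subset of `records`, with `delta_aicc` recomputed;
#'   zero rows if nothing passes.
#' @export
select_models <- function(records, alpha = 0.05, E = 0.05, delta_max = 2.0) {
  stopifnot(nrow(records) >= 1L)
  keep <- !is.na(records$proc_p) & records$proc_p < alpha &
    !is.na(records$omission_rate) & records$omission_rate < E
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    out$delta_aicc <- numeric(0)
    return(out)
  }
  out$delta_aicc <- out$aicc - min(out$aicc)
  out <- out[is.finite(out$delta_aicc) & out$delta_aicc <= delta_max, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binarize a continuous suitability layer
#'
#' Modified least-presence threshold: the suitability value at 0-based index
#' `floor(E * n)` of the ascending-sorted calibration suitabilities becomes
#' the threshold; a cell is suitable iff its value >= threshold. With
#' `E = 0` this is the classic least (minimum) training presence threshold;
#' `E = 0.05` tolerates 5% omission of calibration records.
#'
#' @param layer continuous `raster_grid`.
#' @param calib_suit suitability values at the calibration occurrences.
#' @param E tolerated omission fraction.
#' @return a `binary_map`: `raster_grid` (values 0/1, NA preserved) with
#'   attributes `threshold` and `E`.
#' @export
binarize <- function(layer, calib_suit, E = 0.05) {
  stopifnot(length(calib_suit) >= 1L)
  s <- sort(calib_suit)
  thr <- s[floor(E * length(s)) + 1L]
  v <- as.vector(t(layer$values))
  b <- ifelse(is.na(v), NA_real_, as.numeric(v >= thr))
  out <- grid_from_vector(layer, b)
  attr(out, "threshold") <- thr
  attr(out, "E") <- E
  class(out) <- c("binary_map", class(out))
  out
}

#' Consensus layers
#'
#' `consensus_median()` takes the cellwise median of continuous layers (the
#' "median of medians" final continuous consensus); `consensus_sum()` adds
#' binary maps cellwise, giving a per-cell agreement count in
#' `[0, n_maps]`. Cells that are nodata in every input stay nodata.
#'
#' @param layers list of `raster_grid` with identical geometry.
#' @return a `raster_grid`.
#' @export
consensus_median <- function(layers) {
  stopifnot(length(layers) >= 1L)
  for (l in layers[-1L]) stop_if_geometry_mismatch(layers[[1L]], l)
  vs <- vapply(layers, function(l) as.vector(t(l$values)),
               numeric(layers[[1L]]$n_rows * layers[[1L]]$n_cols))
  vs <- matrix(vs, ncol = length(layers))
  med <- apply(vs, 1L, function(r) {
    if (all(is.na(r))) NA_real_ else stats::median(r, na.rm = TRUE)
  })
  grid_from_vector(layers[[1L]], med)
}

#' @rdname consensus_median
#' @param maps list of `binary_map` with identical geometry.
#' @export
consensus_sum <- function(maps) {
  stopifnot(length(maps) >= 1L)
  for (l in maps[-1L]) stop_if_geometry_mismatch(maps[[1L]], l)
  vs <- vapply(maps, function(l) as.vector(t(l$values)),
               numeric(maps[[1L]]$n_rows * maps[[1L]]$n_cols))
  vs <- matrix(vs, ncol = length(maps))
  s <- apply(vs, 1L, function(r) {
    if (all(is.na(r))) NA_real_ else sum(r, na.rm = TRUE)
  })
  grid_from_vector(maps[[1L]], s)
}

#' Test a binary prediction against independent records
#'
#' Checks whether every independent (invaded-region) record falls in a
#' suitable cell of the binary map — the final evaluation step before a
#' replicate enters the consensus.
#'
#' @param map a `binary_map`.
#' @param records an `occ_set` (typically `role == "independent"`).
#' @return list: `pass` (logical), `flags` data.frame with one row per
#'   record and its `suitable` status.
#' @export
independent_test <- function(map, records) {
  stopifnot(nrow(records) >= 1L)
  cells <- cell_from_lonlat(map, records$lon, records$lat)
  if (anyNA(cells)) stop("independent record(s) outside the raster extent")
  v <- as.vector(t(map$values))[cells]
  if (anyNA(v)) stop("independent record(s) fall on nodata cells")
  flags <- data.frame(lon = records$lon, lat = records$lat, cell = cells,
                      suitable = v == 1)
  list(pass = all(flags$suitable), flags = flags)
}

#' Evaluate the candidate grid over k calibration processes
#'
#' The calibration engine: the occurrence records are split `k` times into
#' random calibration/testing halves, and each split is a separate
#' calibration process. For every candidate configuration and every process,
#' the model is fitted on the calibration half and evaluated on the testing
#' half (partial ROC significance; omission at the `E`-threshold derived
#' from the calibration half); AICc comes from the single refit on all
#' records (shared across processes). Selection ([select_models()]) is then
#' applied per process — some processes may select models while others
#' select none.
#'
#' @param occ_cells row-major cell ids of the occurrence records.
#' @param background_cells background (accessible-area) cell ids.
#' @param stack `env_stack` of predictors.
#' @param candidates data.frame from [enumerate_candidates()].
#' @param k number of random 50/50 splits.
#' @param E tolerated omission.
#' @param n_boot,boot_fraction partial ROC bootstrap settings.
#' @param seed integer seed.
#' @param hinge_knots,threshold_knots knot counts for `h`/`t` features.
#' @param verbose print progress?
#' @return data.frame: one row per candidate x process with `process`,
#'   `proc_p`, `mean_auc_ratio`, `omission_rate`, `aicc`, `n_params`, plus
#'   the candidate columns.
#' @export
calibrate_grid <- function(occ_cells, background_cells, stack, candidates,
                           k = 5L, E = 0.05, n_boot = 500L,
                           boot_fraction = 0.5, seed = 1L,
                           hinge_knots = 20L, threshold_knots = 10L,
                           verbose = FALSE) {
  n <- length(occ_cells)
  splits <- kfold_splits(data.frame(i = seq_len(n)), k = k, seed = seed)
  res <- vector("list", nrow(candidates))
  for (ci in seq_len(nrow(candidates))) {
    cand <- candidates[ci, ]
    vars <- strsplit(cand$variables, ",")[[1L]]
    sub <- env_stack(stack$layers[vars])
    spec <- feature_spec_for(sub, background_cells, cand$classes,
                             hinge_knots = hinge_knots,
                             threshold_knots = threshold_knots)
    ps <- oms <- ratios <- rep(NA_real_, k)
    for (si in seq_len(k)) {
      tr <- occ_cells[splits[[si]]$train]
      te <- occ_cells[splits[[si]]$test]
      fit <- tryCatch(
        maxent_fit(tr, background_cells, sub, spec, cand$rm),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      land_raw <- predict_values(fit, stack_values(sub, background_cells),
                                 output = "raw")
      test_raw <- predict_values(fit, stack_values(sub, te), output = "raw")
      train_raw <- predict_values(fit, stack_values(sub, tr), output = "raw")
      pr <- partial_roc(test_raw, land_raw, E = E, n_boot = n_boot,
                        boot_fraction = boot_fraction,
                        seed = seed + 1000L * si + ci)
      ps[si] <- pr$p_value
      ratios[si] <- pr$mean_auc_ratio
      strain <- sort(train_raw)
      thr <- strain[floor(E * length(strain)) + 1L]
      oms[si] <- omission_rate(test_raw, thr)
    }
    full <- tryCatch(
      maxent_fit(occ_cells, background_cells, sub, spec, cand$rm),
      error = function(e) NULL
    )
    if (is.null(full)) {
      aic <- NA_real_
      npar <- NA_integer_
    } else {
      land_raw_full <- predict_values(full,
                                      stack_values(sub, background_cells),
                                      output = "raw")
      occ_raw <- predict_values(full, stack_values(sub, occ_cells),
                                output = "raw")
      tot <- sum(land_raw_full)
      kk <- sum(full$lambdas != 0)
      aic <- if (n - kk - 1 <= 0 || any(occ_raw <= 0)) Inf else {
        2 * kk - 2 * sum(log(occ_raw / tot)) + 2 * kk * (kk + 1) / (n - kk - 1)
      }
      npar <- kk
    }
    res[[ci]] <- data.frame(cand[rep(1L, k), ], process = seq_len(k),
                            proc_p = ps, mean_auc_ratio = ratios,
                            omission_rate = oms, aicc = aic,
                            n_params = npar)
    if (verbose) {
      message(sprintf(
        "[%d/%d] rm=%.2g %s {%s}: p=%s om=%s AICc=%.1f",
        ci, nrow(candidates), cand$rm, cand$classes, cand$variables,
        paste(formatC(ps, digits = 2, format = "f"), collapse = "/"),
        paste(formatC(oms, digits = 2, format = "f"), collapse = "/"), aic
      ))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-process model selection
#'
#' Applies [select_models()] separately within each calibration process of a
#' [calibrate_grid()] table, mirroring how each of the five calibration
#' exercises may or may not identify models meeting all three criteria.
#'
#' @param records output of [calibrate_grid()] (must have a `process`
#'   column).
#' @inheritParams select_models
#' @return the selected rows across processes (possibly zero rows), with
#'   `delta_aicc` recomputed within each process.
#' @export
select_models_by_process <- function(records, alpha = 0.05, E = 0.05,
                                     delta_max = 2.0) {
  stopifnot("process" %in% names(records))
  parts <- lapply(split(records, records$process), select_models,
                  alpha = alpha, E = E, delta_max = delta_max)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
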