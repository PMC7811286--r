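#' Feature specification for the suitability model
#'
#' Defines how raw predictor values are expanded into model features. The
#' supported classes follow the Maxent convention: `l` linear, `q` quadratic,
#' `p` pairwise product, `t` threshold (step), `h` hinge (forward ramp).
#' Variables are first rescaled to `[0, 1]` by their calibration range (the
#' min/max observed over the background), so feature magnitudes are
#' commensurate.
#'
#' @param classes feature classes as a compact string (e.g. `"lqp"`) or a
#'   character vector of single letters; non-empty subset of `l,q,p,t,h`.
#' @param variable_names predictor names, in order.
#' @param ranges 2-row matrix (`min`, `max`) with one named column per
#'   variable: the calibration ranges.
#' @param hinge_knots,threshold_knots number of equally spaced knots per
#'   variable for the `h` and `t` classes.
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(classes, variable_names, ranges,
                         hinge_knots = 20L, threshold_knots = 10L) {
  cls <- unique(strsplit(paste(classes, collapse = ""), "")[[1L]])
  if (length(cls) == 0L || !all(cls %in% c("l", "q", "p", "t", "h"))) {
    stop("classes must be a non-empty subset of l, q, p, t, h")
  }
  ranges <- as.matrix(ranges)
  if (nrow(ranges) != 2L) stop("ranges must have rows min, max")
  colnames(ranges) <- variable_names
  if (any(!is.finite(ranges)) || any(ranges[1L, ] >= ranges[2L, ])) {
    stop("calibration ranges must be finite with min < max")
  }
  structure(list(classes = cls, variable_names = variable_names,
                 ranges = ranges, hinge_knots = as.integer(hinge_knots),
                 threshold_knots = as.integer(threshold_knots)),
            class = "feature_spec")
}

#' Derive a feature spec from background cells
#'
#' @param stack an `env_stack`.
#' @param background_cells row-major cell ids of the background.
#' @inheritParams feature_spec
#' @return a `feature_spec` with ranges taken from the background values.
#' @export
feature_spec_for <- function(stack, background_cells, classes,
                             hinge_knots = 20L, threshold_knots = 10L) {
  vals <- stack_values(stack, background_cells)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  rng <- apply(vals, 2L, range)
  feature_spec(classes, colnames(vals), rng,
               hinge_knots = hinge_knots, threshold_knots = threshold_knots)
}

#' Build the feature matrix for a set of cells
#'
#' Expands raw predictor values into the model's basis functions. With
#' `clamp = TRUE` each variable is first clipped to its calibration range
#' (the "extrapolation with clamping" transfer mode); otherwise scaled
#' values may fall outside `[0, 1]` beyond the calibration range and
#' features extrapolate freely.
#'
#' @param values numeric matrix, one row per cell, named columns matching
#'   `spec$variable_names`.
#' @param spec a `feature_spec`.
#' @param clamp clip variables to their calibration ranges first?
#' @return numeric feature matrix with named columns; attribute
#'   `feature_class` gives each column's class letter.
#' @export
build_features <- function(values, spec, clamp = FALSE) {
  stopifnot(inherits(spec, "feature_spec"))
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- spec$variable_names
  if (!all(spec$variable_names %in% colnames(values))) {
    stop("values are missing variables: ",
         paste(setdiff(spec$variable_names, colnames(values)), collapse = ", "))
  }
  values <- values[, spec$variable_names, drop = FALSE]
  lo <- spec$ranges[1L, ]
  hi <- spec$ranges[2L, ]
  z <- sweep(sweep(values, 2L, lo), 2L, hi - lo, "/")
  if (clamp) z <- pmin(pmax(z, 0), 1)

  p <- ncol(z)
  vn <- spec$variable_names
  cols <- list()
  klass <- character(0)
  push <- function(m, letter) {
    cols[[length(cols) + 1L]] <<- m
    klass <<- c(klass, rep(letter, ncol(m)))
  }
  if ("l" %in% spec$classes) {
    m <- z; colnames(m) <- paste0("l_", vn); push(m, "l")
  }
  if ("q" %in% spec$classes) {
    m <- z^2; colnames(m) <- paste0("q_", vn); push(m, "q")
  }
  if ("p" %in% spec$classes && p >= 2L) {
    pairs <- utils::combn(p, 2L)
    m <- matrix(0, nrow(z), ncol(pairs))
    nm <- character(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      m[, j] <- z[, a] * z[, b]
      nm[j] <- paste0("p_", vn[a], "_x_", vn[b])
    }
    colnames(m) <- nm
    push(m, "p")
  }
  if ("t" %in% spec$classes) {
    K <- spec$threshold_knots
    knots <- seq_len(K) / (K + 1)
    for (v in seq_len(p)) {
      m <- outer(z[, v], knots, ">=") * 1
      colnames(m) <- paste0("t_", vn[v], "_", seq_len(K))
      push(m, "t")
    }
  }
  if ("h" %in% spec$classes) {
    K <- spec$hinge_knots
    knots <- (seq_len(K) - 1) / K
    for (v in seq_len(p)) {
      m <- vapply(knots, function(k) pmax(0, (z[, v] - k) / (1 - k)),
                  numeric(nrow(z)))
      m <- matrix(m, nrow = nrow(z))
      colnames(m) <- paste0("h_", vn[v], "_", seq_len(K))
      push(m, "h")
    }
  }
  out <- do.call(cbind, cols)
  attr(out, "feature_class") <- klass
  out
}
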