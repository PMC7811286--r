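#' Mobility-oriented parity (MOP) analysis
#'
#' Measures the environmental similarity of every projection cell to the
#' calibration-area environmental cloud, and flags strict extrapolation.
#' Variables are standardized by the reference range
#' (`(x - min) / (max - min)`) so axes are commensurate; each projection
#' cell's statistic is the mean Euclidean distance to its nearest
#' `ceiling(p_nearest * N_ref)` reference cells, rescaled to a similarity
#' `1 - d / max(d)` in `[0, 1]` (1 = indistinguishable from the reference
#' cloud). The strict mask marks cells where at least one variable falls
#' outside the reference range — the non-analogous conditions deleted from
#' binary predictions before interpretation.
#'
#' @param reference `env_stack` of the calibration region.
#' @param reference_mask binary `raster_grid` selecting calibration cells.
#' @param projection `env_stack` with the same variables (any geometry).
#' @param p_nearest fraction of reference cells averaged over (in `(0, 1]`).
#' @param subsample_cap maximum number of reference cells used in the
#'   distance computation (seeded subsample beyond that).
#' @param seed integer seed (only used if the cap binds).
#' @return object of class `mop_result`: `similarity` (`raster_grid`),
#'   `strict_mask` (binary `raster_grid`), `mean_distance` (`raster_grid`).
#' @export
mop <- function(reference, reference_mask, projection, p_nearest = 0.05,
                subsample_cap = 10000L, seed = 1L) {
  if (!setequal(reference$names, projection$names)) {
    stop("reference and projection stacks have different variables")
  }
  if (p_nearest <= 0 || p_nearest > 1) stop("p_nearest must be in (0, 1]")
  ref_cells <- mask_cells(reference_mask)
  if (length(ref_cells) == 0L) stop("reference mask is empty")
  R <- stack_values(reference, ref_cells)[, reference$names, drop = FALSE]
  R <- R[stats::complete.cases(R), , drop = FALSE]
  if (nrow(R) > subsample_cap) {
    keep <- local_rng(seed, "mop_subsample", function() {
      sort(sample.int(nrow(R), subsample_cap))
    })
    R <- R[keep, , drop = FALSE]
  }
  lo <- apply(R, 2L, min)
  hi <- apply(R, 2L, max)
  span <- pmax(hi - lo, .Machine$double.eps)

  tpl <- stack_template(projection)
  P <- stack_values(projection)[, reference$names, drop = FALSE]
  ok <- stats::complete.cases(P)

  out_of <- rep(NA_real_, nrow(P))
  out_of[ok] <- as.numeric(rowSums(
    sweep(P[ok, , drop = FALSE], 2L, lo, "<") |
      sweep(P[ok, , drop = FALSE], 2L, hi, ">")
  ) > 0)

  Rz <- sweep(sweep(R, 2L, lo), 2L, span, "/")
  Pz <- sweep(sweep(P, 2L, lo), 2L, span, "/")
  n_near <- ceiling(p_nearest * nrow(Rz))

  md <- rep(NA_real_, nrow(P))
  idx <- which(ok)
  p_vars <- ncol(Rz)
  for (i in idx) {
    d2 <- (Rz[, 1L] - Pz[i, 1L])^2
    for (j in seq_len(p_vars)[-1L]) d2 <- d2 + (Rz[, j] - Pz[i, j])^2
    md[i] <- mean(sqrt(sort(d2, partial = n_near)[seq_len(n_near)]))
  }
  dmax <- max(md, na.rm = TRUE)
  sim <- if (dmax > 0) 1 - md / dmax else ifelse(is.na(md), NA_real_, 1)

  structure(list(
    similarity = grid_from_vector(tpl, sim),
    mean_distance = grid_from_vector(tpl, md),
    strict_mask = grid_from_vector(tpl, out_of),
    p_nearest = p_nearest
  ), class = "mop_result")
}

#' @export
print.mop_result <- function(x, ...) {
  cat(sprintf("<mop_result> p_nearest = %.3g; %d strict-extrapolation cells\n",
              x$p_nearest, sum(x$strict_mask$values == 1, na.rm = TRUE)))
  invisible(x)
}

#' Trim extrapolation-risk areas from a binary prediction
#'
#' Sets suitable cells flagged by the MOP strict-extrapolation mask to
#' unsuitable, so downstream interpretation (and dispersal simulation) never
#' relies on non-analogous environments. With `similarity_floor` set, cells
#' whose MOP similarity falls below the floor are removed as well.
#'
#' @param map a `binary_map`.
#' @param mop_result a `mop_result` with matching geometry.
#' @param similarity_floor optional minimum similarity in `[0, 1]`.
#' @return trimmed `binary_map`.
#' @export
mop_trim <- function(map, mop_result, similarity_floor = NULL) {
  stop_if_geometry_mismatch(map, mop_result$strict_mask)
  v <- as.vector(t(map$values))
  flag <- as.vector(t(mop_result$strict_mask$values)) == 1
  v[!is.na(v) & !is.na(flag) & flag] <- 0
  if (!is.null(similarity_floor)) {
    s <- as.vector(t(mop_result$similarity$values))
    low <- !is.na(s) & s < similarity_floor
    v[!is.na(v) & low] <- 0
  }
  out <- grid_from_vector(map, v)
  attr(out, "threshold") <- attr(map, "threshold")
  attr(out, "E") <- attr(map, "E")
  class(out) <- c("binary_map", class(out))
  out
}
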