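#' Greedy correlation-based variable selection
#'
#' Screens predictors so that all retained pairs have |Pearson r| below a
#' threshold over the calibration area. Variables are examined in a
#' user-supplied priority order (the mechanism for encoding which variables
#' are considered most biologically interpretable): each variable is kept iff
#' its absolute correlation with every previously kept variable is <= `r_max`
#' over the masked cells. The conventional threshold is `r_max = 0.85`.
#'
#' @param stack an `env_stack`.
#' @param mask binary `raster_grid`; correlations are computed over cells
#'   where the mask is 1 (and all layers are non-`NA`).
#' @param r_max maximum allowed absolute pairwise Pearson correlation.
#' @param priority character vector listing every stack variable exactly
#'   once, most-preferred first; defaults to stack order.
#' @return `env_stack` restricted to the retained variables.
#' @export
select_uncorrelated <- function(stack, mask, r_max = 0.85,
                                priority = stack$names) {
  stopifnot(inherits(stack, "env_stack"))
  if (!setequal(priority, stack$names) || anyDuplicated(priority)) {
    stop("priority must list every stack variable exactly once")
  }
  cells <- mask_cells(mask)
  if (length(cells) == 0L) stop("mask selects no cells")
  vals <- stack_values(stack, cells)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  sds <- apply(vals, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s) over mask: ",
         paste(colnames(vals)[sds == 0], collapse = ", "))
  }
  cm <- abs(stats::cor(vals))
  kept <- character(0)
  for (v in priority) {
    if (all(cm[v, kept] <= r_max)) kept <- c(kept, v)
  }
  env_stack(stack$layers[kept])
}

#' Fit a standardized PCA on the calibration area
#'
#' Principal components analysis of the stack over masked cells, on the
#' correlation matrix (each variable centered and scaled to unit variance —
#' the defensible choice when predictors mix units such as temperature and
#' humidity). Component signs are fixed so each loading vector's
#' largest-magnitude entry is positive, making results deterministic.
#'
#' @param stack an `env_stack`.
#' @param mask binary `raster_grid` defining the fitting cells.
#' @return object of class `pca_transform`: `variable_names`, `means`,
#'   `scales`, `rotation` (columns = components), `variance_explained`
#'   (percent, non-increasing), `sdev`.
#' @export
pca_fit <- function(stack, mask) {
  cells <- mask_cells(mask)
  vals <- stack_values(stack, cells)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  p <- ncol(vals)
  if (nrow(vals) < p + 1L) stop("fewer masked cells than variables + 1")
  sds <- apply(vals, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s) over mask: ",
         paste(colnames(vals)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(vals, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) rot[, j] <- -rot[, j]
  }
  out <- list(
    variable_names = colnames(vals),
    means = pc$center,
    scales = pc$scale,
    rotation = rot,
    sdev = pc$sdev,
    variance_explained = 100 * pc$sdev^2 / sum(pc$sdev^2)
  )
  class(out) <- "pca_transform"
  out
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf("<pca_transform> %d variables; variance explained: %s\n",
              length(x$variable_names),
              paste(sprintf("%.1f%%", x$variance_explained), collapse = " ")))
  invisible(x)
}

#' Project a fitted PCA onto a (possibly larger) stack
#'
#' Applies the centering, scaling and rotation learned on the calibration
#' area to every cell of `stack` — this is how component layers fitted on the
#' accessible area are transferred to the whole world so that values remain
#' comparable between regions.
#'
#' @param stack `env_stack` whose variable names match the transform.
#' @param transform a `pca_transform` from [pca_fit()].
#' @param n_components how many leading score layers to return.
#' @return `env_stack` of layers `PC1..PCk`.
#' @export
pca_project <- function(stack, transform, n_components = 2L) {
  stopifnot(inherits(transform, "pca_transform"))
  if (!identical(sort(stack$names), sort(transform$variable_names))) {
    stop("stack variables do not match the PCA transform")
  }
  p <- length(transform$variable_names)
  if (n_components > p) stop("n_components exceeds number of variables")
  tpl <- stack_template(stack)
  vals <- stack_values(stack)[, transform$variable_names, drop = FALSE]
  z <- sweep(sweep(vals, 2L, transform$means), 2L, transform$scales, "/")
  scores <- z %*% transform$rotation[, seq_len(n_components), drop = FALSE]
  layers <- lapply(seq_len(n_components), function(j) {
    grid_from_vector(tpl, scores[, j])
  })
  names(layers) <- paste0("PC", seq_len(n_components))
  env_stack(layers)
}

#' Serialize / restore a PCA transform as JSON
#'
#' @param transform a `pca_transform`.
#' @param path JSON file path.
#' @export
write_pca <- function(transform, path) {
  jsonlite::write_json(list(
    variable_names = transform$variable_names,
    means = unname(transform$means),
    scales = unname(transform$scales),
    rotation = transform$rotation,
    sdev = transform$sdev,
    variance_explained = transform$variance_explained
  ), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_pca
#' @export
read_pca <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(
    variable_names = j$variable_names,
    means = stats::setNames(j$means, j$variable_names),
    scales = stats::setNames(j$scales, j$variable_names),
    rotation = matrix(unlist(j$rotation), ncol = length(j$variable_names),
                      dimnames = list(j$variable_names, NULL)),
    sdev = j$sdev,
    variance_explained = j$variance_explained
  )
  if (is.matrix(j$rotation)) {
    out$rotation <- j$rotation
    rownames(out$rotation) <- j$variable_names
  }
  colnames(out$rotation) <- paste0("PC", seq_len(ncol(out$rotation)))
  class(out) <- "pca_transform"
  out
}
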