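#' Fit a Maxent-style presence-background model
#'
#' Estimates a Gibbs density over the background cells by minimizing the
#' convex L1-penalized objective
#' \deqn{-\frac{1}{n}\sum_{i \in pres} \lambda^\top f_i +
#'       \log \sum_{b \in bg} e^{\lambda^\top f_b} +
#'       \sum_j \beta_j |\lambda_j|}
#' where the per-feature penalty is
#' `beta_j = rm * c_class * sd_j(background) / sqrt(n_presences)` with class
#' coefficients `c_l = c_q = 0.05`, `c_p = 0.1`, `c_t = 1.0`, `c_h = 0.5`.
#' The regularization multiplier `rm` is the single knob scaling overall
#' model complexity, as in the usual Maxent parameterization. (The class
#' coefficients are this package's own fixed, transparent rule; no attempt
#' is made to reproduce any particular Maxent release's versioned
#' regularization tables.)
#'
#' Optimization is deterministic accelerated proximal gradient descent
#' (FISTA with restart and backtracking line search) started from zero
#' weights; soft-thresholding yields exact zeros, so the count of nonzero
#' weights is the model's parameter count for AICc.
#'
#' @param presence_cells,background_cells row-major cell ids into `stack`.
#' @param stack an `env_stack` with the model's predictors.
#' @param spec a `feature_spec` (see [feature_spec_for()]).
#' @param rm regularization multiplier (> 0).
#' @param tol convergence tolerance on the objective decrease.
#' @param max_iter iteration cap; exceeding it is an error (with the tail of
#'   the objective trace in the message).
#' @param init optional starting weights (default all zero; any start
#'   converges to the same objective value, the objective being convex).
#' @return object of class `maxent_model`: `spec`, `rm`, `lambdas` (named),
#'   `log_partition`, `entropy_H`, `n_presences`, `objective`, `iterations`.
#' @export
maxent_fit <- function(presence_cells, background_cells, stack, spec, rm,
                       tol = 1e-6, max_iter = 10000L, init = NULL) {
  stopifnot(length(presence_cells) >= 2L, length(background_cells) >= 2L,
            rm > 0)
  xp <- stack_values(stack, presence_cells)
  xb <- stack_values(stack, background_cells)
  if (anyNA(xp) || anyNA(xb)) {
    stop("presence or background cells fall on nodata cells")
  }
  Fp <- build_features(xp, spec)
  Fb <- build_features(xb, spec)
  n <- nrow(Fp)
  m <- ncol(Fb)

  cclass <- c(l = 0.05, q = 0.05, p = 0.1, t = 1.0, h = 0.5)
  sdb <- apply(Fb, 2L, stats::sd)
  beta <- rm * cclass[attr(Fb, "feature_class")] * sdb / sqrt(n)
  beta <- unname(beta)

  mp <- colMeans(Fp)

  logsumexp <- function(x) {
    mx <- max(x)
    mx + log(sum(exp(x - mx)))
  }
  smooth_obj <- function(lam) {
    eta <- as.vector(Fb %*% lam)
    -sum(mp * lam) + logsumexp(eta)
  }
  smooth_grad <- function(lam) {
    eta <- as.vector(Fb %*% lam)
    w <- exp(eta - logsumexp(eta))
    -mp + as.vector(crossprod(Fb, w))
  }
  pen <- function(lam) sum(beta * abs(lam))
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

  lam <- if (is.null(init)) numeric(m) else {
    stopifnot(length(init) == m)
    as.numeric(init)
  }
  y <- lam
  t_mom <- 1
  step <- 1
  obj <- smooth_obj(lam) + pen(lam)
  trace <- obj
  it <- 0L
  repeat {
    it <- it + 1L
    g <- smooth_grad(y)
    gy <- smooth_obj(y)
    repeat {
      cand <- soft(y - step * g, step * beta)
      d <- cand - y
      if (smooth_obj(cand) <= gy + sum(g * d) + sum(d * d) / (2 * step) ||
          step < 1e-12) break
      step <- step / 2
    }
    lam_new <- cand
    obj_new <- smooth_obj(lam_new) + pen(lam_new)
    if (obj_new > obj) {           # restart momentum on any increase
      y <- lam
      t_mom <- 1
      g <- smooth_grad(y)
      gy <- smooth_obj(y)
      repeat {
        cand <- soft(y - step * g, step * beta)
        d <- cand - y
        if (smooth_obj(cand) <= gy + sum(g * d) + sum(d * d) / (2 * step) ||
            step < 1e-12) break
        step <- step / 2
      }
      lam_new <- cand
      obj_new <- smooth_obj(lam_new) + pen(lam_new)
    }
    t_new <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    y <- lam_new + ((t_mom - 1) / t_new) * (lam_new - lam)
    converged <- abs(obj - obj_new) < tol && it > 1L
    lam <- lam_new
    t_mom <- t_new
    obj <- obj_new
    trace <- c(trace, obj)
    if (converged) break
    if (it >= max_iter) {
      stop(sprintf(
        "maxent_fit did not converge in %d iterations; objective tail: %s",
        max_iter,
        paste(formatC(utils::tail(trace, 5L), digits = 10, format = "g"),
              collapse = " ")
      ))
    }
  }

  eta <- as.vector(Fb %*% lam)
  logZ <- logsumexp(eta)
  praw <- exp(eta - logZ)
  H <- -sum(praw * log(pmax(praw, 1e-300)))

  structure(list(
    spec = spec, rm = rm,
    lambdas = stats::setNames(lam, colnames(Fb)),
    log_partition = logZ, entropy_H = H,
    n_presences = n, n_background = nrow(Fb),
    objective = obj, iterations = it
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> classes %s, rm %.3g, %d/%d nonzero weights, H = %.3f\n",
    paste(x$spec$classes, collapse = ""), x$rm,
    sum(x$lambdas != 0), length(x$lambdas), x$entropy_H
  ))
  invisible(x)
}

# raw (relative to the calibration background) and cloglog for a value matrix
predict_values <- function(model, values, output = "cloglog",
                           clamp = FALSE) {
  f <- build_features(values, model$spec, clamp = clamp)
  raw <- exp(as.vector(f %*% model$lambdas) - model$log_partition)
  if (output == "raw") raw else 1 - exp(-exp(model$entropy_H) * raw)
}

#' Predict suitability at specific cells
#'
#' Vector variant of [maxent_predict()] for a set of row-major cell ids —
#' convenient for occurrence suitabilities and background summaries.
#'
#' @inheritParams maxent_predict
#' @param cells row-major cell ids into `stack`.
#' @return numeric vector of predictions at `cells`.
#' @export
predict_cell_values <- function(model, stack, cells,
                                output = c("cloglog", "raw"),
                                clamp = FALSE) {
  output <- match.arg(output)
  vals <- stack_values(stack, cells)[, model$spec$variable_names,
                                     drop = FALSE]
  predict_values(model, vals, output = output, clamp = clamp)
}

#' Predict suitability over a stack
#'
#' Evaluates the fitted density at every cell. `raw` output is the Gibbs
#' density normalized over the calibration background (it sums to 1 there);
#' `cloglog` output is the bounded suitability index
#' `1 - exp(-exp(H) * raw)` with `H` the entropy of the fitted background
#' distribution.
#'
#' @param model a `maxent_model`.
#' @param stack `env_stack` containing the model's variables.
#' @param output `"cloglog"` (default) or `"raw"`.
#' @param clamp clamp variables to calibration ranges before evaluating?
#' @return a `raster_grid` (NA where any predictor is NA).
#' @export
maxent_predict <- function(model, stack, output = c("cloglog", "raw"),
                           clamp = FALSE) {
  output <- match.arg(output)
  missing_vars <- setdiff(model$spec$variable_names, stack$names)
  if (length(missing_vars)) {
    stop("stack lacks model variables: ", paste(missing_vars, collapse = ", "))
  }
  tpl <- stack_template(stack)
  vals <- stack_values(stack)[, model$spec$variable_names, drop = FALSE]
  ok <- stats::complete.cases(vals)
  out <- rep(NA_real_, nrow(vals))
  if (any(ok)) {
    out[ok] <- predict_values(model, vals[ok, , drop = FALSE],
                              output = output, clamp = clamp)
  }
  grid_from_vector(tpl, out)
}

#' Transfer a model to a new region under an extrapolation mode
#'
#' The three conventional transfer behaviours outside the calibration
#' ranges: `E` (free extrapolation — features evaluated as-is), `EC`
#' (extrapolation with clamping — each variable clipped to its calibration
#' range first), and `NE` (no extrapolation — cells where any variable is
#' out of range become nodata and are excluded from suitability).
#'
#' @param model a `maxent_model`.
#' @param new_stack `env_stack` for the transfer region.
#' @param mode one of `"E"`, `"EC"`, `"NE"`.
#' @inheritParams maxent_predict
#' @return a `raster_grid`.
#' @export
maxent_transfer <- function(model, new_stack, mode = c("E", "EC", "NE"),
                            output = c("cloglog", "raw")) {
  mode <- match.arg(mode)
  output <- match.arg(output)
  pred <- maxent_predict(model, new_stack, output = output,
                         clamp = (mode == "EC"))
  if (mode == "NE") {
    vals <- stack_values(new_stack)[, model$spec$variable_names,
                                    drop = FALSE]
    lo <- model$spec$ranges[1L, ]
    hi <- model$spec$ranges[2L, ]
    out_of <- rowSums(
      sweep(vals, 2L, lo, "<") | sweep(vals, 2L, hi, ">")
    ) > 0
    v <- as.vector(t(pred$values))
    v[which(out_of)] <- NA_real_
    pred <- grid_from_vector(stack_template(new_stack), v)
  }
  pred
}

#' Bootstrap replicates of a fitted configuration
#'
#' Refits the model on resamples of the presence records (with replacement,
#' background fixed), the replicate scheme used to carry uncertainty through
#' to the final consensus maps.
#'
#' @inheritParams maxent_fit
#' @param n_replicates number of bootstrap refits.
#' @param seed integer seed.
#' @return list of `maxent_model` (first element is the all-records fit).
#' @export
maxent_bootstrap <- function(presence_cells, background_cells, stack, spec,
                             rm, n_replicates = 10L, seed = 1L) {
  idx <- local_rng(seed, "maxent_bootstrap", function() {
    lapply(seq_len(n_replicates), function(i) {
      sample(length(presence_cells), replace = TRUE)
    })
  })
  fits <- lapply(idx, function(ii) {
    maxent_fit(presence_cells[ii], background_cells, stack, spec, rm)
  })
  c(list(maxent_fit(presence_cells, background_cells, stack, spec, rm)),
    fits)
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model a `maxent_model`.
#' @param path JSON file path.
#' @export
write_maxent <- function(model, path) {
  jsonlite::write_json(list(
    classes = model$spec$classes,
    variable_names = model$spec$variable_names,
    ranges = model$spec$ranges,
    hinge_knots = model$spec$hinge_knots,
    threshold_knots = model$spec$threshold_knots,
    rm = model$rm,
    lambdas = as.list(model$lambdas),
    log_partition = model$log_partition,
    entropy_H = model$entropy_H,
    n_presences = model$n_presences,
    n_background = model$n_background
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_maxent
#' @export
read_maxent <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- feature_spec(j$classes, j$variable_names,
                       matrix(unlist(j$ranges), nrow = 2L),
                       hinge_knots = j$hinge_knots,
                       threshold_knots = j$threshold_knots)
  structure(list(
    spec = spec, rm = j$rm,
    lambdas = unlist(j$lambdas),
    log_partition = j$log_partition, entropy_H = j$entropy_H,
    n_presences = j$n_presences, n_background = j$n_background,
    objective = NA_real_, iterations = NA_integer_
  ), class = "maxent_model")
}
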