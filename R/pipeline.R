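#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with the canonical
#' defaults: 50-km distance thinning, 500-km accessible-area buffer,
#' correlation screening at |r| <= 0.85, the 10-value regularization grid
#' and 8 feature-class sets, E = 5% omission, alpha = 0.05 significance,
#' delta AICc <= 2 selection, 10 bootstrap replicates, MOP at 5% nearest,
#' a connectivity ladder d in {1,2,4,8,10,12}, 10 binarization levels from
#' 3% to 10% and 200 automaton steps. A single master `seed` drives every
#' stochastic stage through named substreams.
#'
#' @param predictors `"raw"` (correlation-screened variables) or `"pca"`
#'   (component layers fitted on M, projected everywhere).
#' @param thinning `"distance"` (distance thinning only) or `"country"`
#'   (distance thinning followed by country-density thinning).
#' @param ... overrides for any default listed above.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(predictors = c("raw", "pca"),
                            thinning = c("distance", "country"), ...) {
  cfg <- list(
    predictors = match.arg(predictors),
    thinning = match.arg(thinning),
    min_km = 50, buffer_km = 500, r_max = 0.85,
    n_components = NULL, var_cum_pct = 95,
    rms = default_rms(), class_sets = default_class_sets(),
    min_subset = 2L,
    k = 5L, E = 0.05, alpha = 0.05, delta_max = 2,
    n_boot = 500L, boot_fraction = 0.5,
    n_replicates = 10L, transfer_mode = "E",
    p_nearest = 0.05, mop_subsample_cap = 10000L,
    d_list = c(1, 2, 4, 8, 10, 12),
    E_levels = seq(0.03, 0.10, length.out = 10L),
    steps = 200L,
    hinge_knots = 20L, threshold_knots = 10L,
    country_targets = NULL,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full modeling-to-dispersal workflow
#'
#' Executes the whole chain on one input bundle: occurrence cleaning,
#' thinning per the configured scheme, accessible-area (M) buffering,
#' predictor preparation (correlation screening or PCA projection),
#' candidate-grid calibration, three-criterion model selection, final
#' bootstrap-replicated models, 5%-omission binarization, independent-record
#' testing, median and sum consensus, MOP extrapolation-risk trimming, and
#' the dispersal scenario sweep started from the independent records.
#' If no candidate passes selection the run halts at that stage with the
#' reason recorded in the manifest (which mirrors how some calibration
#' schemes legitimately select nothing).
#'
#' @param species a `virtual_species` (or any list with `env`, `countries`,
#'   `occurrences`, `invasion_records`).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, rasters (`.asc`), tables
#'   (`.csv`) and the manifest (`manifest.json`) are written there.
#' @param verbose print stage progress?
#' @return list with per-stage results: `occ_clean`, `occ_thinned`, `m_mask`,
#'   `predictor_stack`, `candidates`, `evaluation`, `selected`, `models`,
#'   `consensus` (median / sum / trimmed), `mop`, `dispersal`, `manifest`.
#' @export
run_pipeline <- function(species, config = pipeline_config(),
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(seed = config$seed,
                   scheme = paste(config$predictors, config$thinning,
                                  sep = "+"),
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  result <- list()

  # -- occurrences ----------------------------------------------------------
  calib <- species$occurrences[species$occurrences$role == "calibration", ,
                               drop = FALSE]
  calib <- occurrence_set(calib, occ_provenance(species$occurrences))
  occ_clean <- clean_occurrences(calib, species$countries)
  say("clean: %d -> %d records", nrow(calib), nrow(occ_clean))

  occ_thin <- thin_distance(occ_clean, config$min_km, seed = config$seed)
  if (config$thinning == "country") {
    targets <- config$country_targets
    if (is.null(targets)) {
      cnt <- table(occ_thin$country)
      med <- stats::median(as.numeric(cnt))
      dense <- cnt[cnt > 2 * med]
      targets <- stats::setNames(rep(ceiling(med), length(dense)),
                                 names(dense))
    }
    if (length(targets)) {
      occ_thin <- thin_country_density(occ_thin, targets,
                                       seed = config$seed)
    }
  }
  say("thin: %d records retained", nrow(occ_thin))
  note("occurrences", n_input = nrow(calib), n_clean = nrow(occ_clean),
       n_thinned = nrow(occ_thin))
  result$occ_clean <- occ_clean
  result$occ_thinned <- occ_thin

  # -- accessible area and predictors --------------------------------------
  tpl <- stack_template(species$env)
  m_mask <- buffer_mask(occ_thin, config$buffer_km, tpl)
  n_bg <- count_mask_cells(m_mask)
  say("M: %d background cells", n_bg)
  note("accessible_area", buffer_km = config$buffer_km, n_cells = n_bg)
  result$m_mask <- m_mask

  if (config$predictors == "raw") {
    stack <- select_uncorrelated(species$env, m_mask, r_max = config$r_max)
  } else {
    pca <- pca_fit(species$env, m_mask)
    cum <- cumsum(pca$variance_explained)
    k_comp <- config$n_components
    if (is.null(k_comp)) {
      k_comp <- max(2L, which(cum >= config$var_cum_pct)[1L])
    }
    stack <- pca_project(species$env, pca, n_components = k_comp)
    result$pca <- pca
  }
  say("predictors: %s", paste(stack$names, collapse = ", "))
  note("predictors", mode = config$predictors, kept = stack$names)
  result$predictor_stack <- stack

  # -- calibration ----------------------------------------------------------
  occ_cells <- unique(cell_from_lonlat(tpl, occ_thin$lon, occ_thin$lat))
  occ_cells <- occ_cells[!is.na(occ_cells)]
  bg_cells <- mask_cells(m_mask)
  candidates <- enumerate_candidates(stack$names, rms = config$rms,
                                     class_sets = config$class_sets,
                                     min_subset = config$min_subset)
  say("calibration: %d candidates x %d splits", nrow(candidates), config$k)
  evaluation <- calibrate_grid(occ_cells, bg_cells, stack, candidates,
                               k = config$k, E = config$E,
                               n_boot = config$n_boot,
                               boot_fraction = config$boot_fraction,
                               seed = config$seed,
                               hinge_knots = config$hinge_knots,
                               threshold_knots = config$threshold_knots,
                               verbose = verbose)
  selected <- select_models_by_process(evaluation, alpha = config$alpha,
                                       E = config$E,
                                       delta_max = config$delta_max)
  note("calibration", n_candidates = nrow(candidates),
       n_selected = nrow(selected))
  result$candidates <- candidates
  result$evaluation <- evaluation
  result$selected <- selected
  if (nrow(selected) == 0L) {
    manifest$halted <- "no models selected (significance/omission/AICc)"
    say("halted: no models selected")
    result$manifest <- manifest
    if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
    return(result)
  }

  # -- final models, binarization, independent test, consensus -------------
  medians <- list()
  binaries <- list()
  models <- list()
  n_pass <- 0L
  n_reps <- 0L
  sel_configs <- unique(selected[, c("rm", "classes", "variables")])
  for (ri in seq_len(nrow(sel_configs))) {
    cand <- sel_configs[ri, ]
    vars <- strsplit(cand$variables, ",")[[1L]]
    sub <- env_stack(stack$layers[vars])
    spec <- feature_spec_for(sub, bg_cells, cand$classes,
                             hinge_knots = config$hinge_knots,
                             threshold_knots = config$threshold_knots)
    reps <- maxent_bootstrap(occ_cells, bg_cells, sub, spec, cand$rm,
                             n_replicates = config$n_replicates,
                             seed = config$seed + ri)
    models[[ri]] <- reps[[1L]]
    rep_layers <- list()
    for (mod in reps[-1L]) {
      cl <- maxent_transfer(mod, sub, mode = config$transfer_mode,
                            output = "cloglog")
      calib_suit <- predict_values(mod, stack_values(sub, occ_cells),
                                   output = "cloglog")
      bmap <- binarize(cl, calib_suit, E = config$E)
      n_reps <- n_reps + 1L
      it <- tryCatch(independent_test(bmap, species$invasion_records),
                     error = function(e) list(pass = FALSE))
      if (isTRUE(it$pass)) {
        n_pass <- n_pass + 1L
        rep_layers[[length(rep_layers) + 1L]] <- cl
        binaries[[length(binaries) + 1L]] <- bmap
      }
    }
    if (length(rep_layers)) {
      medians[[length(medians) + 1L]] <- consensus_median(rep_layers)
    }
  }
  note("final_models", n_parameterizations = nrow(sel_configs),
       n_replicates = n_reps, n_passing_independent = n_pass)
  result$models <- models
  if (length(medians) == 0L) {
    manifest$halted <- "no replicate predicted all independent records"
    result$manifest <- manifest
    if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
    return(result)
  }
  cons_median <- consensus_median(medians)
  cons_sum <- consensus_sum(binaries)
  result$consensus <- list(median = cons_median, sum = cons_sum)

  # -- MOP trimming ---------------------------------------------------------
  mop_res <- mop(stack, m_mask, stack, p_nearest = config$p_nearest,
                 subsample_cap = config$mop_subsample_cap,
                 seed = config$seed)
  calib_suit_cons <- as.vector(t(cons_median$values))[occ_cells]
  cons_bin <- binarize(cons_median, calib_suit_cons, E = config$E)
  cons_trimmed <- mop_trim(cons_bin, mop_res)
  result$mop <- mop_res
  result$consensus$binary <- cons_bin
  result$consensus$trimmed <- cons_trimmed
  note("mop", n_strict = sum(mop_res$strict_mask$values == 1, na.rm = TRUE),
       n_trimmed = count_mask_cells(cons_bin) - count_mask_cells(cons_trimmed))

  # -- dispersal -------------------------------------------------------------
  # strict-extrapolation cells become nodata: unsuitable and non-traversable
  cm <- as.vector(t(cons_median$values))
  strict <- as.vector(t(mop_res$strict_mask$values)) == 1
  cm[!is.na(strict) & strict] <- NA_real_
  disp_surface <- grid_from_vector(cons_median, cm)
  seeds <- unique(cell_from_lonlat(tpl, species$invasion_records$lon,
                                   species$invasion_records$lat))
  sweep_res <- tryCatch(
    ca_sweep(disp_surface, calib_suit_cons, seeds,
             d_list = config$d_list, E_levels = config$E_levels,
             steps = config$steps),
    error = function(e) NULL
  )
  if (is.null(sweep_res)) {
    manifest$halted <- "dispersal: no seeds on suitable cells"
  } else {
    note("dispersal", n_scenarios = nrow(sweep_res$log),
         max_occupancy = max(sweep_res$occupancy$values, na.rm = TRUE))
  }
  result$dispersal <- sweep_res
  result$manifest <- manifest
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# write the standard output bundle; every file is declared in the manifest
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }
  put_asc <- function(grid, name) {
    p <- file.path(out_dir, name)
    write_raster(grid, p)
    files <<- c(files, name)
  }
  if (!is.null(result$occ_thinned)) {
    put_csv(as.data.frame(result$occ_thinned), "occurrences_thinned.csv")
  }
  if (!is.null(result$evaluation)) {
    put_csv(result$evaluation, "calibration_results.csv")
  }
  if (!is.null(result$selected)) put_csv(result$selected, "selected_models.csv")
  if (!is.null(result$m_mask)) put_asc(result$m_mask, "m_mask.asc")
  if (!is.null(result$consensus)) {
    put_asc(result$consensus$median, "consensus_median.asc")
    put_asc(result$consensus$sum, "consensus_sum.asc")
    if (!is.null(result$consensus$trimmed)) {
      put_asc(result$consensus$trimmed, "consensus_trimmed.asc")
    }
  }
  if (!is.null(result$mop)) {
    put_asc(result$mop$similarity, "mop_similarity.asc")
    put_asc(result$mop$strict_mask, "mop_strict_mask.asc")
  }
  if (!is.null(result$dispersal)) {
    put_asc(result$dispersal$occupancy, "dispersal_occupancy.asc")
    put_csv(result$dispersal$log, "dispersal_log.csv")
  }
  m <- result$manifest
  m$outputs <- files
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
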