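#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study system.
#
# Builds the default virtual species (a 60x60, 1/6-degree landscape with
# three spatially autocorrelated predictors and a known logistic-quadratic
# niche), a biased-sampling variant, and the two-patch invasion fixture used
# by the dispersal analysis, then writes the full input bundle (rasters as
# ESRI ASCII grids, occurrences as CSV, manifest as JSON) under
# results/inputs/.

suppressPackageStartupMessages(library(nichespread))

seed <- 1
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

vs <- virtual_species(seed, bias = c("1" = 10, "2" = 3))
cat(sprintf("virtual species (seed %d): %d x %d grid, %d predictors\n",
            seed, vs$truth$n_rows, vs$truth$n_cols, length(vs$env$names)))
cat(sprintf("  true suitability in [%.3f, %.3f]; %d calibration records, %d independent\n",
            min(vs$truth$values), max(vs$truth$values),
            nrow(vs$occurrences), nrow(vs$invasion_records)))
cat(sprintf("  per-country record counts: %s\n",
            paste(names(table(vs$occurrences$country)),
                  table(vs$occurrences$country),
                  sep = "=", collapse = ", ")))

for (nm in vs$env$names) {
  write_raster(vs$env$layers[[nm]], file.path(out, paste0(nm, ".asc")))
}
write_raster(vs$truth, file.path(out, "true_suitability.asc"))
write_raster(vs$countries, file.path(out, "countries.asc"))
write_occurrences(vs$occurrences, file.path(out, "occurrences.csv"))
write_occurrences(vs$invasion_records, file.path(out, "invasion_records.csv"))

fx <- make_invasion_fixture(seed)
write_raster(fx$binary_truth, file.path(out, "invasion_fixture_truth.asc"))
write_occurrences(fx$invasion_records,
                  file.path(out, "invasion_fixture_records.csv"))
cat(sprintf("invasion fixture: two suitable bands, bridging radius d = %d cells\n",
            fx$bridging_d))

jsonlite::write_json(list(
  seed = seed,
  grid = c(vs$truth$n_rows, vs$truth$n_cols),
  cell_size_deg = vs$truth$cell_size,
  n_predictors = length(vs$env$names),
  response_params = vs$response_params,
  sampling_bias = c("1" = 10, "2" = 3),
  n_occurrences = nrow(vs$occurrences),
  n_invasion_records = nrow(vs$invasion_records),
  fixture_bridging_d = fx$bridging_d
), file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA,
pretty = TRUE)
cat("inputs written to", out, "\n")
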