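test_that("environmental surfaces are reproducible and correctly named", {
  a <- generate_env(7, 20, 20, 3, smoothness = 3)
  b <- generate_env(7, 20, 20, 3, smoothness = 3)
  expect_identical(lapply(a$layers, `[[`, "values"),
                   lapply(b$layers, `[[`, "values"))
  expect_identical(a$names, c("env1", "env2", "env3"))
  c_ <- generate_env(8, 20, 20, 3, smoothness = 3)
  expect_false(identical(a$layers[[1]]$values, c_$layers[[1]]$values))
  expect_error(generate_env(1, 4, 4, 2), "8 x 8")
  expect_error(generate_env(1, 20, 20, 1), "2 variables")
})

test_that("smoothness controls neighboring-cell correlation", {
  lag1 <- function(env) {
    v <- env$layers[[1]]$values
    cor(as.vector(v[, -ncol(v)]), as.vector(v[, -1]))
  }
  rough <- generate_env(3, 40, 40, 2, smoothness = 0)
  smooth <- generate_env(3, 40, 40, 2, smoothness = 6)
  expect_lt(lag1(rough), 0.3)
  expect_gt(lag1(smooth), 0.8)
})

test_that("the true response follows its closed forms", {
  env <- generate_env(2, 10, 10, 2, smoothness = 2)
  flat <- true_response(env, list(a = c(0, 0), b = c(0, 0), c = 0))
  expect_true(all(flat$values == 0.5))

  # interior optimum of the quadratic at x = -a / (2b)
  grid_vals <- seq(-3, 3, length.out = 9)
  env1 <- env_stack(list(x = tiny_grid(matrix(grid_vals, 3, 3)),
                         y = tiny_grid(matrix(0, 3, 3))))
  a <- 1.2; b <- -0.8
  r <- true_response(env1, list(a = c(a, 0), b = c(b, 0), c = 0))
  opt <- -a / (2 * b)
  best <- which.max(as.vector(t(r$values)))
  x <- stack_values(env1)[, "x"]
  expect_equal(x[best], grid_vals[which.min(abs(grid_vals - opt))])

  # hand-evaluated logistic on a toy grid
  want <- plogis(a * x + b * x^2)
  expect_lt(max(abs(as.vector(t(r$values)) - want)), 1e-12)
  expect_error(true_response(env1, list(a = 1, b = -1, c = 0)), "cover")
})

test_that("country partitions are seeded, labeled and can include sea", {
  tpl <- tiny_grid(matrix(0, 20, 20))
  c1 <- voronoi_countries(tpl, n_countries = 4, seed = 5, sea_fraction = 0.15)
  c2 <- voronoi_countries(tpl, n_countries = 4, seed = 5, sea_fraction = 0.15)
  expect_identical(c1$values, c2$values)
  ids <- unique(as.vector(c1$values))
  expect_true(all(stats::na.omit(ids) %in% 1:4))
  expect_gt(sum(is.na(c1$values)), 0)
  land_only <- voronoi_countries(tpl, n_countries = 3, seed = 1,
                                 sea_fraction = 0)
  expect_false(anyNA(land_only$values))
})

test_that("occurrence sampling follows suitability-times-bias weights", {
  tpl <- tiny_grid(matrix(0, 20, 20))
  truth <- raster_grid(matrix(1, 20, 20), cell_size = 0.01, origin_lat = 10)
  # two-country split, equal suitability, 10:1 sampling bias
  ctry <- raster_grid(matrix(rep(c(1, 2), each = 200), 20, 20),
                      cell_size = 0.01, origin_lat = 10)
  occ <- sample_occurrences(truth, 2000, ctry, bias = c("1" = 10, "2" = 1),
                            seed = 3)
  tab <- table(occ$country)
  ratio <- tab[["1"]] / tab[["2"]]
  expect_gte(ratio, 7)
  expect_lte(ratio, 13)

  # uniform truth, no bias: cell frequencies consistent with uniform
  occ2 <- sample_occurrences(truth, 5000, ctry, seed = 4)
  cells <- cell_from_lonlat(truth, occ2$lon, occ2$lat)
  counts <- tabulate(cells, nbins = 400)
  expect_gt(chisq.test(counts)$p.value, 0.01)

  # single record lands on a positive-truth cell, jittered inside it
  one <- sample_occurrences(truth, 1, ctry, seed = 5)
  expect_equal(nrow(one), 1)
  expect_false(is.na(cell_from_lonlat(truth, one$lon, one$lat)))
  # determinism
  again <- sample_occurrences(truth, 1, ctry, seed = 5)
  expect_identical(as.data.frame(one), as.data.frame(again))
})

test_that("virtual species bundles are bit-reproducible per seed", {
  v1 <- virtual_species(21, n_rows = 20, n_cols = 20, n_occ = 40,
                        n_invasion = 3)
  v2 <- virtual_species(21, n_rows = 20, n_cols = 20, n_occ = 40,
                        n_invasion = 3)
  expect_identical(v1$truth$values, v2$truth$values)
  expect_identical(as.data.frame(v1$occurrences),
                   as.data.frame(v2$occurrences))
  expect_identical(as.data.frame(v1$invasion_records),
                   as.data.frame(v2$invasion_records))
  # occurrences fall on non-nodata cells of the truth layer
  cells <- cell_from_lonlat(v1$truth, v1$occurrences$lon,
                            v1$occurrences$lat)
  expect_false(anyNA(cells))
})

test_that("the invasion fixture has two patches bridged exactly at its radius", {
  fx <- make_invasion_fixture(9)
  # two components at radius 1 (count via the independent oracle from a
  # seed in each band)
  suit_cells <- which(as.vector(t(fx$binary_truth$values)) == 1)
  left_seed <- suit_cells[1]
  comp_left <- flood_fill_oracle(fx$binary_truth, left_seed, 1)
  expect_lt(length(comp_left), length(suit_cells))   # >= 2 components
  right_seed <- setdiff(suit_cells, comp_left)[1]
  comp_right <- flood_fill_oracle(fx$binary_truth, right_seed, 1)
  expect_equal(sort(c(comp_left, comp_right)), suit_cells)

  # invasion records sit in suitable cells of the left band
  rec_cells <- cell_from_lonlat(fx$binary_truth, fx$invasion_records$lon,
                                fx$invasion_records$lat)
  expect_true(all(rec_cells %in% comp_left))

  # the documented bridging radius is tight: below it the far band is never
  # reached, at it the whole suitable area is
  below <- ca_simulate(fx$binary_truth, rec_cells, d = fx$bridging_d - 1)
  expect_equal(occupied_cells(below), sort(comp_left))
  at <- ca_simulate(fx$binary_truth, rec_cells, d = fx$bridging_d)
  expect_equal(occupied_cells(at), suit_cells)
})
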