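full_mask <- function(tpl) {
  raster_grid(matrix(1, tpl$n_rows, tpl$n_cols),
              origin_lon = tpl$origin_lon, origin_lat = tpl$origin_lat,
              cell_size = tpl$cell_size)
}

stack_of <- function(...) {
  layers <- lapply(list(...), function(v) tiny_grid(v))
  names(layers) <- paste0("v", seq_along(layers))
  env_stack(layers)
}

test_that("select_uncorrelated drops perfect duplicates, keeps orthogonal sets", {
  set.seed(2)
  a <- matrix(rnorm(100), 10, 10)
  st <- stack_of(a, a)
  kept <- select_uncorrelated(st, full_mask(tiny_grid(a)), r_max = 0.85)
  expect_identical(kept$names, "v1")
  # priority reversal keeps the other one
  kept2 <- select_uncorrelated(st, full_mask(tiny_grid(a)), r_max = 0.85,
                               priority = c("v2", "v1"))
  expect_identical(kept2$names, "v2")

  b <- matrix(rnorm(100), 10, 10)
  st2 <- stack_of(a, b)
  expect_setequal(
    select_uncorrelated(st2, full_mask(tiny_grid(a)), r_max = 0.85)$names,
    c("v1", "v2")
  )
  expect_error(
    select_uncorrelated(stack_of(a, matrix(1, 10, 10)),
                        full_mask(tiny_grid(a))),
    "v2"
  )
})

test_that("select_uncorrelated equals a brute-force greedy oracle", {
  set.seed(31)
  n <- 200
  base <- rnorm(n)
  x1 <- base + rnorm(n, sd = 0.2)
  x2 <- base + rnorm(n, sd = 0.2)      # highly correlated with x1
  x3 <- rnorm(n)
  x4 <- 0.7 * x3 + rnorm(n, sd = 0.4)  # moderately correlated with x3
  vals <- cbind(v1 = x1, v2 = x2, v3 = x3, v4 = x4)
  st <- stack_of(matrix(x1, 10, 20), matrix(x2, 10, 20),
                 matrix(x3, 10, 20), matrix(x4, 10, 20))
  r_max <- 0.85
  # oracle: literal greedy scan over the correlation matrix
  cm <- abs(cor(vals))
  kept <- character(0)
  for (v in paste0("v", 1:4)) {
    if (all(cm[v, kept] <= r_max)) kept <- c(kept, v)
  }
  got <- select_uncorrelated(st, full_mask(st$layers[[1]]), r_max = r_max)
  expect_identical(got$names, kept)
})

test_that("pca_fit satisfies its algebraic invariants", {
  set.seed(8)
  m <- lapply(1:3, function(i) matrix(rnorm(150, sd = i), 10, 15))
  st <- stack_of(m[[1]], m[[2]], m[[3]])
  pc <- pca_fit(st, full_mask(st$layers[[1]]))
  rtr <- t(pc$rotation) %*% pc$rotation
  expect_lt(max(abs(rtr - diag(3))), 1e-8)
  expect_lt(abs(sum(pc$variance_explained) - 100), 1e-6)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  # deterministic sign: largest-magnitude loading positive
  for (j in 1:3) {
    expect_gt(pc$rotation[which.max(abs(pc$rotation[, j])), j], 0)
  }
})

test_that("pca_fit handles symmetric and rank-1 two-variable cases", {
  set.seed(9)
  a <- rnorm(400)
  b <- rnorm(400)
  st <- stack_of(matrix(a, 20, 20), matrix(b, 20, 20))
  pc <- pca_fit(st, full_mask(st$layers[[1]]))
  # independent standardized variables: close to 50/50 (sampling noise)
  expect_lt(abs(pc$variance_explained[1] - 50), 10)

  st2 <- stack_of(matrix(a, 20, 20), matrix(a, 20, 20))
  pc2 <- pca_fit(st2, full_mask(st2$layers[[1]]))
  expect_lt(abs(pc2$variance_explained[1] - 100), 1e-6)
})

test_that("pca_fit matches an eigen-decomposition of the correlation matrix", {
  vals <- matrix(c(1.0, 2.0, 0.5,
                   2.0, 1.0, 0.7,
                   3.0, 4.0, 0.2,
                   4.0, 3.0, 0.9,
                   5.0, 5.5, 0.4), 5, 3, byrow = TRUE)
  st <- stack_of(matrix(vals[, 1], 1, 5), matrix(vals[, 2], 1, 5),
                 matrix(vals[, 3], 1, 5))
  pc <- pca_fit(st, full_mask(st$layers[[1]]))
  ev <- eigen(cor(vals), symmetric = TRUE)
  expect_equal(100 * ev$values / sum(ev$values), pc$variance_explained,
               tolerance = 1e-8)
  for (j in 1:3) {
    w <- ev$vectors[, j]
    if (w[which.max(abs(w))] < 0) w <- -w
    expect_equal(unname(pc$rotation[, j]), w, tolerance = 1e-8)
  }
})

test_that("pca_project reproduces internal scores and centers correctly", {
  set.seed(10)
  m <- lapply(1:3, function(i) matrix(rnorm(200), 10, 20))
  st <- stack_of(m[[1]], m[[2]], m[[3]])
  mask <- full_mask(st$layers[[1]])
  pc <- pca_fit(st, mask)
  proj <- pca_project(st, pc, n_components = 3)
  vals <- stack_values(st)
  scores <- scale(vals, center = pc$means, scale = pc$scales) %*% pc$rotation
  got <- stack_values(proj)
  expect_lt(max(abs(got - scores)), 1e-8)
  # zero mean over the fitting mask, per component
  expect_lt(max(abs(colMeans(got))), 1e-6)
  # component variances over the fitting region equal the eigenvalues
  expect_equal(unname(apply(got, 2, var)), pc$sdev^2, tolerance = 1e-6)
  # a cell at the variable means scores 0
  mid <- matrix(pc$means, 1)
  colnames(mid) <- pc$variable_names
  z <- scale(mid, center = pc$means, scale = pc$scales) %*% pc$rotation
  expect_lt(max(abs(z)), 1e-9)
  expect_error(pca_project(st, pc, n_components = 4), "exceeds")
})

test_that("pca transform survives JSON serialization", {
  set.seed(11)
  st <- stack_of(matrix(rnorm(100), 10, 10), matrix(rnorm(100), 10, 10))
  pc <- pca_fit(st, full_mask(st$layers[[1]]))
  p <- withr::local_tempfile(fileext = ".json")
  write_pca(pc, p)
  pc2 <- read_pca(p)
  expect_equal(unname(pc2$rotation), unname(pc$rotation), tolerance = 1e-12)
  expect_equal(unname(pc2$means), unname(pc$means), tolerance = 1e-12)
  expect_equal(pc2$variance_explained, pc$variance_explained,
               tolerance = 1e-12)
})
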