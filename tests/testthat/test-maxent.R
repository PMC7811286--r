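# small standard fixture: 2 predictors on a 20x50 grid with a known
# quadratic-response species
maxent_fixture <- function(seed = 1, n_pres = 120) {
  env <- generate_env(seed, 20, 50, 2, smoothness = 3)
  truth <- true_response(env, list(a = c(0.8, 0), b = c(-1, -0.4), c = 1))
  bg <- seq_len(1000)
  set.seed(seed + 100)
  pres <- sample(bg, n_pres, replace = TRUE,
                 prob = as.vector(t(truth$values)))
  list(env = env, truth = truth, bg = bg, pres = unique(pres))
}

test_that("feature construction counts and endpoint scaling are exact", {
  rng <- rbind(c(0, 0), c(1, 1))
  spec <- feature_spec("lqp", c("x", "y"), rng)
  f <- build_features(cbind(x = c(0, 1, 0.5), y = c(0, 1, 0.5)), spec)
  expect_equal(ncol(f), 5)  # 2 l + 2 q + 1 p
  expect_equal(unname(f[1, ]), rep(0, 5))
  expect_equal(unname(f[2, ]), rep(1, 5))
  expect_equal(unname(f[3, "p_x_x_y"]), 0.25)

  # threshold features evaluate knot-by-knot
  spec_t <- feature_spec("t", "x", rbind(0, 1), threshold_knots = 3)
  ft <- build_features(cbind(x = 0.6), spec_t)
  knots <- (1:3) / 4
  expect_equal(unname(ft[1, ]), as.numeric(0.6 >= knots))

  # hinge ramps are 0 at range min and 1 at range max
  spec_h <- feature_spec("h", "x", rbind(0, 1), hinge_knots = 4)
  expect_equal(unname(build_features(cbind(x = 0), spec_h)[1, ]), rep(0, 4))
  expect_equal(unname(build_features(cbind(x = 1), spec_h)[1, ]), rep(1, 4))
  expect_error(feature_spec("z", "x", rbind(0, 1)), "subset")
})

test_that("extreme regularization shrinks to the uniform model", {
  fx <- maxent_fixture()
  spec <- feature_spec_for(fx$env, fx$bg, "lq")
  fit <- maxent_fit(fx$pres, fx$bg, fx$env, spec, rm = 1e6)
  expect_true(all(fit$lambdas == 0))
  raw <- maxent_predict(fit, fx$env, output = "raw")
  expect_equal(unique(round(as.vector(raw$values), 12)), 1 / 1000)
  cl <- maxent_predict(fit, fx$env, output = "cloglog")
  expect_equal(unique(round(as.vector(cl$values), 6)),
               round(1 - exp(-1), 6))
})

test_that("raw output sums to one over the background after every fit", {
  for (sd in 1:3) {
    fx <- maxent_fixture(sd)
    spec <- feature_spec_for(fx$env, fx$bg, "lqp")
    fit <- maxent_fit(fx$pres, fx$bg, fx$env, spec, rm = 0.5)
    raw <- predict_cell_values(fit, fx$env, fx$bg, output = "raw")
    expect_lt(abs(sum(raw) - 1), 1e-6)
    expect_true(fit$entropy_H >= 0 && fit$entropy_H <= log(1000))
  }
})

test_that("null presences leave the fitted density near uniform", {
  # presences drawn uniformly from the background carry no signal; the
  # fitted distribution should stay close to uniform (entropy near ln N).
  # Individual weights need not vanish — the near-collinear l/q features of
  # one variable admit cheap cancelling pairs — so the invariant is on the
  # fitted density, not the coefficients.
  near_uniform <- 0
  for (sd in 1:10) {
    env <- generate_env(sd + 50, 20, 50, 2, smoothness = 3)
    bg <- seq_len(1000)
    set.seed(sd)
    pres <- sample(bg, 100)
    spec <- feature_spec_for(env, bg, "lq")
    fit <- maxent_fit(pres, bg, env, spec, rm = 1)
    if (fit$entropy_H / log(1000) > 0.99) near_uniform <- near_uniform + 1
  }
  expect_gte(near_uniform, 9)
})

test_that("single-feature fit matches a 1-D golden-section oracle", {
  # one binary feature with presence mean 0.8, background mean 0.5
  n_bg <- 200
  fb <- matrix(c(rep(1, 100), rep(0, 100)), ncol = 1)
  n_p <- 10
  fp <- matrix(c(rep(1, 8), rep(0, 2)), ncol = 1)
  obj <- function(l) -mean(fp) * l + log(sum(exp(fb * l))) # rm -> 0+
  gs <- optimize(obj, c(-10, 10), tol = 1e-10)$minimum

  # the same objective through the package optimizer, beta ~ 0
  env <- env_stack(list(x = raster_grid(matrix(c(rep(1, 100), rep(0, 100)),
                                               10, 20, byrow = TRUE))))
  spec <- feature_spec("l", "x", rbind(-1e-9, 1 + 1e-9))
  pres_cells <- c(rep(1L, 8), rep(101L, 2))
  # cells 1..100 hold 1 (first five rows), 101..200 hold 0
  fit <- maxent_fit(pres_cells, 1:200, env, spec, rm = 1e-9, tol = 1e-12)
  expect_equal(unname(fit$lambdas[1]), gs, tolerance = 1e-4)
})

test_that("raw predictions match direct evaluation with hand-set weights", {
  env <- env_stack(list(x = tiny_grid(matrix(seq(0, 1, length.out = 10), 2, 5))))
  spec <- feature_spec("lq", "x", rbind(0, 1))
  fit <- maxent_fit(c(3L, 7L), 1:10, env, spec, rm = 1)
  fit$lambdas <- c(l_x = 1.3, q_x = -0.7)
  x <- stack_values(env)[, "x"]
  eta <- 1.3 * x - 0.7 * x^2
  fit$log_partition <- log(sum(exp(eta)))
  raw <- predict_cell_values(fit, env, 1:10, output = "raw")
  expect_lt(max(abs(raw - exp(eta) / sum(exp(eta)))), 1e-10)
  # monotone transform: cloglog ranks equal raw ranks
  praw <- exp(eta - fit$log_partition)
  cl <- 1 - exp(-exp(fit$entropy_H) * praw)
  expect_equal(order(raw), order(cl))
})

test_that("transfer modes agree in range and differ out of range as specified", {
  fx <- maxent_fixture(4)
  spec <- feature_spec_for(fx$env, fx$bg, "lq")
  fit <- maxent_fit(fx$pres, fx$bg, fx$env, spec, rm = 1)
  # in-range: all three modes identical
  pe <- maxent_transfer(fit, fx$env, "E")
  pec <- maxent_transfer(fit, fx$env, "EC")
  pne <- maxent_transfer(fit, fx$env, "NE")
  expect_equal(pe$values, pec$values, tolerance = 1e-12)
  expect_equal(pe$values, pne$values, tolerance = 1e-12)

  # push one cell of variable 1 above its calibration max
  env2 <- fx$env
  hi <- spec$ranges[2, 1]
  env2$layers[[1]]$values[1, 1] <- hi + 5
  tec <- maxent_transfer(fit, env2, "EC")
  tne <- maxent_transfer(fit, env2, "NE")
  # EC: equals the prediction of a cell clamped at the max
  env_cl <- fx$env
  env_cl$layers[[1]]$values[1, 1] <- hi
  ref <- maxent_transfer(fit, env_cl, "E")
  expect_equal(tec$values[1, 1], ref$values[1, 1], tolerance = 1e-12)
  # NE: the out-of-range cell becomes nodata, others unchanged
  expect_true(is.na(tne$values[1, 1]))
  expect_equal(tne$values[-1, ], pe$values[-1, ], tolerance = 1e-12)
  expect_error(maxent_transfer(fit, env2, "XX"))
})

test_that("fitted lq model ranks cells like the true quadratic suitability", {
  passes <- 0
  for (sd in 1:5) {
    env <- generate_env(sd + 20, 40, 50, 2, smoothness = 4)
    truth <- true_response(env, list(a = c(1, 0), b = c(-1.2, 0), c = 0.5))
    bg <- seq_len(2000)
    set.seed(sd)
    pres <- unique(sample(bg, 250, replace = TRUE,
                          prob = as.vector(t(truth$values))))[1:200]
    spec <- feature_spec_for(env, bg, "lq")
    fit <- maxent_fit(pres, bg, env, spec, rm = 1)
    raw <- predict_cell_values(fit, env, bg, output = "raw")
    rho <- cor(raw, as.vector(t(truth$values)), method = "spearman")
    if (rho > 0.9) passes <- passes + 1
  }
  expect_gte(passes, 4)
})

test_that("the fitting objective is convex: multistart converges to one optimum", {
  fx <- maxent_fixture(8)
  spec <- feature_spec_for(fx$env, fx$bg, "lq")
  base <- maxent_fit(fx$pres, fx$bg, fx$env, spec, rm = 1)
  set.seed(55)
  for (i in 1:5) {
    start <- rnorm(length(base$lambdas), sd = 0.5)
    alt <- maxent_fit(fx$pres, fx$bg, fx$env, spec, rm = 1, init = start)
    expect_lt(abs(alt$objective - base$objective), 1e-5)
  }
})

test_that("bootstrap replicates are seeded and background-fixed", {
  fx <- maxent_fixture(6)
  spec <- feature_spec_for(fx$env, fx$bg, "lq")
  reps <- maxent_bootstrap(fx$pres[1:40], fx$bg, fx$env, spec, rm = 1,
                           n_replicates = 3, seed = 5)
  reps2 <- maxent_bootstrap(fx$pres[1:40], fx$bg, fx$env, spec, rm = 1,
                            n_replicates = 3, seed = 5)
  expect_equal(length(reps), 4)  # all-records fit + 3 replicates
  expect_identical(lapply(reps, function(m) m$lambdas),
                   lapply(reps2, function(m) m$lambdas))
})

test_that("model JSON round-trips and reproduces predictions", {
  fx <- maxent_fixture(2)
  spec <- feature_spec_for(fx$env, fx$bg, "lq")
  fit <- maxent_fit(fx$pres, fx$bg, fx$env, spec, rm = 1)
  p <- withr::local_tempfile(fileext = ".json")
  write_maxent(fit, p)
  fit2 <- read_maxent(p)
  r1 <- predict_cell_values(fit, fx$env, fx$bg, output = "cloglog")
  r2 <- predict_cell_values(fit2, fx$env, fx$bg, output = "cloglog")
  expect_equal(r1, r2, tolerance = 1e-12)
})
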