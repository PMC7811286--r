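test_that("candidate enumeration matches the closed-form count", {
  # (2^p - p - 1) subsets of size >= 2, crossed with rms and class sets
  for (p in c(3, 4, 5)) {
    cands <- enumerate_candidates(p, rms = c(1, 2), class_sets = c("lq", "q"))
    expect_equal(nrow(cands), (2^p - p - 1) * 2 * 2)
    expect_false(anyDuplicated(cands) > 0)
    expect_true(all(lengths(strsplit(cands$variables, ",")) >= 2))
  }
  expect_equal(nrow(enumerate_candidates(2, rms = 1, class_sets = "lq")), 1)
  expect_error(enumerate_candidates(1, rms = 1, class_sets = "lq"))
})

test_that("random 50/50 splits are balanced, seeded and near-symmetric", {
  occ <- data.frame(i = 1:10)
  sp <- kfold_splits(occ, k = 5, seed = 3)
  expect_length(sp, 5)
  for (s in sp) {
    expect_length(s$train, 5)
    expect_length(s$test, 5)
    expect_setequal(c(s$train, s$test), 1:10)
  }
  expect_identical(kfold_splits(occ, k = 5, seed = 3), sp)
  expect_error(kfold_splits(data.frame(i = 1:3), k = 2), "at least 4")

  # each record trains in roughly half the splits over many seeds
  n_train <- numeric(20)
  for (sd in 1:200) {
    sp <- kfold_splits(data.frame(i = 1:20), k = 1, seed = sd)
    n_train[sp[[1]]$train] <- n_train[sp[[1]]$train] + 1
  }
  expect_true(all(n_train / 200 >= 0.35 & n_train / 200 <= 0.65))
})

test_that("partial ROC separates signal from noise", {
  set.seed(1)
  land <- runif(2000)
  top <- sort(land, decreasing = TRUE)[1:20] + 1e-3
  pr <- partial_roc(top, land, seed = 5)
  expect_gt(pr$mean_auc_ratio, 1)
  expect_lt(pr$p_value, 0.05)

  # degenerate: constant landscape
  dg <- partial_roc(rep(0.5, 6), rep(0.5, 100), seed = 1)
  expect_true(dg$degenerate)
  expect_equal(dg$mean_auc_ratio, 1)
  expect_equal(dg$p_value, 1)
})

test_that("partial AUC with the full band matches the trapezoid oracle", {
  set.seed(8)
  for (i in 1:5) {
    land <- runif(10)
    test <- runif(7)
    got <- partial_auc(test, land, E = 1)
    # full-band statistic = AUC / (area under y = x) with the package's
    # smoothed sensitivity; oracle rebuilds the same curve independently
    thr <- sort(unique(land))
    x <- vapply(thr, function(t) mean(land >= t), numeric(1))
    st <- sort(test)
    m <- length(test)
    fh <- approx(c(min(land) - 1e-12, st, max(land) + 1e-12),
                 c(0, (seq_len(m) + 0.5) / (m + 1), 1),
                 xout = thr, rule = 2, ties = "ordered")$y
    xx <- c(1, x)
    yy <- c(1, 1 - fh)
    o <- order(xx)
    xx <- xx[o]; yy <- yy[o]
    want <- sum(diff(xx) * (head(yy, -1) + tail(yy, -1)) / 2) /
      ((max(xx)^2 - min(xx)^2) / 2)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("omission_rate counts strictly-below fractions", {
  v <- c(0.1, 0.4, 0.6, 0.9)
  expect_equal(omission_rate(v, 0.05), 0)
  expect_equal(omission_rate(v, 0.95), 1)
  expect_equal(omission_rate(v, 0.5), 0.5)
  expect_equal(omission_rate(v, 0.4), 0.25)  # ties are not omitted
})

test_that("AICc matches its closed form and a direct-evaluation oracle", {
  uni <- raster_grid(matrix(1 / 100, 10, 10))
  expect_equal(aicc(NULL, occ_cells = 1:10, landscape_raw = uni, k = 2),
               4 - 2 * 10 * log(1 / 100) + 12 / 7, tolerance = 1e-10)
  expect_equal(aicc(NULL, occ_cells = 1:10, landscape_raw = uni, k = 2),
               97.8177, tolerance = 1e-3)
  # correction blows up at k = n - 1
  expect_equal(aicc(NULL, occ_cells = 1:10, landscape_raw = uni, k = 9), Inf)
  # random layer vs independent arithmetic
  set.seed(4)
  v <- matrix(runif(50), 5, 10)
  lay <- raster_grid(v)
  occ <- c(3L, 17L, 25L, 40L, 44L)
  p <- as.vector(t(v))[occ] / sum(v)
  want <- 2 * 3 - 2 * sum(log(p)) + 2 * 3 * 4 / (5 - 3 - 1)
  expect_equal(aicc(NULL, occ, lay, k = 3), want, tolerance = 1e-10)
  # zero suitability at an occurrence -> infinite AICc
  v2 <- v; v2[1, 3] <- 0
  expect_equal(aicc(NULL, c(3L, 17L), raster_grid(v2), k = 1), Inf)
})

test_that("three-criterion selection filters and recomputes delta AICc", {
  rec <- data.frame(
    id = 1:6,
    proc_p = c(0.01, 0.20, 0.01, 0.01, 0.01, 0.04),
    omission_rate = c(0.02, 0.02, 0.10, 0.03, 0.04, 0.01),
    aicc = c(105, 100, 101, 103, 110, 104)
  )
  # pass significance+omission: ids 1, 4, 5, 6 -> min AICc 103 (id 4)
  # delta <= 2: ids 4 (0), 6 (1), 1 (2); id 5 dropped (delta 7)
  sel <- select_models(rec)
  expect_setequal(sel$id, c(1, 4, 6))
  expect_equal(sel$delta_aicc[sel$id == 4], 0)
  expect_equal(sel$delta_aicc[sel$id == 1], 2)
  # invariant to input ordering
  sel2 <- select_models(rec[sample(6), ])
  expect_setequal(sel2$id, sel$id)
  # all insignificant -> empty
  rec$proc_p <- 0.9
  expect_equal(nrow(select_models(rec)), 0)
})

test_that("binarization uses the modified least-presence order statistic", {
  lay <- raster_grid(matrix(seq(0, 1, length.out = 20), 4, 5))
  calib <- 0.05 * (1:20)
  b <- binarize(lay, calib, E = 0.05)
  # floor(0.05 * 20) = 1 -> 0-based index 1 -> second smallest value
  expect_equal(attr(b, "threshold"), 0.10)
  expect_identical(sort(unique(as.vector(b$values))), c(0, 1))
  # E = 0 is the least training presence
  b0 <- binarize(lay, calib, E = 0)
  expect_equal(attr(b0, "threshold"), 0.05)
})

test_that("binarization omission is bounded and suitable areas nest in E", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:100, 1)
    calib <- runif(n)
    lay <- raster_grid(matrix(runif(64), 8, 8))
    prev <- NULL
    for (E in c(0, 0.03, 0.05, 0.10)) {
      b <- binarize(lay, calib, E = E)
      om <- mean(calib < attr(b, "threshold"))
      expect_lte(om, E + 1 / n)
      if (!is.null(prev)) {
        # larger E -> higher threshold -> suitable area shrinks
        expect_true(all(b$values <= prev$values))
      }
      prev <- b
    }
  }
})

test_that("consensus layers take cellwise medians and sums", {
  l1 <- raster_grid(matrix(c(0, 0.5, 1, 0.2), 2, 2))
  expect_identical(consensus_median(list(l1, l1, l1))$values, l1$values)
  l2 <- raster_grid(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2))
  l3 <- raster_grid(matrix(c(1, 1, 0, 1), 2, 2))
  med <- consensus_median(list(l1, l2, l3))
  expect_equal(med$values[1, 1], 0.5)
  b <- binarize(l3, 0.5, E = 0)
  expect_equal(unique(as.vector(consensus_sum(list(b, b, b))$values)),
               c(3, 0))
  expect_error(consensus_median(list(l1, tiny_grid(matrix(0, 3, 3)))),
               "geometries")
})

test_that("independent-record testing flags failures and contract breaches", {
  m <- binarize(raster_grid(matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE),
                            origin_lon = 0, origin_lat = 2, cell_size = 1),
                0.5, E = 0)
  good <- occurrence_set(data.frame(species = "sp", lon = c(0.5, 1.5),
                                    lat = c(1.5, 1.5), role = "independent"))
  expect_true(independent_test(m, good)$pass)
  mixed <- occurrence_set(data.frame(species = "sp", lon = c(0.5, 0.5),
                                     lat = c(1.5, 0.5), role = "independent"))
  it <- independent_test(m, mixed)
  expect_false(it$pass)
  expect_identical(it$flags$suitable, c(TRUE, FALSE))
  outside <- occurrence_set(data.frame(species = "sp", lon = 5, lat = 5,
                                       role = "independent"))
  expect_error(independent_test(m, outside), "extent")
  m$values[1, 1] <- NA
  expect_error(independent_test(m, good), "nodata")
})

test_that("per-process selection mirrors process-level success and failure", {
  rec <- data.frame(
    rm = 1, classes = "lq", variables = "a,b",
    process = c(1, 1, 2, 2),
    proc_p = c(0.01, 0.02, 0.5, 0.6),
    omission_rate = c(0.01, 0.02, 0.01, 0.02),
    aicc = c(100, 101, 100, 101)
  )
  sel <- select_models_by_process(rec)
  expect_true(all(sel$process == 1))
  expect_equal(nrow(sel), 2)
})
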