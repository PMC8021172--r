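test_that("generated landscapes hit the requested composition", {
  fr <- c(farmland = 0.68, woodland = 0.07, grassland = 0.05, water = 0.04,
          urban = 0.03, rural_residential = 0.11, industrial_traffic = 0.01,
          barren = 0.01)
  lu <- generate_landscape(c(100, 100), fr, autocorr = 4, seed = 71)
  got <- as.vector(table(factor(lu$values, levels = 1:8))) / 1e4
  expect_true(all(abs(got - unname(fr)) <= 0.02))
  # same seed, same map; different seed, different map
  lu2 <- generate_landscape(c(100, 100), fr, autocorr = 4, seed = 71)
  expect_identical(lu$values, lu2$values)
  lu3 <- generate_landscape(c(100, 100), fr, autocorr = 4, seed = 72)
  expect_false(identical(lu$values, lu3$values))
  expect_error(generate_landscape(c(10, 10), c(farmland = 0.5)), "sum to 1")
})

test_that("zero autocorrelation gives near-independent labels", {
  fr <- c(farmland = 0.6, woodland = 0.4, grassland = 0, water = 0,
          urban = 0, rural_residential = 0, industrial_traffic = 0,
          barren = 0)
  lu <- generate_landscape(c(100, 100), fr, autocorr = 0, seed = 73)
  v <- lu$values
  # join-count statistic: fraction of horizontally adjacent equal pairs;
  # under independence it approaches sum(p^2) = 0.52
  same <- mean(v[, -1] == v[, -ncol(v)])
  expect_lt(abs(same - (0.6^2 + 0.4^2)), 0.02)
  # positive autocorrelation pushes the statistic well above independence
  lu_s <- generate_landscape(c(100, 100), fr, autocorr = 4, seed = 73)
  vs <- lu_s$values
  expect_gt(mean(vs[, -1] == vs[, -ncol(vs)]), 0.8)
})

test_that("cellwise evolution recovers the generating matrix", {
  lu <- generate_landscape(c(200, 200),
                           c(farmland = 0.5, woodland = 0.5, grassland = 0,
                             water = 0, urban = 0, rural_residential = 0,
                             industrial_traffic = 0, barren = 0),
                           autocorr = 0, seed = 74)
  P <- diag(8)
  P[1, 1:2] <- c(0.8, 0.2)
  P[2, 1:2] <- c(0.3, 0.7)
  tm_true <- as_transition_matrix(P, 1:8, default_legend()$names)
  lu1 <- evolve_landscape(lu, tm_true, seed = 75)
  est <- transition_matrix(lu, lu1, 10)
  expect_equal(rowSums(est$probabilities), rep(1, 8), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (i in 1:2) for (j in 1:2) {
    expect_lt(abs(est$probabilities[i, j] - P[i, j]) / P[i, j], 0.05)
  }
  # identity evolution leaves the map untouched
  same <- evolve_landscape(lu, as_transition_matrix(diag(8), 1:8), seed = 76)
  expect_identical(same$values, lu$values)
  bad <- diag(8); bad[1, 1] <- 0.5
  expect_error(evolve_landscape(lu, bad, seed = 1), "non-stochastic")
})

test_that("driver generation encodes the requested model and degrades with noise", {
  lu <- generate_landscape(c(100, 100),
                           c(farmland = 0.7, woodland = 0.3, grassland = 0,
                             water = 0, urban = 0, rural_residential = 0,
                             industrial_traffic = 0, barren = 0),
                           autocorr = 0, seed = 77)
  truth <- logistic_model(2L, -1, c(drvA = 2))
  drv <- generate_drivers(lu, list(truth), seed = 78)
  drv_same <- generate_drivers(lu, list(truth), seed = 78)
  expect_identical(drv$drvA$values, drv_same$drvA$values)
  fit0 <- fit_logistic(lu, 2L, drv)
  noisy <- generate_drivers(lu, list(truth), noise_sd = 3, seed = 78)
  fit3 <- fit_logistic(lu, 2L, noisy)
  # measurement error attenuates the slope
  expect_lt(fit3$coefficients[["drvA"]], fit0$coefficients[["drvA"]])
  expect_error(
    generate_drivers(lu, list(truth, logistic_model(1L, 0, c(drvA = 1))),
                     seed = 1),
    "inconsistent driver names")
})

test_that("the packaged fixture is complete, aligned and reproducible", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg1 <- make_fixture("huaihe-mini", d1, seed = 79, shape = c(50, 50))
  cfg2 <- make_fixture("huaihe-mini", d2, seed = 79, shape = c(50, 50))
  for (f in c("landuse_t0.asc", "landuse_t1.asc", "threats.csv",
              "sensitivity.csv", "fast_urban_growth.yml",
              "transition_rules.csv", "config.yml")) {
    expect_true(file.exists(file.path(d1, f)), label = f)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  t0 <- read_grid(file.path(d1, "landuse_t0.asc"))
  t1 <- read_grid(file.path(d1, "landuse_t1.asc"))
  drv <- read_grid(file.path(d1, "drv_urban.asc"), "continuous")
  expect_silent(assert_aligned(t0, t1, drv))
  expect_identical(t0$legend$names, t1$legend$names)
  expect_error(make_fixture("unknown"), "unknown fixture")
})
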