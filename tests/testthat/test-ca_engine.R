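test_that("neighbourhood density matches hand counts", {
  lu <- make_lu(matrix(1L, 10, 10))
  expect_equal(neighborhood_density(lu, 1L, 5)$values,
               matrix(1, 10, 10))
  expect_equal(neighborhood_density(lu, 2L, 5)$values,
               matrix(0, 10, 10))
  m <- matrix(1L, 10, 10); m[5, 5] <- 5L
  d <- neighborhood_density(make_lu(m), 5L, 5)
  expect_equal(d$values[5, 5], 1 / 25) # interior cell sees itself once
  expect_equal(d$values[1, 1], 0)
  # edge truncation renormalises: corner window is 3x3
  m2 <- matrix(1L, 10, 10); m2[1, 1] <- 5L
  expect_equal(neighborhood_density(make_lu(m2), 5L, 5)$values[1, 1], 1 / 9)
  expect_error(neighborhood_density(lu, 1L, 4), "odd")
})

test_that("kappa reproduces hand-worked agreement values", {
  set.seed(9)
  m <- matrix(sample(1:8, 100, replace = TRUE), 10, 10)
  lu <- make_lu(m)
  expect_equal(kappa(lu, lu), 1)
  # 20 cells, balanced 2-class marginals, one swapped pair:
  # P_o = 0.9, P_c = 0.5, kappa = (0.9 - 0.5)/(1 - 0.5) = 0.8
  a <- make_lu(matrix(rep(c(1L, 2L), each = 10), 4, 5), legend = legend2())
  bv <- a$values
  i1 <- which(bv == 1L)[1]; i2 <- which(bv == 2L)[1]
  bv[c(i1, i2)] <- c(2L, 1L)
  b <- make_lu(bv, legend = legend2())
  expect_equal(mean(a$values == b$values), 0.9)
  expect_equal(kappa(a, b), 0.8)
})

test_that("scenario demands compound annual growth rates", {
  leg <- legend2()
  state <- landhab:::new_class_areas(1:2, leg$names, c(900, 100), "now")
  ident <- as_transition_matrix(diag(2), 1:2, leg$names)
  fast <- scenario_config("fast", rates = c(urban = 5.68))
  dem <- scenario_demands(state, fast, 10, ident)
  expect_equal(unname(dem$areas["urban"]), 100 * 1.0568^10, tolerance = 1e-12)
  expect_equal(unname(dem$areas["urban"]), 173.8, tolerance = 0.05)
  expect_equal(sum(dem$areas), 1000, tolerance = 1e-9)
  slow <- scenario_config("slow", rates = c(urban = 1.45))
  dem2 <- scenario_demands(state, slow, 10, ident)
  expect_equal(unname(dem2$areas["urban"]), 100 * 1.0145^10, tolerance = 1e-12)
  expect_equal(unname(dem2$areas["urban"]), 115.5, tolerance = 0.05)
  none <- scenario_config("none",
                          rates = c(farmland = 0, urban = 0))
  expect_equal(scenario_demands(state, none, 10, ident)$areas, state$areas)
})

test_that("protected classes never shrink in the demand vector", {
  leg <- default_legend()
  state <- landhab:::new_class_areas(1:8, leg$names,
                                     c(600, 100, 80, 60, 50, 70, 20, 20))
  tm <- landhab:::fixture_true_tm()
  eco <- scenario_config("eco", rates = c(urban = 0),
                         protected = c("woodland", "grassland", "water"))
  dem <- scenario_demands(state, eco, 10, tm)
  expect_gte(dem$areas[["woodland"]], state$areas[["woodland"]] - 1e-9)
  expect_gte(dem$areas[["water"]], state$areas[["water"]] - 1e-9)
  expect_equal(dem$areas[["urban"]], state$areas[["urban"]])
  expect_equal(sum(dem$areas), sum(state$areas), tolerance = 1e-9)
})

test_that("identity demands reproduce the input exactly", {
  lu <- generate_landscape(c(40, 40), seed = 31, autocorr = 3)
  ident <- as_transition_matrix(diag(8), 1:8, default_legend()$names)
  out <- simulate_landuse(lu, class_areas(lu), flat_atlas(lu, 1:8), ident,
                          config = ca_config(seed = 2))
  expect_identical(out$values, lu$values)
  expect_equal(kappa(out, lu), 1)
})

test_that("allocation meets demand, clusters growth, and is deterministic", {
  lu <- generate_landscape(c(100, 100), seed = 32, autocorr = 4)
  tm <- landhab:::fixture_true_tm()
  at <- flat_atlas(lu, 1:8, seed = 33)
  dem <- class_areas(lu)
  extra <- 0.2 * dem$areas[["urban"]]
  dem$areas[["urban"]] <- dem$areas[["urban"]] + extra
  dem$areas[["farmland"]] <- dem$areas[["farmland"]] - extra
  cfg <- ca_config(seed = 34)
  out <- simulate_landuse(lu, dem, at, tm, config = cfg)
  # demand satisfied within tolerance, cell count conserved
  got <- class_areas(out)$areas[["urban"]]
  expect_lte(abs(got - dem$areas[["urban"]]), 0.005 * dem$areas[["urban"]])
  expect_identical(sum(!is.na(out$values)), sum(!is.na(lu$values)))
  # new urban clusters near existing urban: mean distance below the
  # random-allocation baseline (mean over all eligible donor cells)
  d_old <- distance_to_classes(lu, 5L)$values
  new_urban <- which(out$values == 5L & lu$values != 5L)
  eligible <- which(lu$values %in% which(tm$probabilities[, 5] > 0) &
                    lu$values != 5L)
  expect_lt(mean(d_old[new_urban]), mean(d_old[eligible]))
  # converted cells are more suitable than unconverted eligible cells
  suit <- at$layers[["5"]]$values
  expect_gt(mean(suit[new_urban]), mean(suit[setdiff(eligible, new_urban)]))
  # determinism
  out2 <- simulate_landuse(lu, dem, at, tm, config = cfg)
  expect_identical(out$values, out2$values)
})

test_that("forbidden transitions never occur", {
  lu <- generate_landscape(c(60, 60), seed = 35, autocorr = 3)
  tm <- landhab:::fixture_true_tm()
  at <- flat_atlas(lu, 1:8, seed = 36)
  dem <- class_areas(lu)
  extra <- 0.3 * dem$areas[["urban"]]
  dem$areas[["urban"]] <- dem$areas[["urban"]] + extra
  dem$areas[["farmland"]] <- dem$areas[["farmland"]] - extra - 5
  dem$areas[["grassland"]] <- dem$areas[["grassland"]] + 10
  dem$areas[["water"]] <- dem$areas[["water"]] - 5
  sc <- scenario_config("no-fill", forbidden = list(c("water", "urban")))
  out <- simulate_landuse(lu, dem, at, tm, sc, ca_config(seed = 37))
  expect_identical(sum(lu$values == 4L & out$values == 5L), 0L)
})

test_that("infeasible demands name the blocked class", {
  lu <- generate_landscape(c(40, 40), seed = 38, autocorr = 3)
  at <- flat_atlas(lu, 1:8, seed = 39)
  ident <- as_transition_matrix(diag(8), 1:8, default_legend()$names)
  dem <- class_areas(lu)
  dem$areas[["urban"]] <- dem$areas[["urban"]] + 50
  dem$areas[["farmland"]] <- dem$areas[["farmland"]] - 50
  # identity rules allow no conversion at all
  expect_error(simulate_landuse(lu, dem, at, ident, config = ca_config(seed = 40)),
               "infeasible.*urban")
})
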