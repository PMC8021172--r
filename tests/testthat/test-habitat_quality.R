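test_that("packaged parameter tables carry the published values", {
  th <- default_threats()
  tab <- do.call(rbind, lapply(th, function(t)
    data.frame(name = t$name, d = t$d_rmax, w = t$weight, decay = t$decay)))
  expect_equal(tab$d, c(6, 10, 8, 12))
  expect_equal(tab$w, c(0.6, 0.9, 0.7, 1))
  expect_equal(tab$decay, c("exponential", "exponential", "exponential",
                            "linear"))
  expect_equal(sum(tab$w), 3.2)
  sens <- default_sensitivity()
  expect_equal(unname(sens$habitat),
               c(0.3, 1, 0.6, 0.8, 0, 0, 0, 0.2))
  expect_equal(unname(sens$sensitivity["woodland", ]),
               c(0.7, 0.9, 0.8, 0.9))
  # zero-suitability built classes have zero sensitivity everywhere
  for (cl in c("urban", "rural_residential", "industrial_traffic")) {
    expect_equal(unname(sens$sensitivity[cl, ]), rep(0, 4))
  }
  bad <- data.frame(landuse = "urban", habitat = 0, farmland = 0.5)
  expect_error(sensitivity_table(bad), "zero habitat suitability")
})

test_that("threat source grids mark exactly the emitting classes", {
  lu <- generate_landscape(c(30, 30), seed = 51, autocorr = 2)
  th <- default_threats()
  urban_th <- th[[2]]
  src <- threat_sources(lu, urban_th)
  expect_equal(sum(src$values, na.rm = TRUE), sum(lu$values == 5L))
  no_urban <- make_lu(matrix(1L, 5, 5))
  expect_equal(threat_sources(no_urban, urban_th)$values, matrix(0, 5, 5))
  expect_equal(threat_sources(no_urban, th[[1]])$values, matrix(1, 5, 5))
})

test_that("decay kernels follow their closed forms", {
  lin <- threat_spec("industrial_traffic", 7L, 12, 1, "linear")
  expt <- threat_spec("farmland", 1L, 6, 0.6, "exponential")
  expect_equal(decay_weight(0, lin), 1)
  expect_equal(decay_weight(0, expt), 1)
  expect_equal(decay_weight(12, lin), 0)
  expect_equal(decay_weight(6, lin), 0.5)
  expect_equal(decay_weight(6, expt), exp(-2.99), tolerance = 1e-12)
  expect_equal(decay_weight(6, expt), 0.0503, tolerance = 1e-3)
  expect_equal(decay_weight(7, expt), 0) # truncated beyond d_rmax
  d <- seq(0, 15, by = 0.5)
  expect_true(all(diff(decay_weight(d, lin)) <= 0))
  expect_true(all(diff(decay_weight(d, expt)) <= 0))
  expect_error(decay_weight(-1, lin), ">= 0")
})

test_that("degradation matches the literal double-sum on a hand fixture", {
  m <- matrix(2L, 5, 5) # woodland everywhere
  m[3, 3] <- 5L         # one urban source
  lu <- make_lu(m)
  th <- default_threats()
  sens <- default_sensitivity()
  D <- degradation(lu, th, sens)
  expect_equal(D$values, brute_degradation(lu, th, sens), tolerance = 1e-12)
  # the urban cell itself is insensitive to every threat -> D = 0 there
  expect_equal(D$values[3, 3], 0)
  # no sources at all -> identically zero
  lw <- make_lu(matrix(2L, 5, 5))
  expect_equal(degradation(lw, list(th[[2]]), sens)$values, matrix(0, 5, 5))
})

test_that("degradation is weight-scale invariant, local, and monotone", {
  lu <- generate_landscape(c(40, 40), seed = 52, autocorr = 3)
  th <- default_threats()
  sens <- default_sensitivity()
  D1 <- degradation(lu, th, sens)
  th10 <- lapply(th, function(t) { t$weight <- t$weight * 10; t })
  expect_equal(degradation(lu, th10, sens)$values, D1$values,
               tolerance = 1e-12)
  # adding a source farther than every d_rmax leaves a cell unchanged
  m <- matrix(2L, 40, 40)
  luw <- make_lu(m)
  m2 <- m; m2[40, 40] <- 5L # ~ 39*sqrt(2) = 55 km from cell (1,1)
  luw2 <- make_lu(m2)
  D_far <- degradation(luw2, th, sens)
  expect_equal(D_far$values[1, 1], 0)
  # converting a cell to a source class never decreases D anywhere
  m3 <- lu$values
  cand <- which(m3 == 2L)[1]
  m3[cand] <- 5L
  D2 <- degradation(make_lu(m3), th, sens)
  base <- D1$values; base[cand] <- D2$values[cand] # cell changed class
  expect_true(all(D2$values - base >= -1e-12, na.rm = TRUE))
})

test_that("half-saturation constant is half the maximum degradation", {
  D <- cont_grid(matrix(c(0.1, 0.8, 0.3, 0), 2, 2))
  expect_equal(half_saturation(D), 0.4)
  expect_warning(k0 <- half_saturation(cont_grid(matrix(0, 2, 2))),
                 "falling back")
  expect_equal(k0, 0.5)
})

test_that("quality transform hits its analytic anchor points", {
  sens <- default_sensitivity()
  # row 1: woodland with D = 0; row 2: woodland with D = k; urban anywhere
  m <- matrix(c(2L, 2L, 5L, 2L), 2, 2)
  lu <- make_lu(m)
  Dv <- matrix(c(0, 0.7, 0.7, 1.4), 2, 2)
  D <- cont_grid(Dv, 1000, lu$origin)
  Q <- habitat_quality(D, lu, sens, k = 0.7, z = 2.5)
  expect_equal(Q$values[1, 1], 1)        # H = 1, D = 0
  expect_equal(Q$values[2, 1], 0.5)      # H = 1, D = k -> H/2
  expect_equal(Q$values[1, 2], 0)        # urban: H = 0 regardless of D
  expect_equal(Q$values[2, 2], 1 * 0.7^2.5 / (1.4^2.5 + 0.7^2.5))
  expect_true(all(Q$values >= 0 & Q$values <= 1))
  expect_error(habitat_quality(D, lu, sens, k = 0), "k must be > 0")
})

test_that("quality is bounded by suitability and decreasing in degradation", {
  lu <- generate_landscape(c(40, 40), seed = 53, autocorr = 3)
  sens <- default_sensitivity()
  D <- degradation(lu, default_threats(), sens)
  k <- half_saturation(D)
  Q <- habitat_quality(D, lu, sens, k)
  H <- sens$habitat[landhab:::legend_name(lu$legend, lu$values)]
  expect_true(all(Q$values <= matrix(H, 40, 40) + 1e-12, na.rm = TRUE))
  expect_true(all(Q$values >= 0, na.rm = TRUE))
  # doubling D never increases Q
  Q2 <- habitat_quality(cont_grid(2 * D$values, 1000, D$origin), lu, sens, k)
  expect_true(all(Q2$values <= Q$values + 1e-12, na.rm = TRUE))
})

test_that("five-grade classification uses the printed partition", {
  vals <- matrix(c(0.3662, 0.85, 1.0, 0, 0.2, 0.4, 0.6, 0.8, 0.199), 3, 3)
  Q <- cont_grid(vals)
  g <- grade(Q)
  lab <- attr(g, "labels")
  expect_equal(lab[g$values[1, 1]], "IV") # 0.3662
  expect_equal(lab[g$values[2, 1]], "I")  # 0.85
  expect_equal(lab[g$values[3, 1]], "I")  # 1.0, closed top bin
  expect_equal(lab[g$values[1, 2]], "V")  # 0
  expect_equal(lab[g$values[2, 2]], "IV") # 0.2 lower-inclusive
  expect_equal(lab[g$values[3, 2]], "III")
  expect_equal(lab[g$values[1, 3]], "II")
  expect_equal(lab[g$values[2, 3]], "I")
  expect_equal(lab[g$values[3, 3]], "V")
  expect_error(grade(cont_grid(matrix(1.2))), "\\[0, 1\\]")
})

test_that("mean quality averages non-nodata cells only", {
  expect_equal(mean_quality(cont_grid(matrix(0.5, 3, 3))), 0.5)
  expect_equal(mean_quality(cont_grid(matrix(c(0, 1, 0, 1), 2, 2))), 0.5)
  expect_equal(mean_quality(cont_grid(matrix(c(0.4, NA), 1, 2))), 0.4)
  expect_error(mean_quality(cont_grid(matrix(NA_real_, 1, 1))), "empty")
})
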