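test_that("ascii grid round-trip preserves values, metadata and legend", {
  dir <- withr::local_tempdir()
  m <- matrix(c(1L, 2L, 1L, NA, 2L, 1L, 1L, 1L, 2L), 3, 3)
  lu <- make_lu(m, cell = 500, legend = legend2())
  p <- file.path(dir, "toy.asc")
  write_grid(lu, p)
  back <- read_grid(p, "categorical")
  expect_identical(back$values, lu$values)
  expect_equal(back$cell_size, 500)
  expect_equal(back$origin, lu$origin)
  expect_identical(back$legend$names, c("farmland", "urban"))
  expect_identical(sum(is.na(back$values)), 1L)

  g <- cont_grid(matrix(c(0.25, -1.5, pi, NA), 2, 2), 1000, c(10, 20))
  pc <- file.path(dir, "cont.asc")
  write_grid(g, pc)
  gb <- read_grid(pc, "continuous")
  expect_equal(gb$values, g$values, tolerance = 1e-12)
})

test_that("read_grid rejects broken inputs", {
  dir <- withr::local_tempdir()
  expect_error(read_grid(file.path(dir, "nope.asc")), "not found")
  p <- file.path(dir, "frac.asc")
  write_grid(cont_grid(matrix(c(1, 2.5, 3, 4), 2, 2)), p)
  expect_error(read_grid(p, "categorical"), "non-integer")
  bad <- file.path(dir, "bad.asc")
  writeLines(c("this is", "not a", "raster", "at", "all", "x", "1 2"), bad)
  expect_error(read_grid(bad), "format")
})

test_that("reclassify maps codes, conserves cells, rejects gaps", {
  big <- class_legend(1:25, paste0("class_", 1:25), builtup = character())
  set.seed(42)
  m <- matrix(sample(1:25, 100, replace = TRUE), 10, 10)
  m[1, 1] <- NA
  lu <- make_lu(m, legend = big)
  mapping <- setNames(((1:25 - 1) %% 8) + 1, 1:25)
  out <- reclassify(lu, mapping)
  expect_lte(length(unique(out$values[!is.na(out$values)])), 8L)
  expect_identical(sum(!is.na(out$values)), sum(!is.na(lu$values)))
  expect_true(is.na(out$values[1, 1]))

  ident <- setNames(1:25, 1:25)
  expect_identical(reclassify(lu, ident)$values, lu$values)

  lu2 <- make_lu(matrix(c(1L, 2L, 1L, 2L), 2, 2), legend = legend2())
  merged <- reclassify(lu2, c("1" = 1, "2" = 1))
  expect_identical(unique(as.vector(merged$values)), 1L)
  expect_error(reclassify(lu2, c("1" = 1)), "cover.*2")
})

test_that("distance transform matches definition on hand cases", {
  m <- matrix(1L, 5, 5)
  m[3, 3] <- 5L
  lu <- make_lu(m)
  d <- distance_to_classes(lu, 5)
  expect_equal(d$values[3, 3], 0)
  expect_equal(d$values[3, 4], 1000)
  expect_equal(d$values[2, 2], 1000 * sqrt(2), tolerance = 1e-12)
  expect_error(distance_to_classes(lu, 8), "no source")
})

test_that("distance transform equals brute-force oracle on random grids", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(sample(1:8, 20 * 17, replace = TRUE, prob = c(8, rep(1, 7))),
                20, 17)
    m[sample(length(m), 10)] <- NA
    lu <- make_lu(m)
    if (!any(m == 5, na.rm = TRUE)) m[1, 1] <- 5L
    d <- distance_to_classes(lu, c(5L, 7L))
    expect_equal(d$values, brute_distance(lu, c(5L, 7L)), tolerance = 1e-9)
  }
})

test_that("alignment check names the offending property", {
  a <- make_lu(matrix(1L, 4, 4))
  expect_silent(assert_aligned(a, a))
  b <- make_lu(matrix(1L, 4, 4), cell = 500)
  expect_error(assert_aligned(a, b), "cell_size")
  d <- make_lu(matrix(1L, 5, 4))
  expect_error(assert_aligned(a, d), "shape")
  e <- a; e$origin <- c(1, 2)
  expect_error(assert_aligned(a, e), "origin")
})

test_that("built-up aggregate is exactly its three member classes", {
  leg <- default_legend()
  expect_setequal(builtup_codes(leg), c(5L, 6L, 7L))
  expect_setequal(leg$builtup,
                  c("urban", "rural_residential", "industrial_traffic"))
})

test_that("driver stacks harmonise nodata masks", {
  a <- cont_grid(matrix(c(1, NA, 3, 4), 2, 2))
  b <- cont_grid(matrix(c(1, 2, NA, 4), 2, 2))
  st <- driver_stack(list(x = a, y = b))
  expect_identical(is.na(st$x$values), is.na(st$y$values))
  expect_identical(sum(is.na(st$x$values)), 2L)
})
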