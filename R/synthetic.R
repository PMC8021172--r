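#' Generate a spatially clustered categorical landscape
#'
#' Draws a Gaussian white-noise field, smooths it with a Gaussian kernel
#' whose standard deviation is the requested autocorrelation scale, and
#' assigns classes by rank thresholds so the realised class fractions
#' match the request exactly (up to whole-cell rounding). An
#' autocorrelation scale of 0 yields spatially independent labels. The
#' default composition mirrors a farmland-dominated river-basin
#' landscape: ~68% farmland, dotted rural settlement (~11%), sparse urban
#' and industrial land, clustered woodland/grassland/water.
#'
#' @param shape integer (rows, cols).
#' @param fractions named numeric vector of class fractions over the
#'   legend names, summing to 1.
#' @param cell_size cell edge in metres (default 1000).
#' @param autocorr autocorrelation scale in cells (Gaussian sd; >= 0).
#' @param seed integer seed; same seed, same landscape.
#' @param legend a [class_legend()] naming the classes.
#' @return a [land_grid()].
#' @export
generate_landscape <- function(shape = c(100, 100),
                               fractions = c(farmland = 0.68, woodland = 0.07,
                                             grassland = 0.05, water = 0.04,
                                             urban = 0.03,
                                             rural_residential = 0.11,
                                             industrial_traffic = 0.01,
                                             barren = 0.01),
                               cell_size = 1000, autocorr = 5, seed = NULL,
                               legend = default_legend()) {
  if (any(fractions < 0)) stop("fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (autocorr < 0) stop("autocorrelation scale must be >= 0")
  codes <- legend_code(legend, names(fractions))
  nr <- shape[1]; nc <- shape[2]
  field <- with_seed(seed, {
    f <- matrix(stats::rnorm(nr * nc), nr, nc)
    if (autocorr > 0) {
      r <- ceiling(3 * autocorr)
      k1 <- stats::dnorm(-r:r, sd = autocorr)
      k1 <- k1 / sum(k1)
      f <- conv2(f, matrix(k1, nrow = 1))
      f <- conv2(f, matrix(k1, ncol = 1))
    }
    # deterministic jitter breaks rank ties without altering the field shape
    f + stats::runif(nr * nc) * 1e-9
  })
  n <- nr * nc
  counts <- round_preserve_sum(fractions * n, total = n)
  v <- integer(n)
  ord <- order(field)
  stops <- cumsum(counts)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  for (i in seq_along(codes)) {
    if (counts[i] > 0) v[ord[starts[i]:stops[i]]] <- codes[i]
  }
  land_grid(matrix(v, nr, nc), cell_size, c(0, nr * cell_size), legend)
}

#' Generate driver layers with known logistic structure
#'
#' Builds continuous driver layers such that the log-odds of each class's
#' presence on the given landscape follows the supplied logistic models
#' exactly, enabling coefficient-recovery tests. For each model the
#' drivers it references are drawn as conditional Gaussians (unit
#' within-class standard deviation) whose class-conditional means are
#' solved from the target coefficients and the class prevalence; by the
#' Gaussian discriminant / logistic duality the implied logistic model
#' has precisely the requested intercept and slopes. Optional independent
#' measurement noise (`noise_sd`) attenuates the recoverable
#' coefficients, emulating noisy covariates. Each driver name may be
#' referenced by exactly one model.
#'
#' @param lu a [land_grid()] fixing presence/absence per class.
#' @param true_models list of [logistic_model()] ground truths.
#' @param noise_sd standard deviation of additional measurement noise
#'   added to each driver (default 0: coefficients hold exactly).
#' @param seed integer seed.
#' @return a [driver_stack()].
#' @export
generate_drivers <- function(lu, true_models, noise_sd = 0, seed = NULL) {
  all_names <- unlist(lapply(true_models, function(m) names(m$coefficients)))
  if (anyDuplicated(all_names))
    stop("inconsistent driver names: driver(s) shared between models: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  nr <- nrow(lu$values); nc <- ncol(lu$values)
  mask <- is.na(lu$values)
  layers <- list()
  with_seed(seed, {
    for (m in true_models) {
      pres <- !mask & lu$values == m$class_code
      if (!any(pres)) stop("model class ", m$class_code, " absent from landscape")
      p1 <- mean(pres[!mask])
      beta <- m$coefficients
      nz <- which(beta != 0)
      if (!length(nz)) stop("model for class ", m$class_code,
                            " needs a non-zero coefficient")
      # conditional means: delta_k = beta_k (unit sd); midpoints chosen so
      # the implied intercept matches the requested one
      need <- stats::qlogis(p1) - m$intercept
      mid <- setNames(rep(0, length(beta)), names(beta))
      mid[nz] <- (need / length(nz)) / beta[nz]
      for (k in seq_along(beta)) {
        mu <- ifelse(pres, mid[k] + beta[k] / 2, mid[k] - beta[k] / 2)
        x <- mu + stats::rnorm(nr * nc)
        if (noise_sd > 0) x <- x + stats::rnorm(nr * nc, sd = noise_sd)
        x[mask] <- NA_real_
        layers[[names(beta)[k]]] <- cont_grid(matrix(x, nr, nc),
                                              lu$cell_size, lu$origin)
      }
    }
  })
  driver_stack(layers)
}

#' Evolve a landscape one step under a known transition matrix
#'
#' Resamples every cell's class independently from its row of the
#' transition matrix (cellwise i.i.d., no spatial process), so that
#' empirical transition frequencies converge to the matrix with map size.
#' This makes Markov estimation exactly identifiable; spatial structure
#' in projections is the CA engine's responsibility, not the fixture's.
#'
#' @param lu a [land_grid()].
#' @param tm a [transition_matrix()] (or bare row-stochastic matrix whose
#'   rows/cols follow the legend codes).
#' @param seed integer seed.
#' @return the evolved [land_grid()].
#' @export
evolve_landscape <- function(lu, tm, seed = NULL) {
  codes <- lu$legend$codes
  P <- if (inherits(tm, "transition_matrix")) {
    if (!identical(tm$classes, codes)) stop("transition classes must match legend")
    tm$probabilities
  } else as.matrix(tm)
  if (nrow(P) != length(codes) || ncol(P) != length(codes))
    stop("transition matrix must be ", length(codes), " x ", length(codes))
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("non-stochastic matrix: rows must be >= 0 and sum to 1")
  v0 <- lu$values
  v <- v0
  with_seed(seed, {
    for (i in seq_along(codes)) {
      idx <- which(!is.na(v0) & v0 == codes[i])
      if (length(idx))
        v[idx] <- sample(codes, length(idx), replace = TRUE, prob = P[i, ])
    }
  })
  land_grid(v, lu$cell_size, lu$origin, lu$legend)
}

# plausible decadal transition matrix for the synthetic study landscape:
# built-up classes absorb farmland and grassland; every class pair keeps a
# small positive flow so any policy-driven conversion stays reachable
fixture_true_tm <- function(legend = default_legend()) {
  n <- length(legend$codes)
  P <- matrix(0, n, n, dimnames = list(legend$names, legend$names))
  set_p <- function(from, to, p) P[from, to] <<- p
  set_p("farmland", c("urban", "rural_residential", "industrial_traffic",
                      "woodland", "grassland", "water", "barren"),
        c(0.012, 0.008, 0.004, 0.003, 0.002, 0.002, 0.0005))
  set_p("woodland", c("farmland", "grassland", "urban", "rural_residential",
                      "industrial_traffic", "water", "barren"),
        c(0.006, 0.004, 0.002, 0.001, 0.001, 0.0005, 0.0005))
  set_p("grassland", c("farmland", "woodland", "urban", "rural_residential",
                       "industrial_traffic", "water", "barren"),
        c(0.010, 0.004, 0.004, 0.002, 0.001, 0.002, 0.0005))
  set_p("water", c("farmland", "woodland", "grassland", "urban",
                   "rural_residential", "industrial_traffic", "barren"),
        c(0.004, 0.0005, 0.001, 0.001, 0.0005, 0.001, 0.002))
  set_p("urban", c("farmland", "woodland", "grassland", "water",
                   "rural_residential", "industrial_traffic", "barren"),
        c(0.001, 0.0005, 0.0005, 0.0005, 0.001, 0.004, 0.0002))
  set_p("rural_residential", c("farmland", "woodland", "grassland", "water",
                               "urban", "industrial_traffic", "barren"),
        c(0.010, 0.002, 0.002, 0.001, 0.010, 0.002, 0.0005))
  set_p("industrial_traffic", c("farmland", "woodland", "grassland", "water",
                                "urban", "rural_residential", "barren"),
        c(0.002, 0.002, 0.001, 0.001, 0.006, 0.001, 0.0002))
  set_p("barren", c("farmland", "woodland", "grassland", "water", "urban",
                    "rural_residential", "industrial_traffic"),
        c(0.020, 0.020, 0.010, 0.005, 0.002, 0.002, 0.001))
  diag(P) <- 1 - rowSums(P)
  as_transition_matrix(P, legend$codes, legend$names, interval = 10)
}

fixture_true_models <- function(legend = default_legend()) {
  lapply(legend$codes, function(code) {
    nm <- legend_name(legend, code)
    logistic_model(code, intercept = -2,
                   coefficients = setNames(2.5, paste0("drv_", nm)))
  })
}

#' Write a complete synthetic pipeline fixture
#'
#' Generates and writes a small, fully self-consistent input set for
#' [run_pipeline()]: two dated 100 x 100 landscapes (the second evolved
#' from the first under a known decadal transition matrix with growing
#' built-up classes), one informative driver layer per class, the
#' packaged threat and sensitivity tables, the three policy scenario
#' YAMLs and a pipeline config. Deterministic per seed.
#'
#' @param name fixture identifier; `"huaihe-mini"` is the only packaged
#'   fixture.
#' @param dir output directory (created if needed).
#' @param seed integer seed (default 1103).
#' @param shape landscape dimensions (default 100 x 100).
#' @return invisibly, the path of the written pipeline config YAML.
#' @export
make_fixture <- function(name = "huaihe-mini", dir = tempfile("fixture"),
                         seed = 1103L, shape = c(100L, 100L)) {
  if (!identical(name, "huaihe-mini")) stop("unknown fixture id: ", name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  legend <- default_legend()
  lu0 <- generate_landscape(shape, seed = seed, legend = legend, autocorr = 4)
  tm_true <- fixture_true_tm(legend)
  lu1 <- evolve_landscape(lu0, tm_true, seed = seed + 1L)
  drivers <- generate_drivers(lu1, fixture_true_models(legend),
                              seed = seed + 2L)
  write_grid(lu0, file.path(dir, "landuse_t0.asc"))
  write_grid(lu1, file.path(dir, "landuse_t1.asc"))
  write_transition_matrix(tm_true, file.path(dir, "transition_rules.csv"))
  drv_paths <- list()
  for (nm in names(drivers)) {
    p <- paste0(nm, ".asc")
    write_grid(drivers[[nm]], file.path(dir, p))
    drv_paths[[nm]] <- p
  }
  file.copy(system.file("extdata", "threats_default.csv", package = "landhab"),
            file.path(dir, "threats.csv"), overwrite = TRUE)
  file.copy(system.file("extdata", "sensitivity_default.csv",
                        package = "landhab"),
            file.path(dir, "sensitivity.csv"), overwrite = TRUE)
  scen_files <- c("fast_urban_growth.yml", "farmland_conservation.yml",
                  "ecological_conservation.yml")
  for (f in scen_files) {
    file.copy(system.file("extdata", f, package = "landhab"),
              file.path(dir, f), overwrite = TRUE)
  }
  config <- list(
    inputs = list(landuse_t0 = "landuse_t0.asc",
                  landuse_t1 = "landuse_t1.asc",
                  transition_matrix = "transition_rules.csv",
                  drivers = drv_paths,
                  threats = "threats.csv",
                  sensitivity = "sensitivity.csv",
                  scenarios = as.list(scen_files)),
    parameters = list(interval_years = 10, horizon_years = 10,
                      seed = as.integer(seed), z = 2.5),
    output = list(dir = "output"))
  cfg_path <- file.path(dir, "config.yml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
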