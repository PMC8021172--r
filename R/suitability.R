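#' Specify a logistic occurrence model
#'
#' Container for a per-class logistic model
#' `logit P = intercept + sum_k beta_k x_k`, either fitted by
#' [fit_logistic()] or supplied as ground truth for synthetic experiments.
#'
#' @param class_code integer land-use class code the model describes.
#' @param intercept intercept on the raw driver scale.
#' @param coefficients named numeric vector of raw-scale coefficients,
#'   one per driver layer.
#' @param scaled optional list with `intercept` and `coefficients` on the
#'   standardised (z-score) driver scale.
#' @param z_values optional named Wald z statistics.
#' @param n number of cells used in fitting.
#' @return an object of class `logistic_model`.
#' @export
logistic_model <- function(class_code, intercept, coefficients,
                           scaled = NULL, z_values = NULL, n = NA_integer_) {
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    stop("coefficients must be named by driver")
  structure(list(class_code = as.integer(class_code),
                 intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 scaled = scaled, z_values = z_values, n = n),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("logistic_model for class %d (n = %s)\n", x$class_code,
              format(x$n)))
  print(round(c("(intercept)" = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Fit a logistic occurrence model for one land-use class
#'
#' Maximum-likelihood logistic regression of the binary presence indicator
#' of `target_class` on the driver layers. Drivers are standardised
#' (z-scored) before fitting for numerical stability; coefficients are
#' reported on both the standardised and the raw scale. A seeded random
#' subsample of cells can be used for speed; the default uses every
#' non-nodata cell. No driver screening is applied: all supplied drivers
#' enter the model and Wald z statistics are reported so users can judge
#' importance themselves.
#'
#' @param lu a [land_grid()].
#' @param target_class class code whose presence is modelled.
#' @param drivers a [driver_stack()] aligned with `lu`.
#' @param sample_frac fraction of usable cells to fit on, in (0, 1].
#' @param seed integer seed controlling the subsample (determinism).
#' @return a [logistic_model()].
#' @export
fit_logistic <- function(lu, target_class, drivers, sample_frac = 1,
                         seed = NULL) {
  if (!inherits(drivers, "driver_stack")) drivers <- driver_stack(drivers)
  assert_aligned(c(list(lu), unclass(drivers)))
  ok <- !is.na(lu$values)
  for (g in drivers) ok <- ok & !is.na(g$values)
  y <- as.integer(lu$values[ok] == as.integer(target_class))
  X <- vapply(drivers, function(g) g$values[ok], numeric(sum(ok)))
  colnames(X) <- names(drivers)
  if (sample_frac <= 0 || sample_frac > 1) stop("sample_frac must be in (0, 1]")
  if (sample_frac < 1) {
    keep <- with_seed(seed, sample.int(length(y), ceiling(sample_frac * length(y))))
    y <- y[keep]; X <- X[keep, , drop = FALSE]
  }
  if (sum(y) == 0L) stop("target class ", target_class, " absent (no presences)")
  if (all(y == 1L)) stop("target class ", target_class,
                         " covers all cells (no absences)")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0))
    stop("constant driver: ", paste(colnames(X)[sdv == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  qrz <- qr(cbind(1, Z))
  if (qrz$rank < ncol(Z) + 1L) {
    aliased <- colnames(Z)[setdiff(seq_len(ncol(Z)),
                                   qrz$pivot[seq_len(qrz$rank)] - 1L)]
    stop("collinear driver(s): ", paste(aliased, collapse = ", "))
  }
  dat <- data.frame(y = y, Z)
  fit <- stats::glm(y ~ ., data = dat, family = stats::binomial())
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("collinear driver(s): ",
         paste(names(co)[is.na(co)], collapse = ", "))
  b_scaled <- co[-1]
  names(b_scaled) <- colnames(X)
  b_raw <- b_scaled / sdv
  b0_raw <- unname(co[1]) - sum(b_scaled * mu / sdv)
  zv <- summary(fit)$coefficients[-1, "z value"]
  names(zv) <- colnames(X)
  logistic_model(target_class, b0_raw, b_raw,
                 scaled = list(intercept = unname(co[1]),
                               coefficients = b_scaled),
                 z_values = zv, n = length(y))
}

#' Predict a suitability surface from a logistic model
#'
#' Evaluates the inverse-logit of the model's linear predictor on every
#' cell of the driver stack; probabilities lie strictly in (0, 1) and
#' nodata propagates.
#'
#' @param model a [logistic_model()].
#' @param drivers a [driver_stack()] containing every driver the model
#'   references.
#' @return a [cont_grid()] of occurrence probabilities.
#' @export
predict_suitability <- function(model, drivers) {
  if (!inherits(drivers, "driver_stack")) drivers <- driver_stack(drivers)
  need <- names(model$coefficients)
  missing <- setdiff(need, names(drivers))
  if (length(missing))
    stop("missing driver layer(s): ", paste(missing, collapse = ", "))
  ref <- drivers[[1]]
  eta <- matrix(model$intercept, nrow(ref$values), ncol(ref$values))
  for (nm in need) eta <- eta + model$coefficients[[nm]] * drivers[[nm]]$values
  cont_grid(stats::plogis(eta), ref$cell_size, ref$origin)
}

#' Assemble a per-class suitability atlas
#'
#' Fits one logistic model per class present on the land-use grid and
#' predicts its occurrence-probability layer, collecting the layers into a
#' suitability atlas used by the cellular-automata allocation step. Fit
#' failures are collected across classes and reported together.
#'
#' @inheritParams fit_logistic
#' @param classes class codes to model (default: all classes present).
#' @return a [suitability_atlas()].
#' @export
build_atlas <- function(lu, drivers, classes = NULL, sample_frac = 1,
                        seed = NULL) {
  if (!inherits(drivers, "driver_stack")) drivers <- driver_stack(drivers)
  present <- sort(unique(lu$values[!is.na(lu$values)]))
  classes <- classes %||% present
  if (length(classes) < 2L) stop("need >= 2 classes to build an atlas")
  models <- list(); layers <- list(); failures <- character()
  for (k in seq_along(classes)) {
    cls <- classes[k]
    res <- tryCatch(
      fit_logistic(lu, cls, drivers, sample_frac = sample_frac,
                   seed = if (is.null(seed)) NULL else seed + k),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("class ", cls, ": ", conditionMessage(res)))
    } else {
      models[[as.character(cls)]] <- res
      layers[[as.character(cls)]] <- predict_suitability(res, drivers)
    }
  }
  if (length(failures))
    stop("atlas fitting failed:\n  ", paste(failures, collapse = "\n  "))
  suitability_atlas(layers, models)
}

#' Construct a suitability atlas from probability layers
#'
#' Lower-level constructor for an atlas: a named list of aligned
#' probability layers, keyed by class code, optionally with the fitted
#' models as provenance. [build_atlas()] is the usual entry point;
#' constructing an atlas directly is useful for synthetic experiments.
#'
#' @param layers named list of [cont_grid()] probability layers, names =
#'   class codes; all values in `[0, 1]` or `NA`.
#' @param models optional named list of [logistic_model()] provenance.
#' @return an object of class `suitability_atlas`.
#' @export
suitability_atlas <- function(layers, models = NULL) {
  if (is.null(names(layers))) stop("atlas layers must be named by class code")
  if (length(layers) >= 2L) assert_aligned(layers)
  for (nm in names(layers)) {
    v <- layers[[nm]]$values
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("atlas layer ", nm, " has values outside [0, 1]")
  }
  structure(list(layers = layers, models = models,
                 classes = as.integer(names(layers))),
            class = "suitability_atlas")
}

#' @export
print.suitability_atlas <- function(x, ...) {
  cat(sprintf("suitability_atlas: %d class layers (%s)\n",
              length(x$layers), paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Write an atlas as per-class probability rasters
#'
#' Writes one `suitability_<code>.asc` layer per class into a directory
#' (created if needed), plus the fitted models as YAML when present.
#'
#' @param atlas a [suitability_atlas()].
#' @param dir output directory.
#' @return `dir` invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(atlas$layers)) {
    write_grid(atlas$layers[[nm]],
               file.path(dir, paste0("suitability_", nm, ".asc")))
  }
  if (!is.null(atlas$models))
    write_atlas_models(atlas, file.path(dir, "models.yml"))
  invisible(dir)
}

#' Write atlas models to YAML
#'
#' Serialises class, raw- and standardised-scale coefficients and Wald z
#' statistics for each fitted model.
#'
#' @param atlas a [suitability_atlas()] with models.
#' @param path YAML output path.
#' @return `path` invisibly.
#' @export
write_atlas_models <- function(atlas, path) {
  if (is.null(atlas$models)) stop("atlas carries no fitted models")
  out <- lapply(atlas$models, function(m) {
    list(class_code = m$class_code,
         intercept = m$intercept,
         coefficients = as.list(m$coefficients),
         scaled_intercept = m$scaled$intercept,
         scaled_coefficients = as.list(m$scaled$coefficients),
         z_values = as.list(m$z_values),
         n = m$n)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
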