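#' Threat factor specification
#'
#' A threat is a land-use category that degrades habitat in its
#' surroundings, parameterised by the classes emitting it, a maximum
#' influence distance, a weight and a distance-decay kind. The packaged
#' default set ([default_threats()]) comprises farmland (6 km, weight 0.6,
#' exponential), urban land (10 km, 0.9, exponential), rural residential
#' land (8 km, 0.7, exponential) and industrial/traffic land (12 km,
#' 1.0, linear).
#'
#' @param name threat identifier (a class name by convention).
#' @param source_classes integer codes of the land-use classes emitting
#'   the threat.
#' @param d_rmax maximum influence distance in km (> 0).
#' @param weight relative threat weight (>= 0); weights are normalised to
#'   sum to one inside [degradation()], so only ratios matter.
#' @param decay `"linear"` or `"exponential"`.
#' @return an object of class `threat_spec`.
#' @export
threat_spec <- function(name, source_classes, d_rmax, weight,
                        decay = c("linear", "exponential")) {
  decay <- match.arg(decay)
  if (d_rmax <= 0) stop("d_rmax must be > 0")
  if (weight < 0) stop("weight must be >= 0")
  structure(list(name = name, source_classes = as.integer(source_classes),
                 d_rmax = as.numeric(d_rmax), weight = as.numeric(weight),
                 decay = decay),
            class = "threat_spec")
}

#' Default threat parameter set
#'
#' Reads the packaged threat table (maximum influence distance, weight and
#' decay kind per threat) and resolves source classes against a legend.
#'
#' @param legend legend used to resolve threat names to source codes.
#' @return list of [threat_spec()].
#' @export
default_threats <- function(legend = default_legend()) {
  read_threats(system.file("extdata", "threats_default.csv",
                           package = "landhab"), legend)
}

#' Read a threat table from CSV
#'
#' Expected columns: `threat`, `max_dist_km`, `weight`, `decay`, and
#' optionally `source_classes` (comma-separated class names; defaults to
#' the threat name itself).
#'
#' @param path CSV path.
#' @param legend legend resolving class names to codes.
#' @return list of [threat_spec()].
#' @export
read_threats <- function(path, legend = default_legend()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    src_names <- if ("source_classes" %in% names(df) &&
                     nzchar(df$source_classes[i]))
      trimws(strsplit(df$source_classes[i], ",")[[1]]) else df$threat[i]
    threat_spec(df$threat[i], legend_code(legend, src_names),
                df$max_dist_km[i], df$weight[i], df$decay[i])
  })
}

#' Habitat suitability and sensitivity table
#'
#' Per land-use class: intrinsic habitat suitability `H_j` in `[0, 1]` and
#' sensitivity `S_jr` in `[0, 1]` to each threat. Classes with zero
#' suitability (the built environment classes in the packaged defaults)
#' must have zero sensitivity to every threat.
#'
#' @param df data frame with columns `landuse`, `habitat`, then one
#'   sensitivity column per threat name.
#' @return an object of class `sensitivity_table`.
#' @export
sensitivity_table <- function(df) {
  if (!all(c("landuse", "habitat") %in% names(df)))
    stop("sensitivity table needs 'landuse' and 'habitat' columns")
  threat_cols <- setdiff(names(df), c("landuse", "habitat"))
  vals <- as.matrix(df[, c("habitat", threat_cols)])
  if (any(vals < 0 | vals > 1, na.rm = TRUE))
    stop("suitability and sensitivity values must lie in [0, 1]")
  zero_h <- df$habitat == 0
  if (any(zero_h) && any(df[zero_h, threat_cols] != 0))
    stop("classes with zero habitat suitability must have zero sensitivities")
  structure(list(landuse = df$landuse,
                 habitat = setNames(df$habitat, df$landuse),
                 sensitivity = `rownames<-`(as.matrix(df[, threat_cols,
                                                         drop = FALSE]),
                                            df$landuse)),
            class = "sensitivity_table")
}

#' Default suitability/sensitivity table
#'
#' @return the packaged [sensitivity_table()] covering the eight analysis
#'   classes and four default threats.
#' @export
default_sensitivity <- function() {
  read_sensitivity(system.file("extdata", "sensitivity_default.csv",
                               package = "landhab"))
}

#' Read a sensitivity table from CSV
#'
#' @param path CSV with columns `landuse`, `habitat`, one column per threat.
#' @return a [sensitivity_table()].
#' @export
read_sensitivity <- function(path) {
  sensitivity_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Binary threat-source grid
#'
#' 1 on cells whose land-use class emits the threat, 0 elsewhere
#' (`NA` on nodata).
#'
#' @param lu a [land_grid()].
#' @param threat a [threat_spec()].
#' @return a [cont_grid()] of 0/1 values.
#' @export
threat_sources <- function(lu, threat) {
  if (!all(threat$source_classes %in% lu$legend$codes))
    stop("unknown source class code(s): ",
         paste(setdiff(threat$source_classes, lu$legend$codes), collapse = ", "))
  out <- matrix(0, nrow(lu$values), ncol(lu$values))
  out[!is.na(lu$values) & lu$values %in% threat$source_classes] <- 1
  out[is.na(lu$values)] <- NA_real_
  cont_grid(out, lu$cell_size, lu$origin)
}

#' Distance-decay impact of a threat
#'
#' Impact of a threat source at distance `d` (km): linear decay
#' `1 - d/d_rmax` clamped to `[0, 1]`; exponential decay
#' `exp(-decay_const * d / d_rmax)` truncated to 0 beyond `d_rmax`, with
#' the conventional constant 2.99 so the impact at the maximum distance
#' is ~0.05. Monotone non-increasing in `d`; impact 1 at `d = 0`.
#'
#' @param d distance(s) in km (>= 0).
#' @param threat a [threat_spec()].
#' @param decay_const exponential rate constant (default 2.99).
#' @return impact value(s) in `[0, 1]`.
#' @export
decay_weight <- function(d, threat, decay_const = 2.99) {
  if (any(d < 0)) stop("distance must be >= 0")
  if (threat$decay == "linear") {
    pmax(1 - d / threat$d_rmax, 0)
  } else {
    ifelse(d > threat$d_rmax, 0, exp(-decay_const * d / threat$d_rmax))
  }
}

# decay kernel over cell offsets for one threat: entry at offset (di, dj)
# is the impact of a source that many cells away; 0 beyond d_rmax.
threat_kernel <- function(threat, cell_size, decay_const = 2.99) {
  dmax_cells <- floor(threat$d_rmax * 1000 / cell_size)
  off <- -dmax_cells:dmax_cells
  dk <- sqrt(outer(off^2, off^2, "+")) * cell_size / 1000 # km
  k <- decay_weight(pmin(dk, threat$d_rmax + 1), threat, decay_const)
  k[dk > threat$d_rmax] <- 0
  k
}

#' Per-cell habitat degradation from threat exposure
#'
#' Accumulates, for every cell `x` of class `j`, the distance-decayed
#' impact of every threat-source cell `y` within the threat's maximum
#' influence distance:
#' `D_x = sum_r sum_y (w_r / sum_r w_r) * r_y * i_r(d_xy) * beta_x * S_jr`,
#' where `r_y` is binary source presence, `i_r` the decay kernel
#' ([decay_weight()]), `beta_x` an optional accessibility grid (default 1
#' everywhere) and `S_jr` the sensitivity of the cell's class to threat
#' `r`. Weights are normalised by their sum, so scaling all weights by a
#' common factor leaves `D` unchanged. Computed by convolving each
#' source mask with its decay kernel; nodata cells emit and receive
#' nothing.
#'
#' @param lu a [land_grid()].
#' @param threats list of [threat_spec()], e.g. [default_threats()].
#' @param sens a [sensitivity_table()] with a column per threat name and a
#'   row per legend class name.
#' @param accessibility optional [cont_grid()] of `beta_x` in `[0, 1]`.
#' @param decay_const exponential kernel constant (default 2.99).
#' @return a `degradation_grid` (a [cont_grid()] subclass, values >= 0).
#' @export
degradation <- function(lu, threats, sens, accessibility = NULL,
                        decay_const = 2.99) {
  legend <- lu$legend
  for (th in threats) {
    if (!th$name %in% colnames(sens$sensitivity))
      stop("sensitivity missing for threat: ", th$name)
  }
  cls_names <- legend_name(legend, legend$codes)
  missing_cls <- setdiff(cls_names, rownames(sens$sensitivity))
  if (length(missing_cls))
    stop("sensitivity missing for class(es): ",
         paste(missing_cls, collapse = ", "))
  if (!is.null(accessibility)) assert_aligned(lu, accessibility)
  w <- vapply(threats, function(th) th$weight, 0)
  wn <- w / sum(w)
  nr <- nrow(lu$values); nc <- ncol(lu$values)
  nod <- is.na(lu$values)
  class_idx <- matrix(match(legend_name(legend, ifelse(nod, legend$codes[1],
                                                       lu$values)),
                            rownames(sens$sensitivity)), nr, nc)
  D <- matrix(0, nr, nc)
  for (t in seq_along(threats)) {
    th <- threats[[t]]
    src <- threat_sources(lu, th)$values
    src[is.na(src)] <- 0
    exposure <- conv2(src, threat_kernel(th, lu$cell_size, decay_const))
    s_map <- matrix(sens$sensitivity[, th$name][class_idx], nr, nc)
    D <- D + wn[t] * exposure * s_map
  }
  if (!is.null(accessibility)) D <- D * accessibility$values
  D[nod] <- NA_real_
  out <- cont_grid(D, lu$cell_size, lu$origin)
  class(out) <- c("degradation_grid", class(out))
  attr(out, "threats") <- vapply(threats, function(th) th$name, "")
  attr(out, "decay_const") <- decay_const
  out
}

#' Half-saturation constant from a degradation grid
#'
#' Half the maximum observed degradation, the conventional choice for the
#' half-saturation constant of the quality transform. When scoring several
#' maps of one study (a baseline and scenario projections), compute `k`
#' once from the baseline and pass it explicitly to [habitat_quality()]
#' so all maps share one transform.
#'
#' @param D a [degradation()] grid.
#' @return `k = max(D) / 2`; falls back to 0.5 with a warning when no
#'   degradation exists anywhere.
#' @export
half_saturation <- function(D) {
  m <- max(D$values, na.rm = TRUE)
  if (m <= 0) {
    warning("no degradation anywhere; falling back to k = 0.5")
    return(0.5)
  }
  m / 2
}

#' Habitat quality from degradation
#'
#' Per-cell habitat quality
#' `Q_x = H_j * k^z / (D_x^z + k^z)`: intrinsic suitability of the cell's
#' class, scaled down by a half-saturation response to degradation. Where
#' `D = 0`, `Q` equals `H_j`; where `D = k`, `Q = H_j / 2`; classes with
#' `H_j = 0` score 0 regardless of exposure.
#'
#' @param D a [degradation()] grid.
#' @param lu the [land_grid()] the degradation was computed on.
#' @param sens the [sensitivity_table()] providing `H_j`.
#' @param k half-saturation constant (> 0), usually [half_saturation()]
#'   of the baseline degradation.
#' @param z normalisation exponent (default 2.5).
#' @return a `habitat_quality_grid` (a [cont_grid()] subclass) with
#'   attributes `k` and `z`.
#' @export
habitat_quality <- function(D, lu, sens, k, z = 2.5) {
  if (k <= 0) stop("k must be > 0")
  if (z <= 0) stop("z must be > 0")
  assert_aligned(D, lu)
  h <- sens$habitat[legend_name(lu$legend, lu$legend$codes)]
  idx <- match(lu$values, lu$legend$codes)
  H <- matrix(h[idx], nrow(lu$values), ncol(lu$values))
  Q <- H * (k^z / (D$values^z + k^z))
  Q[is.na(lu$values)] <- NA_real_
  out <- cont_grid(Q, lu$cell_size, lu$origin)
  class(out) <- c("habitat_quality_grid", class(out))
  attr(out, "k") <- k
  attr(out, "z") <- z
  out
}

GRADE_LABELS <- c("I", "II", "III", "IV", "V")

#' Five-grade classification of habitat quality
#'
#' Equal-interval grading of the quality index: grade V (worst) covers
#' `[0, 0.2)`, IV `[0.2, 0.4)`, III `[0.4, 0.6)`, II `[0.6, 0.8)` and I
#' (best) `[0.8, 1]`. Bins are lower-inclusive with the top bin closed
#' at 1.
#'
#' @param Q a [habitat_quality()] grid (values in `[0, 1]` or `NA`).
#' @return a `grade_map`: integer matrix grid with values 1-5 meaning
#'   grades I-V, labels in `attr(, "labels")`.
#' @export
grade <- function(Q) {
  v <- Q$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("quality values must lie in [0, 1]")
  # findInterval keeps the lower-inclusive bin edges exact (no 0.6/0.2
  # floating-point drift)
  g <- matrix(5L - findInterval(v, c(0.2, 0.4, 0.6, 0.8)),
              nrow(v), ncol(v))
  out <- structure(list(values = g, cell_size = Q$cell_size,
                        origin = Q$origin),
                   class = c("grade_map", "lh_grid"))
  attr(out, "labels") <- GRADE_LABELS
  attr(out, "breaks") <- seq(0, 1, by = 0.2)
  out
}

#' @export
print.grade_map <- function(x, ...) {
  tb <- table(factor(GRADE_LABELS[x$values], levels = GRADE_LABELS))
  cat("grade_map (I best ... V worst):\n")
  print(tb)
  invisible(x)
}

#' Mean habitat quality
#'
#' Arithmetic mean of the quality index over non-nodata cells, the
#' study-level summary statistic used to compare dates and scenarios.
#'
#' @param Q a [habitat_quality()] grid.
#' @return scalar mean.
#' @export
mean_quality <- function(Q) {
  v <- Q$values[!is.na(Q$values)]
  if (!length(v)) stop("empty grid: no non-nodata cells")
  mean(v)
}
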