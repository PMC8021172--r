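#' Per-class area vector
#'
#' Areas (km^2) of each legend class on a land-use grid, the state vector
#' of the Markov chain. Nodata cells are excluded.
#'
#' @param lu a [land_grid()].
#' @param label optional date/scenario label.
#' @return an object of class `class_areas` with elements `classes`
#'   (codes), `names`, `areas` (km^2, named by class name), `label`.
#' @export
class_areas <- function(lu, label = NULL) {
  codes <- lu$legend$codes
  counts <- tabulate(match(lu$values[!is.na(lu$values)], codes),
                     nbins = length(codes))
  areas <- counts * cell_area_km2(lu)
  names(areas) <- lu$legend$names
  structure(list(classes = codes, names = lu$legend$names,
                 areas = areas, label = label),
            class = "class_areas")
}

new_class_areas <- function(classes, names, areas, label = NULL) {
  stopifnot(length(classes) == length(areas))
  if (any(areas < -1e-9)) stop("class areas must be non-negative")
  areas <- pmax(areas, 0)
  names(areas) <- names
  structure(list(classes = as.integer(classes), names = names,
                 areas = areas, label = label),
            class = "class_areas")
}

#' @export
print.class_areas <- function(x, ...) {
  cat("class areas (km^2)", if (!is.null(x$label)) paste0(" [", x$label, "]"),
      ":\n", sep = "")
  print(round(x$areas, 2))
  invisible(x)
}

#' Estimate a land-use transition matrix from two dated maps
#'
#' Cross-tabulates cell pairs between two aligned land-use grids with the
#' same legend. `areas[i, j]` is the area (km^2) moving from class `i` at
#' the start date to class `j` at the end date; `probabilities[i, j]` is
#' the row-normalised transition probability
#' `p_ij = A_ij / sum_j A_ij`. Classes absent at the start date receive an
#' identity row so the matrix stays row-stochastic. Cells that are nodata
#' at either date are excluded.
#'
#' @param lu_t0,lu_t1 aligned [land_grid()]s with identical legends.
#' @param interval interval between the two maps, in years (default 10).
#' @return object of class `transition_matrix` with elements `classes`,
#'   `names`, `areas`, `probabilities`, `interval`.
#' @export
transition_matrix <- function(lu_t0, lu_t1, interval = 10) {
  assert_aligned(lu_t0, lu_t1)
  if (!same_legend(lu_t0$legend, lu_t1$legend))
    stop("legend mismatch between the two maps")
  codes <- lu_t0$legend$codes
  ok <- !is.na(lu_t0$values) & !is.na(lu_t1$values)
  tab <- table(factor(lu_t0$values[ok], levels = codes),
               factor(lu_t1$values[ok], levels = codes))
  areas <- unclass(tab) * cell_area_km2(lu_t0)
  dimnames(areas) <- list(from = lu_t0$legend$names, to = lu_t0$legend$names)
  rs <- rowSums(areas)
  probs <- areas
  for (i in seq_along(codes)) {
    probs[i, ] <- if (rs[i] > 0) areas[i, ] / rs[i] else
      as.numeric(seq_along(codes) == i) # identity row for absent classes
  }
  structure(list(classes = codes, names = lu_t0$legend$names,
                 areas = areas, probabilities = probs,
                 interval = as.numeric(interval)),
            class = "transition_matrix")
}

#' Build a transition matrix from a probability matrix
#'
#' Wraps a user-supplied row-stochastic matrix (e.g. a known ground truth
#' for synthetic experiments) in the `transition_matrix` structure.
#'
#' @param probs square row-stochastic matrix; row/column order follows
#'   `classes`.
#' @param classes integer class codes.
#' @param names class names (default `class_<code>` or legend names).
#' @param interval interval in years.
#' @param areas optional area matrix (km^2).
#' @return a `transition_matrix`.
#' @export
as_transition_matrix <- function(probs, classes, names = NULL,
                                 interval = 10, areas = NULL) {
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs)) stop("probability matrix must be square")
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-8))
    stop("probability matrix must be row-stochastic")
  names <- names %||% paste0("class_", classes)
  dimnames(probs) <- list(from = names, to = names)
  structure(list(classes = as.integer(classes), names = names,
                 areas = areas, probabilities = probs,
                 interval = as.numeric(interval)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d classes, %g-year interval\n",
              length(x$classes), x$interval))
  print(round(x$probabilities, 4))
  invisible(x)
}

#' Project class areas forward under a transition matrix
#'
#' Applies the estimated transition step `steps` times: with row-stochastic
#' `P` (rows = origin class) and `a` the vector of origin areas, the
#' destination areas after one step are `t(P) %*% a`. Total area is
#' conserved exactly by row-stochasticity.
#'
#' @param state a [class_areas()] vector.
#' @param tm a [transition_matrix()] over the same classes in the same
#'   order.
#' @param steps number of transition steps (>= 0); one step spans the
#'   matrix's estimation interval.
#' @return a projected `class_areas`.
#' @export
project_areas <- function(state, tm, steps = 1) {
  if (steps < 0 || steps != round(steps)) stop("steps must be a non-negative integer")
  if (!identical(state$classes, tm$classes))
    stop("class-order mismatch between state and transition matrix")
  a <- state$areas
  P <- tm$probabilities
  for (s in seq_len(steps)) a <- as.numeric(crossprod(P, a))
  new_class_areas(state$classes, state$names, a,
                  label = paste0(state$label %||% "state", " +", steps, " step(s)"))
}

#' Write a transition matrix to CSV
#'
#' Long format with columns `from`, `to`, `area_km2`, `probability` and a
#' leading comment line carrying the interval, re-readable by
#' [read_transition_matrix()].
#'
#' @param tm a `transition_matrix`.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_transition_matrix <- function(tm, path) {
  n <- length(tm$classes)
  df <- data.frame(
    from_code = rep(tm$classes, each = n),
    from = rep(tm$names, each = n),
    to_code = rep(tm$classes, n),
    to = rep(tm$names, n),
    area_km2 = if (is.null(tm$areas)) NA_real_ else as.vector(t(tm$areas)),
    probability = as.vector(t(tm$probabilities)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# interval_years: %g", tm$interval), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a transition matrix written by [write_transition_matrix()]
#'
#' @param path CSV path.
#' @return a `transition_matrix`.
#' @export
read_transition_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  interval <- if (grepl("interval_years:", first))
    as.numeric(sub(".*interval_years:\\s*", "", first)) else 10
  df <- utils::read.csv(path, comment.char = "#")
  codes <- sort(unique(df$from_code))
  nm <- df$from[match(codes, df$from_code)]
  n <- length(codes)
  probs <- matrix(0, n, n, dimnames = list(from = nm, to = nm))
  areas <- matrix(0, n, n, dimnames = list(from = nm, to = nm))
  i <- match(df$from_code, codes); j <- match(df$to_code, codes)
  probs[cbind(i, j)] <- df$probability
  has_area <- !all(is.na(df$area_km2))
  if (has_area) areas[cbind(i, j)] <- df$area_km2
  structure(list(classes = as.integer(codes), names = nm,
                 areas = if (has_area) areas else NULL,
                 probabilities = probs, interval = interval),
            class = "transition_matrix")
}
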