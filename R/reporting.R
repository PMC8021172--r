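#' Cross-tabulated change matrix between two categorical maps
#'
#' Cellwise cross-tabulation of two aligned maps of the same category
#' system (habitat grades or land-use classes), scaled to area (km^2).
#' The diagonal holds unchanged area; the off-diagonal total is the
#' "changed area" statistic used in change-direction accounting.
#'
#' @param a,b aligned `grade_map`s or [land_grid()]s of the same kind.
#' @return an object of class `change_matrix` with elements `labels`,
#'   `areas` (km^2 matrix, rows = category at `a`, cols = category at
#'   `b`), `total`, `changed`.
#' @export
change_matrix <- function(a, b) {
  if (inherits(a, "grade_map") && inherits(b, "grade_map")) {
    assert_aligned(a, b)
    labels <- attr(a, "labels")
    va <- factor(GRADE_LABELS[a$values], levels = labels)
    vb <- factor(GRADE_LABELS[b$values], levels = labels)
    cell_km2 <- (a$cell_size / 1000)^2
  } else if (is_land_grid(a) && is_land_grid(b)) {
    assert_aligned(a, b)
    if (!same_legend(a$legend, b$legend))
      stop("category-system mismatch: different legends")
    labels <- a$legend$names
    va <- factor(legend_name(a$legend, a$values), levels = labels)
    vb <- factor(legend_name(b$legend, b$values), levels = labels)
    cell_km2 <- cell_area_km2(a)
  } else {
    stop("category-system mismatch: maps must both be grade maps or both land-use grids")
  }
  ok <- !is.na(va) & !is.na(vb)
  areas <- unclass(table(va[ok], vb[ok])) * cell_km2
  dimnames(areas) <- list(from = labels, to = labels)
  structure(list(labels = labels, areas = areas,
                 total = sum(areas),
                 changed = sum(areas) - sum(diag(areas))),
            class = "change_matrix")
}

#' @export
print.change_matrix <- function(x, ...) {
  cat(sprintf("change_matrix: total %.2f km^2, changed %.2f km^2\n",
              x$total, x$changed))
  print(round(x$areas, 2))
  invisible(x)
}

#' Share of one change direction in the total changed area
#'
#' `100 * areas[from, to] / (off-diagonal total)`, the percentage used to
#' describe dominant change directions (e.g. the share of grade IV
#' degrading to grade V).
#'
#' @param cm a [change_matrix()].
#' @param from_cat,to_cat category labels.
#' @return percentage of the total changed area.
#' @export
changed_fraction <- function(cm, from_cat, to_cat) {
  if (cm$changed <= 0) stop("zero changed area")
  i <- match(from_cat, cm$labels); j <- match(to_cat, cm$labels)
  if (is.na(i) || is.na(j)) stop("unknown category label")
  if (i == j) stop("diagonal (unchanged) entries are not change directions")
  100 * cm$areas[i, j] / cm$changed
}

#' Per-class area summary with percentages
#'
#' @param lu a [land_grid()].
#' @return data frame with `class`, `code`, `area_km2`, `pct` (of the
#'   non-nodata total; sums to 100).
#' @export
area_summary <- function(lu) {
  ca <- class_areas(lu)
  total <- sum(ca$areas)
  if (total <= 0) stop("empty grid: no non-nodata cells")
  data.frame(class = ca$names, code = ca$classes,
             area_km2 = as.numeric(ca$areas),
             pct = 100 * as.numeric(ca$areas) / total)
}
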