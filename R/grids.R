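#' Class legend for categorical land-use grids
#'
#' A legend maps integer raster codes to land-use class names. The canonical
#' eight-class legend used throughout the package covers farmland, woodland,
#' grassland, water, urban, rural residential, industrial/traffic and barren
#' land; the three built environment classes (urban, rural residential,
#' industrial/traffic) form the "built-up" aggregate. Legends with other
#' vocabularies (e.g. a 25-class source product awaiting reclassification)
#' are permitted; the built-up aggregate is then empty unless supplied.
#'
#' @param codes integer vector of unique raster codes.
#' @param names character vector of unique class names, same length.
#' @param builtup character vector of names forming the built-up aggregate.
#' @return an object of class `class_legend`.
#' @seealso [default_legend()], [builtup_codes()]
#' @export
class_legend <- function(codes, names,
                         builtup = intersect(
                           c("urban", "rural_residential", "industrial_traffic"),
                           names)) {
  codes <- as.integer(codes)
  names <- as.character(names)
  if (length(codes) != length(names) || length(codes) < 1L)
    stop("legend needs equally many codes and names (>= 1)")
  if (anyDuplicated(codes)) stop("legend codes must be unique")
  if (anyDuplicated(names)) stop("legend names must be unique")
  if (!all(builtup %in% names))
    stop("built-up members must be legend names")
  structure(list(codes = codes, names = names, builtup = builtup),
            class = "class_legend")
}

#' The canonical eight-class land-use legend
#'
#' Codes 1-8 for farmland, woodland, grassland, water, urban,
#' rural_residential, industrial_traffic and barren land, with the built-up
#' aggregate set to the three built environment classes.
#'
#' @return a `class_legend`.
#' @export
default_legend <- function() {
  class_legend(1:8,
               c("farmland", "woodland", "grassland", "water", "urban",
                 "rural_residential", "industrial_traffic", "barren"))
}

#' Codes of the built-up aggregate
#'
#' @param legend a `class_legend`.
#' @return integer codes of the built-up member classes.
#' @export
builtup_codes <- function(legend) {
  legend$codes[match(legend$builtup, legend$names)]
}

legend_code <- function(legend, name) {
  i <- match(name, legend$names)
  if (anyNA(i)) stop("unknown class name(s): ",
                     paste(name[is.na(i)], collapse = ", "))
  legend$codes[i]
}

legend_name <- function(legend, code) {
  i <- match(code, legend$codes)
  if (anyNA(i)) stop("unknown class code(s): ",
                     paste(code[is.na(i)], collapse = ", "))
  legend$names[i]
}

same_legend <- function(a, b) {
  identical(a$codes, b$codes) && identical(a$names, b$names)
}

#' Categorical land-use grid
#'
#' The spatial state of the landscape: a matrix of integer class codes with
#' georeferencing metadata. Row 1 / column 1 is the upper-left cell; `origin`
#' is the map coordinate of the grid's upper-left corner and `cell_size` the
#' cell edge length in metres. `NA` marks nodata. Cell area `cell_size^2` is
#' the unit of all area accounting.
#'
#' @param values integer matrix of class codes (`NA` = nodata).
#' @param cell_size cell edge length in metres (> 0); default 1000 m,
#'   matching a 1 km x 1 km evaluation unit.
#' @param origin numeric length-2, (x, y) of the upper-left corner.
#' @param legend a `class_legend` covering every code in `values`.
#' @return an object of class `land_grid`.
#' @export
land_grid <- function(values, cell_size = 1000, origin = c(0, 0),
                      legend = default_legend()) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (nrow(values) < 1L || ncol(values) < 1L) stop("grid must have >= 1 row and column")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  present <- unique(values[!is.na(values)])
  if (!all(present %in% legend$codes))
    stop("values contain codes absent from legend: ",
         paste(setdiff(present, legend$codes), collapse = ", "))
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)[1:2], legend = legend),
            class = c("land_grid", "lh_grid"))
}

#' Continuous grid
#'
#' A real-valued raster layer (drivers, distances, suitability,
#' degradation, quality) sharing the coordinate convention of [land_grid()].
#' `NA` marks nodata.
#'
#' @param values numeric matrix.
#' @inheritParams land_grid
#' @return an object of class `cont_grid`.
#' @export
cont_grid <- function(values, cell_size = 1000, origin = c(0, 0)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) stop("grid must have >= 1 row and column")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)[1:2]),
            class = c("cont_grid", "lh_grid"))
}

is_land_grid <- function(x) inherits(x, "land_grid")

# area of one cell in km^2
cell_area_km2 <- function(grid) (grid$cell_size / 1000)^2

#' @export
print.land_grid <- function(x, ...) {
  cat(sprintf("land_grid: %d x %d cells, %g m cells, %d classes, %d nodata\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              length(unique(x$values[!is.na(x$values)])),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.cont_grid <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("cont_grid: %d x %d cells, %g m cells, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$cell_size, rng[1], rng[2]))
  invisible(x)
}

ASC_NODATA <- -9999L

#' Read a raster from an Esri ASCII grid file
#'
#' Reads the six-line `.asc` header and the value block. For categorical
#' grids a legend is attached: either the `legend` argument, a YAML sidecar
#' written by [write_grid()] (`<path>.yml`), or a generic legend built from
#' the observed codes.
#'
#' @param path file path to an `.asc` raster.
#' @param kind `"categorical"` (land-use codes) or `"continuous"`.
#' @param legend optional `class_legend` for categorical grids.
#' @return a [land_grid()] or [cont_grid()].
#' @export
read_grid <- function(path, kind = c("categorical", "continuous"),
                      legend = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(head_lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys) || anyNA(vals[need]))
    stop("unsupported raster format (expected Esri ASCII grid header): ", path)
  ncols <- as.integer(vals["ncols"]); nrows <- as.integer(vals["nrows"])
  cell <- vals["cellsize"]
  nod <- if ("nodata_value" %in% keys) vals["nodata_value"] else NA_real_
  raw <- scan(path, skip = 6L, quiet = TRUE)
  if (length(raw) != nrows * ncols)
    stop("unsupported raster format: value count does not match header in ", path)
  m <- matrix(raw, nrow = nrows, ncol = ncols, byrow = TRUE)
  if (!is.na(nod)) m[m == nod] <- NA
  origin <- c(vals[["xllcorner"]], vals[["yllcorner"]] + nrows * cell)
  if (kind == "continuous") return(cont_grid(m, cell, origin))
  if (any(m[!is.na(m)] != round(m[!is.na(m)])))
    stop("categorical raster contains non-integer values: ", path)
  storage.mode(m) <- "integer"
  if (is.null(legend)) {
    sidecar <- paste0(path, ".yml")
    if (file.exists(sidecar)) {
      y <- yaml::read_yaml(sidecar)
      legend <- class_legend(unlist(y$codes), unlist(y$names),
                             builtup = as.character(unlist(y$builtup)))
    } else {
      codes <- sort(unique(m[!is.na(m)]))
      legend <- if (all(codes %in% 1:8)) default_legend() else
        class_legend(codes, paste0("class_", codes), builtup = character())
    }
  }
  land_grid(m, cell, origin, legend)
}

#' Write a raster to an Esri ASCII grid file
#'
#' Categorical values are written as integers (bit-identical round-trip);
#' a legend sidecar `<path>.yml` is written alongside land-use grids so
#' [read_grid()] recovers the class vocabulary.
#'
#' @param grid a [land_grid()] or [cont_grid()].
#' @param path output file path (parent directory must exist).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  if (!dir.exists(dirname(path))) stop("unwritable path (no such directory): ", path)
  m <- grid$values
  nrows <- nrow(m); ncols <- ncol(m)
  header <- c(
    paste("ncols", ncols),
    paste("nrows", nrows),
    paste("xllcorner", format(grid$origin[1], digits = 15)),
    paste("yllcorner", format(grid$origin[2] - nrows * grid$cell_size, digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("NODATA_value", ASC_NODATA))
  if (is_land_grid(grid)) {
    m[is.na(m)] <- ASC_NODATA
    body <- apply(m, 1, paste, collapse = " ")
  } else {
    mm <- matrix(formatC(m, format = "g", digits = 15), nrow = nrows)
    mm[is.na(m)] <- as.character(ASC_NODATA)
    body <- apply(mm, 1, paste, collapse = " ")
  }
  writeLines(c(header, body), path)
  if (is_land_grid(grid)) {
    yaml::write_yaml(list(codes = grid$legend$codes,
                          names = grid$legend$names,
                          builtup = grid$legend$builtup),
                     paste0(path, ".yml"))
  }
  invisible(path)
}

#' Reclassify a categorical grid
#'
#' Maps every code in the grid through a code-to-code table, e.g. collapsing
#' a 25-class source product into the eight analysis classes. Nodata cells
#' are untouched and the non-nodata cell count is conserved.
#'
#' @param grid a [land_grid()].
#' @param mapping named integer vector (`names` = input codes, values =
#'   output codes) or a two-column data frame `from`, `to`. Must cover every
#'   code present in the grid.
#' @param legend optional `class_legend` for the result; defaults to the
#'   input legend when all output codes are part of it, otherwise a generic
#'   legend over the output codes.
#' @return a reclassified [land_grid()].
#' @export
reclassify <- function(grid, mapping, legend = NULL) {
  if (is.data.frame(mapping)) {
    mp <- as.integer(mapping[[2]])
    names(mp) <- as.character(as.integer(mapping[[1]]))
    mapping <- mp
  }
  from <- as.integer(names(mapping))
  to <- as.integer(mapping)
  present <- unique(grid$values[!is.na(grid$values)])
  missing <- setdiff(present, from)
  if (length(missing))
    stop("mapping does not cover grid code(s): ", paste(missing, collapse = ", "))
  out <- grid$values
  idx <- match(out, from)
  out[] <- to[idx]
  if (is.null(legend)) {
    legend <- if (all(unique(to[!is.na(idx)]) %in% grid$legend$codes))
      grid$legend
    else {
      codes <- sort(unique(to))
      if (all(codes %in% 1:8)) default_legend()
      else class_legend(codes, paste0("class_", codes), builtup = character())
    }
  }
  land_grid(out, grid$cell_size, grid$origin, legend)
}

#' Read a reclassification table from YAML
#'
#' The YAML maps input codes to output codes, e.g. `"1": 1`, `"21": 2`.
#'
#' @param path YAML file path.
#' @return named integer vector usable as [reclassify()] `mapping`.
#' @export
read_reclass_table <- function(path) {
  y <- yaml::read_yaml(path)
  out <- as.integer(unlist(y))
  names(out) <- names(unlist(y))
  out
}

#' Euclidean distance to the nearest cell of given classes
#'
#' Exact centre-to-centre Euclidean distance (metres) from every cell to
#' the nearest cell carrying one of `source_codes`. Source cells have
#' distance 0. Nodata cells are excluded both as sources and as targets
#' (they are `NA` in the result). Used to build distance-to-feature driver
#' layers and threat-exposure distances.
#'
#' @param grid a [land_grid()].
#' @param source_codes integer class codes acting as sources.
#' @return a [cont_grid()] of distances in metres.
#' @export
distance_to_classes <- function(grid, source_codes) {
  v <- grid$values
  src <- !is.na(v) & v %in% as.integer(source_codes)
  if (!any(src)) stop("no source cells present for codes ",
                      paste(source_codes, collapse = ", "))
  d2 <- edt_squared(src)
  d <- sqrt(d2) * grid$cell_size
  d[is.na(v)] <- NA_real_
  cont_grid(d, grid$cell_size, grid$origin)
}

#' Check that grids are mutually aligned
#'
#' Passes silently iff all grids share shape, cell size and origin; stops
#' with the offending property otherwise. All multi-layer operations in the
#' package require aligned inputs.
#'
#' @param ... two or more grids, or a single list of grids.
#' @return `TRUE` invisibly.
#' @export
assert_aligned <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && !inherits(gs[[1]], "lh_grid")) gs <- gs[[1]]
  if (length(gs) < 2L) stop("need >= 2 grids to compare")
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!identical(dim(g$values), dim(ref$values)))
      stop("grids misaligned: differing shape (",
           paste(dim(ref$values), collapse = "x"), " vs ",
           paste(dim(g$values), collapse = "x"), ")")
    if (!isTRUE(all.equal(g$cell_size, ref$cell_size)))
      stop("grids misaligned: differing cell_size (",
           ref$cell_size, " vs ", g$cell_size, ")")
    if (!isTRUE(all.equal(g$origin, ref$origin)))
      stop("grids misaligned: differing origin")
  }
  invisible(TRUE)
}

#' Bundle co-registered driver layers
#'
#' A driver stack is a named set of continuous grids (elevation, slope,
#' climate surfaces, distance-to-feature layers, socio-economic surfaces)
#' sharing shape, cell size and origin. Nodata masks are harmonised to
#' their union so logistic fits see one consistent mask.
#'
#' @param layers named list of [cont_grid()] objects.
#' @return an object of class `driver_stack` (a named list of layers).
#' @export
driver_stack <- function(layers) {
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("driver layers must be named")
  if (anyDuplicated(names(layers))) stop("driver names must be unique")
  if (length(layers) >= 2L) assert_aligned(layers)
  mask <- Reduce(`|`, lapply(layers, function(g) is.na(g$values)))
  layers <- lapply(layers, function(g) {
    g$values[mask] <- NA_real_
    g
  })
  structure(layers, class = "driver_stack")
}

#' @export
print.driver_stack <- function(x, ...) {
  cat(sprintf("driver_stack: %d layers (%s), %d x %d cells\n",
              length(x), paste(names(x), collapse = ", "),
              nrow(x[[1]]$values), ncol(x[[1]]$values)))
  invisible(x)
}
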