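#' Land-cover class codes
#'
#' First-level ecosystem classification used throughout the package:
#' 1 farmland, 2 forest, 3 grassland, 4 aquatic, 5 settlement, 6 other.
#' Second-level codes (11, 12, 21, ...) are out of scope and rejected on read.
#'
#' @format Named integer vector of length 6.
#' @export
CLASS_CODES <- c(farmland = 1L, forest = 2L, grassland = 3L,
                 aquatic = 4L, settlement = 5L, other = 6L)

#' Construct a categorical land-cover map
#'
#' The common currency of all raster stages: an integer grid of ecosystem
#' class codes with a nodata code, a per-cell area and an opaque georeference
#' carried through untouched. Grid convention is row-major with cell (1,1)
#' at the top-left; the area of a class is its cell count times `cell_area`,
#' reported in km^2.
#'
#' @param grid integer matrix of class codes.
#' @param cell_area area of one cell in km^2 (default 1, i.e. a 1-km grid).
#' @param nodata integer code marking invalid cells (default 0).
#' @param georef list carried through to writers; `xll`, `yll` and `cellsize`
#'   (km) are used by the ASCII-grid writer, anything else is opaque.
#' @return An object of class `class_map`.
#' @export
class_map <- function(grid, cell_area = 1, nodata = 0L,
                      georef = list(xll = 0, yll = 0, cellsize = 1)) {
  stopifnot(is.matrix(grid), cell_area > 0)
  storage.mode(grid) <- "integer"
  bad <- setdiff(unique(as.vector(grid)), c(CLASS_CODES, as.integer(nodata)))
  if (length(bad) > 0)
    stop("unknown class code(s): ", paste(sort(bad), collapse = ", "),
         " (valid codes are ", paste(CLASS_CODES, collapse = ", "),
         ", nodata ", nodata, ")")
  structure(list(grid = grid, cell_area = as.numeric(cell_area),
                 nodata = as.integer(nodata), georef = georef),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat("<class_map> ", nrow(x$grid), " x ", ncol(x$grid),
      " cells, cell_area ", x$cell_area, " km^2, nodata code ", x$nodata,
      "\n", sep = "")
  a <- class_areas(x)
  cat("areas (km^2): ", paste(names(a), a, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

valid_mask <- function(map) map$grid != map$nodata

#' Per-class areas of a class map
#'
#' @param map a [class_map()].
#' @return Named numeric vector (km^2) over the six classes; nodata excluded.
#' @export
class_areas <- function(map) {
  stopifnot(inherits(map, "class_map"))
  v <- map$grid[valid_mask(map)]
  cnt <- tabulate(v, nbins = 6L)
  stats::setNames(cnt * map$cell_area, names(CLASS_CODES))
}

#' Per-class cell counts of a class map
#' @param map a [class_map()].
#' @return Named integer vector over the six classes.
#' @export
class_counts <- function(map) {
  stats::setNames(tabulate(map$grid[valid_mask(map)], nbins = 6L),
                  names(CLASS_CODES))
}

grid_shape <- function(x) {
  if (inherits(x, "class_map")) dim(x$grid)
  else if (inherits(x, "driver_stack")) dim(x$layers[[1L]])
  else if (is.matrix(x)) dim(x)
  else stop("not a grid-like object")
}

#' Check that maps and driver stacks share one grid
#'
#' Two grids are aligned iff their shapes, cell areas and georeference
#' headers agree. No reprojection or resampling is performed anywhere in the
#' package, so misalignment is always an input error.
#'
#' @param ... two or more `class_map` / `driver_stack` objects, optionally
#'   named for readable reports.
#' @return A list with elements `ok` (logical) and `mismatch` (character;
#'   names the first disagreeing property, or `NA` when aligned).
#' @export
align_check <- function(...) {
  objs <- list(...)
  if (length(objs) < 2) stop("align_check needs at least two grids")
  nm <- names(objs)
  if (is.null(nm)) nm <- paste0("grid", seq_along(objs))
  nm[nm == ""] <- paste0("grid", which(nm == ""))
  ref <- objs[[1L]]
  ref_shape <- grid_shape(ref)
  ref_area <- if (inherits(ref, "class_map")) ref$cell_area else NA_real_
  ref_geo <- if (inherits(ref, "class_map")) ref$georef else NULL
  for (i in seq_along(objs)[-1L]) {
    o <- objs[[i]]
    if (!identical(grid_shape(o), ref_shape))
      return(list(ok = FALSE, mismatch = sprintf(
        "shape: %s is %s, %s is %s", nm[1L],
        paste(ref_shape, collapse = "x"), nm[i],
        paste(grid_shape(o), collapse = "x"))))
    if (inherits(o, "class_map") && !is.na(ref_area) &&
        !isTRUE(all.equal(o$cell_area, ref_area)))
      return(list(ok = FALSE, mismatch = sprintf(
        "cell_area: %s is %g, %s is %g", nm[1L], ref_area, nm[i],
        o$cell_area)))
    if (inherits(o, "class_map") && !is.null(ref_geo) &&
        !isTRUE(all.equal(o$georef[c("xll", "yll", "cellsize")],
                          ref_geo[c("xll", "yll", "cellsize")])))
      return(list(ok = FALSE, mismatch = "georeference"))
  }
  list(ok = TRUE, mismatch = NA_character_)
}

stop_unless_aligned <- function(...) {
  rep <- align_check(...)
  if (!rep$ok) stop("grids are not aligned (", rep$mismatch, ")")
  invisible(TRUE)
}

#' Construct a stack of continuous driver layers
#'
#' Spatial covariates (elevation, slope, climate, distance-to-road, GDP,
#' population, ...) used to fit development-probability surfaces. All layers
#' must share one shape; the nodata mask is shared with the companion
#' class map.
#'
#' @param layers named list of numeric matrices, one per driver.
#' @return An object of class `driver_stack`.
#' @export
driver_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || anyDuplicated(names(layers)) ||
      any(names(layers) == ""))
    stop("driver layers must have unique non-empty names")
  d <- dim(layers[[1L]])
  for (l in layers) {
    stopifnot(is.matrix(l))
    if (!identical(dim(l), d)) stop("driver layers differ in shape")
  }
  structure(list(layers = layers), class = "driver_stack")
}

#' @export
print.driver_stack <- function(x, ...) {
  cat("<driver_stack> ", length(x$layers), " layers (",
      paste(names(x$layers), collapse = ", "), "), ",
      nrow(x$layers[[1L]]), " x ", ncol(x$layers[[1L]]), " cells\n", sep = "")
  invisible(x)
}
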