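# Raster and table I/O.
#
# Rasters use the ESRI ASCII grid format (.asc): a 6-line header (ncols,
# nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by one
# whitespace-separated row of values per grid row, top row first. cellsize is
# in km, so cell_area = cellsize^2 km^2. All CSVs have a header row and use
# '.' as the decimal separator.

read_asc <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- character(6); for (i in 1:6) hdr[i] <- readLines(con, n = 1L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  keys <- tolower(kv[, 1L]); vals <- as.numeric(kv[, 2L])
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  h <- stats::setNames(vals, keys)
  vals <- scan(con, what = numeric(), quiet = TRUE)
  nr <- as.integer(h["nrows"]); nc <- as.integer(h["ncols"])
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  grid <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  list(grid = grid, xll = unname(h["xllcorner"]), yll = unname(h["yllcorner"]),
       cellsize = unname(h["cellsize"]), nodata = unname(h["nodata_value"]))
}

write_asc <- function(grid, path, xll = 0, yll = 0, cellsize = 1,
                      nodata = -9999) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("ncols", ncol(grid)),
               paste("nrows", nrow(grid)),
               paste("xllcorner", format(xll, scientific = FALSE)),
               paste("yllcorner", format(yll, scientific = FALSE)),
               paste("cellsize", format(cellsize, scientific = FALSE)),
               paste("NODATA_value", format(nodata, scientific = FALSE))),
             con)
  g <- grid
  g[is.na(g)] <- nodata
  writeLines(apply(g, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a categorical class map from an ASCII grid
#'
#' Any cell value outside the six first-level class codes (plus the nodata
#' code) is rejected with an error naming the offending values; in
#' particular second-level codes such as 11 or 21 must be aggregated to
#' first level before use.
#'
#' @param path path to a `.asc` file with integer class codes.
#' @param nodata nodata code; defaults to the NODATA_value of the file header.
#' @return A [class_map()]; `cell_area` is `cellsize^2` (cellsize in km).
#' @export
read_class_map <- function(path, nodata = NULL) {
  r <- read_asc(path)
  if (any(r$grid != round(r$grid), na.rm = TRUE))
    stop("class raster contains non-integer values: ", path)
  nd <- if (is.null(nodata)) as.integer(r$nodata) else as.integer(nodata)
  grid <- r$grid
  storage.mode(grid) <- "integer"
  class_map(grid, cell_area = r$cellsize^2, nodata = nd,
            georef = list(xll = r$xll, yll = r$yll, cellsize = r$cellsize))
}

#' Write a class map as an ASCII grid
#'
#' @param map a [class_map()].
#' @param path output path.
#' @return `path`, invisibly. Round-trips bit-identically through
#'   [read_class_map()].
#' @export
write_class_map <- function(map, path) {
  stopifnot(inherits(map, "class_map"))
  g <- map$georef
  write_asc(map$grid, path, xll = g$xll %||% 0, yll = g$yll %||% 0,
            cellsize = g$cellsize %||% sqrt(map$cell_area),
            nodata = map$nodata)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a stack of continuous driver rasters
#'
#' @param paths named character vector of `.asc` paths; names become layer
#'   names (defaults to file names without extension).
#' @return A [driver_stack()]. Nodata cells become `NA`.
#' @export
read_driver_stack <- function(paths) {
  nm <- names(paths)
  if (is.null(nm)) nm <- tools::file_path_sans_ext(basename(paths))
  layers <- lapply(paths, function(p) {
    r <- read_asc(p)
    g <- r$grid
    g[g == r$nodata] <- NA_real_
    g
  })
  names(layers) <- nm
  driver_stack(layers)
}

#' Write a driver stack as one ASCII grid per layer
#'
#' @param stack a [driver_stack()].
#' @param dir output directory (created if missing).
#' @param cellsize cell edge in km written into each header.
#' @return Named vector of written paths, invisibly.
#' @export
write_driver_stack <- function(stack, dir, cellsize = 1) {
  stopifnot(inherits(stack, "driver_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_asc(stack$layers[[nm]], p, cellsize = cellsize)
    p
  }, character(1))
  invisible(paths)
}

#' Read a four-pool carbon-density table from CSV
#'
#' Expected columns: `class_code`, `class_name`, `c_above`, `c_below`,
#' `c_soil`, `c_dead` (densities in Mg/hm^2). A `c_tot` column is added as
#' the pool sum.
#'
#' @param path CSV path.
#' @return A validated density `data.frame`; see [carbon_density_table()].
#' @export
read_density_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  carbon_density_table(df)
}

#' Read a region-by-indicator table with orientations from CSV
#'
#' Layout: a `region` column, one numeric column per indicator, and a first
#' data row named `orientation` holding `positive`/`negative` per indicator
#' (or a sidecar via `orientation_path` with columns `indicator`,
#' `orientation`).
#'
#' @param path CSV path.
#' @param orientation_path optional sidecar CSV.
#' @return List with `values` (data.frame, region column first) and
#'   `orientations` (named character vector).
#' @export
read_indicator_table <- function(path, orientation_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("region" %in% names(df))
  if (!is.null(orientation_path)) {
    o <- utils::read.csv(orientation_path, stringsAsFactors = FALSE)
    ors <- stats::setNames(o$orientation, o$indicator)
  } else {
    i <- match("orientation", df$region)
    if (is.na(i)) stop("no orientation row and no sidecar given")
    ors <- unlist(df[i, -1L])
    df <- df[-i, , drop = FALSE]
  }
  vals <- df
  vals[-1L] <- lapply(vals[-1L], as.numeric)
  rownames(vals) <- NULL
  list(values = vals, orientations = ors[names(vals)[-1L]])
}
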