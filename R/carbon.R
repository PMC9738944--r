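# Four-pool carbon-density bookkeeping.
#
# Unit convention, fixed package-wide: densities in Mg/hm^2, areas in km^2,
# storage reported in 10^4 Mg. 1 km^2 = 100 hm^2 and 10^4 Mg per reporting
# unit cancel to storage = area_km2 * density / 100. Densities are treated
# as static over time (no temporal interpolation).

#' Validate a four-pool carbon-density table
#'
#' Each land-cover class carries densities for the aboveground biomass,
#' belowground biomass, soil organic carbon and dead organic matter pools;
#' the total density is their sum.
#'
#' @param df data.frame with columns `class_code`, `class_name`, `c_above`,
#'   `c_below`, `c_soil`, `c_dead`. A `c_tot` column, if present, is checked
#'   against the pool sum; otherwise it is added.
#' @return The table with `c_tot`, ordered by `class_code`.
#' @export
carbon_density_table <- function(df) {
  need <- c("class_code", "c_above", "c_below", "c_soil", "c_dead")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("density table missing column(s): ", paste(miss, collapse = ", "))
  pools <- as.matrix(df[c("c_above", "c_below", "c_soil", "c_dead")])
  if (any(pools < 0)) stop("carbon-pool densities must be non-negative")
  tot <- rowSums(pools)
  if ("c_tot" %in% names(df) &&
      any(abs(df$c_tot - tot) > 1e-9))
    stop("c_tot column disagrees with the pool sum")
  df$c_tot <- tot
  df[order(df$class_code), , drop = FALSE]
}

#' Total carbon density of one class
#'
#' Sum of the four pool densities (Mg/hm^2).
#'
#' @param c_above,c_below,c_soil,c_dead non-negative pool densities.
#' @return Total density in Mg/hm^2.
#' @examples
#' total_density(13.05, 7.30, 103.48, 2.32) # farmland, 126.15
#' @export
total_density <- function(c_above, c_below, c_soil, c_dead) {
  if (any(c(c_above, c_below, c_soil, c_dead) < 0))
    stop("carbon-pool densities must be non-negative")
  c_above + c_below + c_soil + c_dead
}

densities_for <- function(table, codes = CLASS_CODES) {
  i <- match(codes, table$class_code)
  if (anyNA(i))
    stop("no density row for class(es): ",
         paste(codes[is.na(i)], collapse = ", "))
  stats::setNames(table$c_tot[i], names(codes))
}

#' Per-class carbon storage from per-class areas
#'
#' Tabular entry point to the bookkeeping: storage(10^4 Mg) =
#' area(km^2) x total density(Mg/hm^2) / 100 per class, with a totals row.
#' Full precision is retained in `storage`; `storage_rep` is rounded half-up
#' to 2 decimals at the reporting boundary only.
#'
#' @param areas named numeric vector of areas in km^2; names or positions
#'   must map onto class codes 1..6 (missing classes count as 0).
#' @param table density table (see [carbon_density_table()]).
#' @return data.frame with columns `class_code`, `class_name`, `area_km2`,
#'   `storage` and `storage_rep`, plus a `total` row.
#' @export
storage_from_area_table <- function(areas, table) {
  table <- carbon_density_table(table)
  full <- stats::setNames(numeric(6L), names(CLASS_CODES))
  if (!is.null(names(areas)) && all(names(areas) %in% names(CLASS_CODES))) {
    full[names(areas)] <- areas
  } else if (length(areas) == 6L) {
    full[] <- areas
  } else stop("areas must be named by class or be length 6")
  if (any(full < 0)) stop("areas must be non-negative")
  ct <- stats::setNames(numeric(6L), names(CLASS_CODES))
  i <- match(CLASS_CODES, table$class_code)
  ct[!is.na(i)] <- table$c_tot[i[!is.na(i)]]
  need <- is.na(i) & full > 0
  if (any(need))
    stop("no density row for class(es): ",
         paste(CLASS_CODES[need], collapse = ", "))
  storage <- full * ct / 100
  out <- data.frame(class_code = c(unname(CLASS_CODES), NA),
                    class_name = c(names(CLASS_CODES), "total"),
                    area_km2 = c(unname(full), sum(full)),
                    storage = c(unname(storage), sum(storage)))
  out$storage_rep <- round_half_up(out$storage, 2)
  out
}

#' Carbon storage of a class map
#'
#' @param map a [class_map()].
#' @param table density table; every class present in the map must have a row.
#' @return Same summary as [storage_from_area_table()] applied to
#'   [class_areas()] of the map.
#' @export
carbon_storage <- function(map, table) {
  stopifnot(inherits(map, "class_map"))
  present <- unique(map$grid[valid_mask(map)])
  missing <- setdiff(present, table$class_code)
  if (length(missing) > 0)
    stop("no density row for class(es): ", paste(sort(missing), collapse = ", "))
  storage_from_area_table(class_areas(map), table)
}

#' Per-cell carbon-storage change between two epochs
#'
#' For each cell the change is (density at t1 - density at t0) x cell_area x
#' 100, i.e. Mg per cell, so the matrix sum equals the landscape storage
#' delta (in Mg) with no unit juggling. Unchanged cells are exactly 0;
#' cells that are nodata in either epoch are `NA`.
#'
#' @param map_t0,map_t1 aligned [class_map()]s.
#' @param table shared density table.
#' @return Numeric matrix (Mg per cell) of the same shape as the inputs.
#' @export
carbon_change_map <- function(map_t0, map_t1, table) {
  stop_unless_aligned(t0 = map_t0, t1 = map_t1)
  table <- carbon_density_table(table)
  ct <- densities_for(table)
  lut <- numeric(max(CLASS_CODES))
  lut[CLASS_CODES] <- ct
  v0 <- valid_mask(map_t0); v1 <- valid_mask(map_t1)
  ok <- v0 & v1
  delta <- matrix(NA_real_, nrow(map_t0$grid), ncol(map_t0$grid))
  delta[ok] <- (lut[map_t1$grid[ok]] - lut[map_t0$grid[ok]]) *
    map_t0$cell_area * 100
  delta
}
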