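# Area-flow accounting between epochs and map-agreement metrics.

#' Class-to-class transition matrix between two epochs
#'
#' Entry (i, j) is the area (km^2) of cells of class i at t0 and class j at
#' t1. Cells that are nodata in either epoch are excluded from the
#' cross-tabulation, which keeps the row/column marginals equal to the
#' per-epoch class areas over the shared valid mask.
#'
#' @param map_t0,map_t1 aligned [class_map()]s.
#' @return 6 x 6 numeric matrix (km^2) with class-name dimnames.
#' @export
transition_matrix <- function(map_t0, map_t1) {
  stop_unless_aligned(t0 = map_t0, t1 = map_t1)
  ok <- valid_mask(map_t0) & valid_mask(map_t1)
  a <- factor(map_t0$grid[ok], levels = CLASS_CODES)
  b <- factor(map_t1$grid[ok], levels = CLASS_CODES)
  m <- unclass(table(a, b)) * map_t0$cell_area
  dimnames(m) <- list(from = names(CLASS_CODES), to = names(CLASS_CODES))
  m
}

#' Agreement between a reference and a simulated map
#'
#' Overall accuracy is the share of valid cells with identical class; Cohen's
#' kappa corrects it for chance agreement expected from the confusion-matrix
#' marginals: kappa = (p_o - p_e) / (1 - p_e). In the degenerate case
#' p_e = 1 (both maps constant), kappa is defined as 1 when the maps are
#' identical and 0 otherwise.
#'
#' @param map_ref,map_sim aligned [class_map()]s.
#' @return List with `confusion` (cell counts), `overall_accuracy`, `kappa`.
#' @export
agreement <- function(map_ref, map_sim) {
  stop_unless_aligned(ref = map_ref, sim = map_sim)
  ok <- valid_mask(map_ref) & valid_mask(map_sim)
  n <- sum(ok)
  if (n == 0) stop("no cells valid in both maps")
  a <- factor(map_ref$grid[ok], levels = CLASS_CODES)
  b <- factor(map_sim$grid[ok], levels = CLASS_CODES)
  cm <- unclass(table(a, b))
  dimnames(cm) <- list(ref = names(CLASS_CODES), sim = names(CLASS_CODES))
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) as.numeric(po == 1)
           else (po - pe) / (1 - pe)
  list(confusion = cm, overall_accuracy = po, kappa = kappa)
}
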