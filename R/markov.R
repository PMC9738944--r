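# First-order Markov projection of per-class area demand.

#' Estimate a Markov transition-probability matrix from observed flows
#'
#' Row-normalises a transition count/area matrix: P[i, j] = flow(i -> j) /
#' area of class i at t0. Classes absent at t0 (empty rows) get an identity
#' row, so an absent class stays absent rather than producing NaN.
#'
#' @param counts 6 x 6 non-negative flow matrix, e.g. from
#'   [transition_matrix()].
#' @param step_span years covered by one step of the chain (metadata only;
#'   default 10).
#' @return List of class `markov_model` with `P` (row-stochastic matrix) and
#'   `step_span`.
#' @export
estimate_markov <- function(counts, step_span = 10) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts))
  if (any(counts < 0)) stop("transition counts must be non-negative")
  rs <- rowSums(counts)
  P <- counts
  for (i in seq_len(nrow(P))) {
    if (rs[i] > 0) P[i, ] <- counts[i, ] / rs[i]
    else { P[i, ] <- 0; P[i, i] <- 1 }
  }
  structure(list(P = P, step_span = step_span), class = "markov_model")
}

#' Project per-class area demand n steps ahead
#'
#' demand = areas %*% P^n. Total area is conserved (row-stochastic chain);
#' integer cell targets use largest-remainder rounding so the counts sum
#' exactly to the total cell count, which lets the cellular automaton stop
#' at tolerance 0.
#'
#' @param areas named per-class areas (km^2) at the chain's start epoch.
#' @param model a `markov_model` from [estimate_markov()].
#' @param n_steps number of steps (>= 1); with a decade chain, 1 step
#'   projects 10 years ahead.
#' @param cell_area km^2 per cell, used to convert areas to cell counts.
#' @return data.frame of class/`target_km2`/`target_cells` (a demand vector).
#' @export
project_demand <- function(areas, model, n_steps = 1, cell_area = 1) {
  stopifnot(inherits(model, "markov_model"), n_steps >= 1)
  v <- as.numeric(areas)
  for (s in seq_len(n_steps)) v <- as.numeric(v %*% model$P)
  cells <- largest_remainder(v / cell_area,
                             round(sum(areas) / cell_area))
  data.frame(class_code = unname(CLASS_CODES)[seq_along(v)],
             class_name = names(CLASS_CODES)[seq_along(v)],
             target_km2 = v, target_cells = cells)
}
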