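# Demand-driven patch-generating cellular automaton ("CA based on multiple
# random seeds"): allocates Markov demand over development-probability
# surfaces under neighbourhood effects, a 0/1 transition mask, and a
# threshold-decreasing seeding mechanism.

#' Cellular-automaton configuration
#'
#' @param neighborhood_size odd window edge for the neighbourhood effect
#'   (default 3).
#' @param patch_decay attenuation coefficient of the decreasing acceptance
#'   threshold, in (0, 1]; the threshold is multiplied by it whenever a round
#'   leaves unmet demand, so patches grow before new ones nucleate. Higher
#'   values decay slower, making conversion harder for longer (default 0.5).
#' @param expansion_coeff probability scale of spontaneous random patch
#'   seeds, in (0, 1]; higher values nucleate new patches more easily
#'   (default 0.5).
#' @param seed_fraction share of zero-neighbourhood candidate cells eligible
#'   as spontaneous seeds per round (default 0.05).
#' @param allowed 6 x 6 0/1 conversion mask (1 = conversion permitted);
#'   default all-ones. The diagonal must be 1.
#' @param domain_weights named per-class neighbourhood weight vector
#'   (default all 1; see [expansion_share_weights()]).
#' @param demand_tolerance per-class slack, in cells, of the stopping rule
#'   (default 0).
#' @param max_rounds hard iteration cap; hitting it flags the result as
#'   unconverged (default 300).
#' @param rng_seed integer seed; identical seeds give identical simulations.
#' @return List of class `ca_config`.
#' @export
ca_config <- function(neighborhood_size = 3, patch_decay = 0.5,
                      expansion_coeff = 0.5, seed_fraction = 0.05,
                      allowed = NULL, domain_weights = NULL,
                      demand_tolerance = 0, max_rounds = 300, rng_seed = 1) {
  stopifnot(neighborhood_size %% 2 == 1, neighborhood_size >= 3,
            patch_decay > 0, patch_decay <= 1,
            expansion_coeff >= 0, expansion_coeff <= 1,
            seed_fraction >= 0, seed_fraction <= 1)
  if (is.null(allowed))
    allowed <- matrix(1L, 6, 6, dimnames = list(names(CLASS_CODES),
                                                names(CLASS_CODES)))
  if (any(diag(allowed) != 1)) stop("transition-mask diagonal must be all 1")
  if (is.null(domain_weights))
    domain_weights <- stats::setNames(rep(1, 6), names(CLASS_CODES))
  structure(list(neighborhood_size = as.integer(neighborhood_size),
                 patch_decay = patch_decay,
                 expansion_coeff = expansion_coeff,
                 seed_fraction = seed_fraction, allowed = allowed,
                 domain_weights = domain_weights,
                 demand_tolerance = as.integer(demand_tolerance),
                 max_rounds = as.integer(max_rounds),
                 rng_seed = as.integer(rng_seed)),
            class = "ca_config")
}

neigh_fraction <- function(grid, valid, k, w) {
  isk <- matrix(as.numeric(grid == k & valid), nrow(grid), ncol(grid))
  v <- matrix(as.numeric(valid), nrow(grid), ncol(grid))
  kc <- box_sum(isk, w) - isk          # class-k neighbours, centre excluded
  vc <- box_sum(v, w) - v              # valid neighbours, centre excluded
  out <- matrix(0, nrow(grid), ncol(grid))
  pos <- vc > 0
  out[pos] <- kc[pos] / vc[pos]
  out
}

#' Neighbourhood effect of a class
#'
#' Fraction of class-k cells among the valid neighbours in a w x w window
#' centred on each cell, centre excluded; edge cells use the truncated
#' window and nodata cells count in neither numerator nor denominator.
#'
#' @param map a [class_map()].
#' @param class_k class code or name.
#' @param window odd window edge (default 3, i.e. the 8 neighbours).
#' @return Matrix of densities in [0, 1].
#' @export
neighborhood_effect <- function(map, class_k, window = 3) {
  stopifnot(inherits(map, "class_map"))
  if (window %% 2 != 1) stop("window must be odd")
  neigh_fraction(map$grid, valid_mask(map), resolve_class(class_k), window)
}

demand_cells <- function(demand) {
  if (is.data.frame(demand)) {
    stats::setNames(as.integer(demand$target_cells),
                    demand$class_name %||% names(CLASS_CODES))
  } else stats::setNames(as.integer(demand), names(demand) %||%
                           names(CLASS_CODES))
}

#' Run the patch-generating cellular automaton
#'
#' Starting from `map_t0`, cells of over-demand classes compete to convert
#' into under-demand classes until every class's cell count matches its
#' demand within `demand_tolerance`. Each round, a candidate conversion of a
#' cell into class k carries overall probability OP_k = P_dev_k x Omega_k x
#' w_k (development probability x neighbourhood effect x domain weight);
#' where Omega_k = 0 a spontaneous-seed path lets new patches nucleate with
#' probability `expansion_coeff x seed_fraction`, using OP_k = P_dev_k x w_k
#' x U(0,1). The candidate class is drawn by roulette wheel over OP, the
#' conversion is accepted iff OP clears the current threshold (initialised
#' at the 90th percentile of first-round OP), and per-class caps guarantee
#' that demand is never overshot and restricted transitions never occur.
#' The threshold decays by `patch_decay` after any round leaving unmet
#' demand. Deterministic given `cfg$rng_seed`.
#'
#' @param map_t0 starting [class_map()].
#' @param suitability a `suitability_stack` from [fit_suitability()]; classes
#'   without a surface get a flat 0.5.
#' @param demand per-class target cell counts: a [project_demand()] frame or
#'   a named integer vector summing to the valid cell count of `map_t0`.
#' @param cfg a [ca_config()].
#' @return List of class `ca_result`: `map` (final [class_map()]), `log`
#'   (per-round data.frame: round, tau, converted, remaining deficit),
#'   `achieved` / `demanded` counts, `realized_flows` (6 x 6 cell-count
#'   matrix of conversions performed), `converged`, `rounds`.
#' @export
simulate_ca <- function(map_t0, suitability, demand, cfg = ca_config()) {
  stopifnot(inherits(map_t0, "class_map"), inherits(cfg, "ca_config"))
  dem <- demand_cells(demand)
  full_dem <- stats::setNames(integer(6L), names(CLASS_CODES))
  full_dem[names(dem)] <- dem
  grid <- map_t0$grid
  valid <- valid_mask(map_t0)
  n_valid <- sum(valid)
  if (sum(full_dem) != n_valid)
    stop("demand (", sum(full_dem), " cells) must equal the valid cell count (",
         n_valid, ")")
  counts <- class_counts(map_t0)
  deficit <- full_dem - counts
  # feasibility under the mask
  for (k in which(deficit > cfg$demand_tolerance)) {
    donors <- which(deficit < 0 & cfg$allowed[, k] == 1 & counts > 0)
    if (length(donors) == 0)
      stop("demand for class ", names(CLASS_CODES)[k],
           " is infeasible under the transition mask")
  }
  d <- dim(grid)
  surf <- lapply(seq_len(6L), function(k) {
    s <- suitability$surfaces[[names(CLASS_CODES)[k]]]
    if (is.null(s)) matrix(0.5, d[1], d[2]) else { s[is.na(s)] <- 0; s }
  })
  w <- cfg$domain_weights[names(CLASS_CODES)]
  flows <- matrix(0L, 6, 6, dimnames = dimnames(cfg$allowed))
  log_rows <- list()
  tau <- NA_real_
  rounds <- 0L
  with_seed(cfg$rng_seed, {
    repeat {
      if (max(deficit) <= cfg$demand_tolerance || rounds >= cfg$max_rounds)
        break
      rounds <- rounds + 1L
      targets <- which(deficit > cfg$demand_tolerance)
      sources <- which(deficit < 0)
      cand <- which(valid & matrix(grid %in% sources, d[1], d[2]))
      if (length(cand) == 0) break
      op <- matrix(0, length(cand), length(targets))
      for (j in seq_along(targets)) {
        k <- targets[j]
        om <- neigh_fraction(grid, valid, k, cfg$neighborhood_size)[cand]
        pd <- surf[[k]][cand]
        opk <- pd * om * w[k]
        z <- om == 0
        if (any(z) && cfg$expansion_coeff * cfg$seed_fraction > 0) {
          nz <- sum(z)
          seeded <- stats::runif(nz) < cfg$expansion_coeff * cfg$seed_fraction
          opk[z][seeded] <- pd[z][seeded] * w[k] * stats::runif(sum(seeded))
        }
        opk[cfg$allowed[cbind(grid[cand], k)] == 0] <- 0
        op[, j] <- opk
      }
      rs <- rowSums(op)
      live <- which(rs > 0)
      if (is.na(tau) && length(live) > 0)
        tau <- stats::quantile(op[op > 0], 0.9, names = FALSE)
      converted <- 0L
      if (length(live) > 0) {
        # roulette wheel over candidate classes
        u <- stats::runif(length(live)) * rs[live]
        pick <- integer(length(live))
        acc <- numeric(length(live))
        for (j in seq_along(targets)) {
          col <- op[live, j]
          sel <- pick == 0L & u <= acc + col
          pick[sel] <- j
          acc <- acc + col
        }
        pick[pick == 0L] <- length(targets)  # numerical slack
        chosen_op <- op[cbind(live, pick)]
        keep <- chosen_op >= tau & chosen_op > 0
        cells <- cand[live[keep]]
        tgt <- targets[pick[keep]]
        score <- chosen_op[keep]
        if (length(cells) > 0) {
          ord <- order(-score)
          cells <- cells[ord]; tgt <- tgt[ord]
          src <- grid[cells]
          take <- logical(length(cells))
          gain <- integer(6L); lose <- integer(6L)
          room_gain <- pmax(deficit, 0L)
          room_lose <- pmax(-deficit, 0L)
          for (m in seq_along(cells)) {
            k <- tgt[m]; i <- src[m]
            if (gain[k] < room_gain[k] && lose[i] < room_lose[i]) {
              take[m] <- TRUE
              gain[k] <- gain[k] + 1L
              lose[i] <- lose[i] + 1L
            }
          }
          cells <- cells[take]; tgt <- tgt[take]; src <- src[take]
          if (length(cells) > 0) {
            grid[cells] <- tgt
            converted <- length(cells)
            for (m in seq_along(cells))
              flows[src[m], tgt[m]] <- flows[src[m], tgt[m]] + 1L
            counts <- counts - tabulate(src, 6L) + tabulate(tgt, 6L)
            deficit <- full_dem - counts
          }
        }
      }
      log_rows[[rounds]] <- data.frame(
        round = rounds, tau = if (is.na(tau)) NA_real_ else tau,
        converted = converted,
        deficit_remaining = sum(pmax(deficit - cfg$demand_tolerance, 0L)))
      if (max(deficit) > cfg$demand_tolerance && !is.na(tau))
        tau <- tau * cfg$patch_decay
    }
  })
  out <- map_t0
  out$grid <- grid
  structure(list(map = out,
                 log = if (length(log_rows)) do.call(rbind, log_rows)
                       else data.frame(round = integer(), tau = numeric(),
                                       converted = integer(),
                                       deficit_remaining = integer()),
                 achieved = counts, demanded = full_dem,
                 realized_flows = flows,
                 converged = max(full_dem - counts) <= cfg$demand_tolerance,
                 rounds = rounds),
            class = "ca_result")
}

#' End-to-end projection: expansion analysis, demand, simulation, carbon
#'
#' Composes the pipeline for one or more future horizons:
#' [extract_expansion()] and [fit_suitability()] on the observed epoch pair,
#' [estimate_markov()] and [project_demand()] for each horizon's demand
#' (demand chains the Markov vectors from the t1 areas, independent of the
#' simulated maps), then [simulate_ca()] — each horizon starting from the
#' previous simulated map — and [carbon_storage()] on every result.
#'
#' @param map_t0,map_t1 the observed epoch pair.
#' @param drivers [driver_stack()] of spatial covariates.
#' @param density carbon-density table.
#' @param cfg a [ca_config()]; if its `domain_weights` are all 1 they are
#'   replaced by [expansion_share_weights()] of the observed flows.
#' @param steps integer vector of Markov steps ahead of t1 (e.g. `c(1, 3)`
#'   for one and three decades); empty returns the fitted intermediates only.
#' @param sampling_rate LEAS sampling rate (default 0.01).
#' @param seed integer seed for extraction and forest fitting.
#' @return List with `flows`, `model`, `suitability`, `weights` and
#'   `horizons` (per step: `demand`, `result`, `summary`).
#' @export
run_projection <- function(map_t0, map_t1, drivers, density,
                           cfg = ca_config(), steps = c(1, 3),
                           sampling_rate = 0.01, seed = 1) {
  stop_unless_aligned(t0 = map_t0, t1 = map_t1, drv = drivers)
  flows <- transition_matrix(map_t0, map_t1)
  model <- estimate_markov(flows)
  samples <- lapply(CLASS_CODES, function(k)
    suppressWarnings(extract_expansion(map_t0, map_t1, k,
                                       sampling_rate = sampling_rate,
                                       seed = seed + k)))
  samples <- Filter(function(s) s$n_expansion > 0, samples)
  suit <- fit_suitability(samples, drivers, map_t1, seed = seed)
  if (all(cfg$domain_weights == 1))
    cfg$domain_weights <- expansion_share_weights(flows)
  out <- list(flows = flows, model = model, suitability = suit,
              weights = cfg$domain_weights, horizons = list())
  if (length(steps) == 0) return(out)
  steps <- sort(steps)
  areas_t1 <- class_areas(map_t1)
  cur <- map_t1
  for (i in seq_along(steps)) {
    dem <- project_demand(areas_t1, model, n_steps = steps[i],
                          cell_area = map_t1$cell_area)
    hcfg <- cfg
    hcfg$rng_seed <- cfg$rng_seed + i - 1L
    res <- simulate_ca(cur, suit, dem, hcfg)
    cur <- res$map
    out$horizons[[as.character(steps[i])]] <-
      list(demand = dem, result = res, summary = carbon_storage(cur, density))
  }
  out
}

#' Demand-matched random-allocation baseline
#'
#' Satisfies the same per-class demand as [simulate_ca()] but places every
#' conversion uniformly at random among mask-permitted surplus cells,
#' ignoring suitability and neighbourhood structure. Used as the null
#' benchmark a real simulation must beat on map agreement.
#'
#' @param map_t0 starting [class_map()].
#' @param demand as in [simulate_ca()].
#' @param allowed 6 x 6 0/1 conversion mask (default all-ones).
#' @param seed integer seed.
#' @return A [class_map()] meeting the demand exactly.
#' @export
random_allocation_baseline <- function(map_t0, demand, allowed = NULL,
                                       seed = 1) {
  stopifnot(inherits(map_t0, "class_map"))
  if (is.null(allowed)) allowed <- matrix(1L, 6, 6)
  dem <- demand_cells(demand)
  full_dem <- stats::setNames(integer(6L), names(CLASS_CODES))
  full_dem[names(dem)] <- dem
  grid <- map_t0$grid
  valid <- valid_mask(map_t0)
  if (sum(full_dem) != sum(valid))
    stop("demand must equal the valid cell count")
  with_seed(seed, {
    repeat {
      counts <- tabulate(grid[valid], 6L)
      deficit <- full_dem - counts
      if (all(deficit <= 0)) break
      k <- which.max(deficit)
      donors <- which(deficit < 0 & allowed[, k] == 1)
      if (length(donors) == 0)
        stop("demand for class ", names(CLASS_CODES)[k],
             " is infeasible under the transition mask")
      pool <- which(valid & matrix(grid %in% donors, nrow(grid), ncol(grid)))
      take <- min(deficit[k], length(pool))
      pick <- pool[sample.int(length(pool), take)]
      grid[pick] <- k
    }
  })
  out <- map_t0
  out$grid <- grid
  out
}
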