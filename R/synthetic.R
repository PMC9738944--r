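# Synthetic two-epoch landscapes with planted driver effects.
#
# Every generator is a pure function of its arguments plus an explicit seed;
# no global random state is consumed (the caller's RNG state is restored).

#' Generate a spatially autocorrelated class map
#'
#' A smooth Gaussian random field (iterated box blur of white noise) is
#' thresholded at the class-fraction quantiles: the lowest-valued cells get
#' the first class in `class_fractions`, and so on. Realised class counts
#' follow largest-remainder apportionment of the fractions, so realised
#' shares match the targets to within one cell. Spatial clustering (Moran's
#' I) increases with `autocorrelation_scale`.
#'
#' @param shape integer vector `c(rows, cols)`, at least 10 x 10.
#' @param class_fractions named numeric vector of target shares (names from
#'   `names(CLASS_CODES)`), non-negative, summing to 1 within 1e-9.
#' @param autocorrelation_scale smoothing length in cells (0 = white noise).
#' @param seed integer seed.
#' @param cell_area km^2 per cell.
#' @return A [class_map()] with no nodata cells.
#' @export
generate_landscape <- function(shape, class_fractions,
                               autocorrelation_scale = 5, seed = 1,
                               cell_area = 1) {
  stopifnot(length(shape) == 2, all(shape >= 10))
  if (any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must be non-negative and sum to 1")
  codes <- CLASS_CODES[names(class_fractions)]
  if (anyNA(codes)) stop("unknown class name in class_fractions")
  n <- prod(shape)
  field <- with_seed(seed, {
    f <- matrix(stats::rnorm(n), shape[1], shape[2])
    f <- smooth_field(f, autocorrelation_scale)
    f + matrix(stats::runif(n, -1e-9, 1e-9), shape[1], shape[2]) # break ties
  })
  counts <- largest_remainder(class_fractions, n)
  ord <- order(field)
  grid <- integer(n)
  grid[ord] <- rep(codes, counts)
  class_map(matrix(grid, shape[1], shape[2]), cell_area = cell_area)
}

#' Generate driver layers with planted class effects
#'
#' Each driver is a class-dependent mean shift plus smooth unit-variance
#' noise: value = shift[class(cell)] + noise. With `strength` (the shift, in
#' noise standard deviations) around 2, the planted direction is recoverable
#' by a point-biserial correlation well above 0.3; strength 0 gives a driver
#' uncorrelated with the classes.
#'
#' @param map companion [class_map()].
#' @param driver_specs list of specs, each a list with `name`, optional
#'   `affinity` (named numeric, mean shift per class name) and optional
#'   `scale` (noise smoothing length in cells, default 3).
#' @param seed integer seed.
#' @return A [driver_stack()] aligned with `map`; nodata cells are `NA`.
#' @export
generate_drivers <- function(map, driver_specs, seed = 1) {
  stopifnot(inherits(map, "class_map"))
  if (length(driver_specs) == 0) stop("driver_specs must not be empty")
  d <- dim(map$grid)
  layers <- with_seed(seed, {
    lapply(driver_specs, function(sp) {
      noise <- matrix(stats::rnorm(prod(d)), d[1], d[2])
      noise <- smooth_field(noise, sp$scale %||% 3)
      noise <- noise / stats::sd(noise)
      shift <- numeric(max(CLASS_CODES))
      if (!is.null(sp$affinity)) {
        cc <- CLASS_CODES[names(sp$affinity)]
        if (anyNA(cc)) stop("unknown class name in affinity of ", sp$name)
        shift[cc] <- sp$affinity
      }
      g <- map$grid
      layer <- matrix(0, d[1], d[2])
      ok <- valid_mask(map)
      layer[ok] <- shift[g[ok]]
      layer <- layer + noise
      layer[!ok] <- NA_real_
      layer
    })
  })
  names(layers) <- vapply(driver_specs, `[[`, character(1), "name")
  driver_stack(layers)
}

resolve_class <- function(x) {
  if (is.character(x)) {
    cc <- CLASS_CODES[x]
    if (anyNA(cc)) stop("unknown class name: ", x)
    unname(cc)
  } else as.integer(x)
}

#' Evolve a landscape under known conversion rules
#'
#' Applies an ordered list of class-to-class conversions with exact cell
#' counts. For each move, the converted cells are the source cells with the
#' highest affinity score (a weighted sum of z-scored driver layers), ties
#' broken by a seeded shuffle, so downstream stages have exact expectations:
#' the transition matrix of (t0, t1) reproduces the planted counts and the
#' expansion cells sit where the steering drivers say. Stochastic placement
#' (sampling proportional to exp(score)) is available for stress tests.
#'
#' @param map_t0 starting [class_map()].
#' @param drivers aligned [driver_stack()] (may be `NULL` if no move uses an
#'   affinity).
#' @param moves list of moves, each a list with `from`, `to` (class name or
#'   code), `count` (cells) and optional `affinity` (named weights over
#'   driver layers).
#' @param seed integer seed (tie-breaking / stochastic placement).
#' @param allowed optional 6 x 6 0/1 mask; a move with `allowed[from,to]==0`
#'   is an error.
#' @param stochastic if `TRUE`, sample conversion cells with probability
#'   proportional to `exp(score)` instead of taking the top-count.
#' @return The evolved [class_map()] (same shape, cell_area, nodata mask).
#' @export
evolve_landscape <- function(map_t0, drivers = NULL, moves = list(),
                             seed = 1, allowed = NULL, stochastic = FALSE) {
  stopifnot(inherits(map_t0, "class_map"))
  if (!is.null(drivers)) stop_unless_aligned(map = map_t0, drv = drivers)
  grid <- map_t0$grid
  zlayers <- if (!is.null(drivers))
    lapply(drivers$layers, function(l) {
      mu <- mean(l, na.rm = TRUE); s <- stats::sd(l, na.rm = TRUE)
      if (s == 0) s <- 1
      (l - mu) / s
    }) else list()
  with_seed(seed, {
    for (mv in moves) {
      from <- resolve_class(mv$from); to <- resolve_class(mv$to)
      if (!is.null(allowed) && allowed[from, to] == 0)
        stop("move ", from, "->", to, " violates the transition mask")
      src <- which(grid == from)
      if (mv$count > length(src))
        stop("move ", from, "->", to, ": requested ", mv$count,
             " cells but only ", length(src), " available")
      if (mv$count == 0) next
      score <- numeric(length(src))
      if (!is.null(mv$affinity)) {
        for (dn in names(mv$affinity)) {
          if (is.null(zlayers[[dn]])) stop("no driver layer named ", dn)
          score <- score + mv$affinity[[dn]] * zlayers[[dn]][src]
        }
      }
      pick <- if (stochastic) {
        src[sample.int(length(src), mv$count, prob = exp(score - max(score)))]
      } else {
        src[order(-score, sample.int(length(src)))[seq_len(mv$count)]]
      }
      grid[pick] <- to
    }
  })
  out <- map_t0
  out$grid <- grid
  out
}

#' Generate a region-by-indicator table with known structure
#'
#' @param n_regions number of regions (>= 2; the entropy normaliser
#'   k = 1/ln(n) is undefined for one region).
#' @param indicator_specs list of specs, each a list with `name`,
#'   `orientation` (`"positive"`/`"negative"`), optional `mean` and `sd`.
#' @param seed integer seed.
#' @param dominant optional region index planted to be best on every
#'   indicator (max for positive, min for negative), pinning the composite
#'   score ordering.
#' @return List with `values` (data.frame, `region` column first) and
#'   `orientations` (named character vector), the layout
#'   [read_indicator_table()] returns.
#' @export
generate_indicator_table <- function(n_regions, indicator_specs, seed = 1,
                                     dominant = NULL) {
  if (n_regions < 2) stop("need at least 2 regions")
  if (length(indicator_specs) < 1) stop("need at least one indicator")
  vals <- with_seed(seed, {
    sapply(indicator_specs, function(sp) {
      x <- stats::rnorm(n_regions, sp$mean %||% 0, sp$sd %||% 1)
      if (!is.null(dominant)) {
        best <- if ((sp$orientation %||% "positive") == "positive")
          max(x) + abs(sp$sd %||% 1) else min(x) - abs(sp$sd %||% 1)
        x[dominant] <- best
      }
      x
    })
  })
  vals <- matrix(vals, nrow = n_regions)
  nm <- vapply(indicator_specs, `[[`, character(1), "name")
  colnames(vals) <- nm
  ors <- vapply(indicator_specs,
                function(sp) sp$orientation %||% "positive", character(1))
  list(values = data.frame(region = paste0("region_", seq_len(n_regions)),
                           vals, check.names = FALSE),
       orientations = stats::setNames(ors, nm))
}

#' A complete synthetic case-study fixture
#'
#' Generates the study conditions every downstream stage is tested on: a
#' two-epoch landscape whose class shares mirror the Guizhou 2020 composition
#' (farmland 0.2742, forest 0.5283, grassland 0.1771, aquatic 0.0068,
#' settlement 0.0134, other 0.0002), six drivers with planted effects
#' (elevation favouring forest, GDP/population/road access favouring
#' settlement, slope disfavouring it), and a t0 -> t1 evolution whose
#' conversion counts are the observed decade's province-wide flows scaled to
#' the grid size, steered by those same drivers.
#'
#' @param seed integer seed driving all three generators.
#' @param shape grid shape (default 200 x 200).
#' @return List with `t0`, `t1` ([class_map()]s), `drivers`
#'   ([driver_stack()]), `moves` (the planted conversion list), `density`
#'   (the bundled density table) and `allowed` (transition mask freezing
#'   aquatic and settlement cells, as in the case study).
#' @export
synthetic_case_study <- function(seed = 1, shape = c(200, 200)) {
  fractions <- c(farmland = 0.2742, forest = 0.5283, grassland = 0.1771,
                 aquatic = 0.0068, settlement = 0.0134, other = 0.0002)
  t0 <- generate_landscape(shape, fractions, autocorrelation_scale = 6,
                           seed = seed)
  specs <- list(
    list(name = "elevation", affinity = c(forest = 1.5, grassland = 0.5),
         scale = 6),
    list(name = "slope", affinity = c(settlement = -1.5, farmland = -0.5),
         scale = 4),
    list(name = "gdp", affinity = c(settlement = 2.0), scale = 4),
    list(name = "population", affinity = c(settlement = 1.5, farmland = 0.5),
         scale = 4),
    list(name = "precipitation", affinity = c(forest = 0.5), scale = 8),
    list(name = "dist_road", affinity = c(settlement = -2.0), scale = 5))
  drivers <- generate_drivers(t0, specs, seed = seed + 1L)
  # decade flows scaled from the observed province-wide transfers
  sc <- prod(shape) / 176098
  f <- function(x) max(1L, as.integer(round(x * sc)))
  moves <- list(
    list(from = "farmland", to = "forest", count = f(1649),
         affinity = c(elevation = 1, precipitation = 0.5)),
    list(from = "farmland", to = "grassland", count = f(614),
         affinity = c(elevation = 0.5)),
    list(from = "forest", to = "farmland", count = f(1677),
         affinity = c(elevation = -1, slope = -0.5)),
    list(from = "forest", to = "grassland", count = f(677),
         affinity = c(precipitation = -1)),
    list(from = "grassland", to = "farmland", count = f(599),
         affinity = c(slope = -1)),
    list(from = "grassland", to = "forest", count = f(608),
         affinity = c(elevation = 1)),
    list(from = "farmland", to = "settlement", count = f(1500),
         affinity = c(gdp = 1.5, population = 1, dist_road = -1.5)),
    list(from = "grassland", to = "settlement", count = f(236),
         affinity = c(gdp = 1.5, dist_road = -1.5)),
    list(from = "farmland", to = "aquatic", count = f(704),
         affinity = c(slope = -1)))
  allowed <- matrix(1L, 6, 6,
                    dimnames = list(names(CLASS_CODES), names(CLASS_CODES)))
  allowed["aquatic", -4] <- 0L     # water is not allowed to convert
  allowed["settlement", -5] <- 0L  # construction land is not allowed to convert
  t1 <- evolve_landscape(t0, drivers, moves, seed = seed + 2L,
                         allowed = allowed)
  list(t0 = t0, t1 = t1, drivers = drivers, moves = moves,
       density = guizhou_carbon_density(), allowed = allowed)
}

#' Write a full synthetic input bundle to disk
#'
#' Emits everything the command-line pipeline needs: two class-map ASCII
#' grids, one ASCII grid per driver, the density CSV, an indicator CSV with
#' an orientation row, and a YAML run config pointing at them all.
#'
#' @param dir output directory (created).
#' @param seed integer seed passed to [synthetic_case_study()].
#' @param shape grid shape.
#' @return The config path, invisibly.
#' @export
write_fixture_bundle <- function(dir, seed = 1, shape = c(60, 60)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- synthetic_case_study(seed = seed, shape = shape)
  write_class_map(cs$t0, file.path(dir, "t0.asc"))
  write_class_map(cs$t1, file.path(dir, "t1.asc"))
  write_driver_stack(cs$drivers, file.path(dir, "drivers"))
  file.copy(system.file("extdata", "guizhou_carbon_density.csv",
                        package = "carbonscape", mustWork = TRUE),
            file.path(dir, "density.csv"), overwrite = TRUE)
  it <- generate_indicator_table(
    9, lapply(paste0("ind", 1:6), function(nm)
      list(name = nm,
           orientation = if (nm %in% c("ind5", "ind6")) "negative"
                         else "positive")),
    seed = seed)
  orow <- data.frame(region = "orientation", as.list(unname(it$orientations)),
                     check.names = FALSE)
  names(orow) <- names(it$values)
  vrow <- it$values
  vrow[-1L] <- lapply(vrow[-1L], as.character)
  utils::write.csv(rbind(orow, vrow), file.path(dir, "indicators.csv"),
                   row.names = FALSE)
  cfg <- list(t0 = "t0.asc", t1 = "t1.asc",
              drivers = "drivers",
              density_table = "density.csv",
              indicator_table = "indicators.csv",
              out_dir = "out",
              horizons = list(1L),
              sampling_rate = 1.0,
              seed = as.integer(seed),
              ca = list(neighborhood_size = 3L, patch_decay = 0.5,
                        expansion_coeff = 0.5, seed_fraction = 0.05,
                        demand_tolerance = 0L, max_rounds = 300L))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
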