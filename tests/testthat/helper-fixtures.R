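# Fixtures are built in code at test time; nothing is read from disk except
# the package's own bundled reference tables.

# A deterministic 30 x 30 epoch pair with known conversions and a nodata
# border cell, for transition/carbon/LEAS contract cases.
small_pair <- function(n_convert = 50, nodata_cells = 3) {
  grid <- matrix(rep(c(1L, 2L, 3L), length.out = 900), 30, 30)
  grid[seq_len(nodata_cells)] <- 0L
  t0 <- class_map(grid)
  g1 <- grid
  src <- which(grid == 1L)
  g1[src[seq_len(n_convert)]] <- 5L
  t1 <- class_map(g1)
  list(t0 = t0, t1 = t1)
}

# Landscape with one strongly planted settlement driver and a planted
# settlement expansion steered by it; used for planted-effect recovery.
leas_fixture <- function(seed, shape = c(60, 60), n_expand = 120,
                         strength = 2.5) {
  fr <- c(farmland = 0.45, forest = 0.35, grassland = 0.15,
          settlement = 0.05)
  t0 <- generate_landscape(shape, fr, autocorrelation_scale = 4, seed = seed)
  drivers <- generate_drivers(t0, list(
    list(name = "gdp", affinity = c(settlement = strength), scale = 3),
    list(name = "elevation", affinity = c(forest = 0.5), scale = 5),
    list(name = "noise1", scale = 3),
    list(name = "noise2", scale = 3)), seed = seed + 1L)
  t1 <- evolve_landscape(t0, drivers, list(
    list(from = "farmland", to = "settlement", count = n_expand,
         affinity = c(gdp = 1))), seed = seed + 2L)
  list(t0 = t0, t1 = t1, drivers = drivers)
}

expect_map_equal <- function(a, b) {
  expect_identical(a$grid, b$grid)
  expect_equal(a$cell_area, b$cell_area)
  expect_identical(a$nodata, b$nodata)
}

read_asc_matrix <- function(path) {
  r <- carbonscape:::read_asc(path)
  g <- r$grid
  g[g == r$nodata] <- NA
  g
}
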