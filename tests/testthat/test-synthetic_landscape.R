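test_that("landscape generation is a pure function of its arguments and seed", {
  fr <- c(farmland = 0.3, forest = 0.5, grassland = 0.2)
  a <- generate_landscape(c(40, 40), fr, 4, seed = 9)
  b <- generate_landscape(c(40, 40), fr, 4, seed = 9)
  expect_identical(a$grid, b$grid)
  c2 <- generate_landscape(c(40, 40), fr, 4, seed = 10)
  expect_false(identical(a$grid, c2$grid))
})

test_that("degenerate and invalid fraction specs are handled", {
  m <- generate_landscape(c(12, 12), c(forest = 1.0), seed = 1)
  expect_true(all(m$grid == CLASS_CODES["forest"]))
  expect_error(generate_landscape(c(12, 12), c(forest = 0.5, other = 0.4)),
               "sum to 1")
  expect_error(generate_landscape(c(5, 5), c(forest = 1.0)))
})

test_that("realised shares hit the Guizhou 2020 composition targets", {
  fr <- c(farmland = 0.2742, forest = 0.5283, grassland = 0.1771,
          aquatic = 0.0068, settlement = 0.0134, other = 0.0002)
  m <- generate_landscape(c(200, 200), fr, 6, seed = 3)
  shares <- class_areas(m) / sum(class_areas(m))
  expect_true(all(abs(shares[names(fr)] - fr) < 0.02))
})

test_that("spatial clustering increases with the autocorrelation scale", {
  fr <- c(forest = 0.5, farmland = 0.5)
  mi <- sapply(c(1, 4, 8), function(sc) {
    m <- generate_landscape(c(80, 80), fr, sc, seed = 5)
    morans_i(matrix(as.numeric(m$grid == 2L), 80, 80))
  })
  expect_true(all(diff(mi) > 0))
})

test_that("drivers carry planted class effects of the requested strength", {
  fr <- c(farmland = 0.4, forest = 0.4, grassland = 0.2)
  m <- generate_landscape(c(100, 100), fr, 4, seed = 2)
  ds <- generate_drivers(m, list(
    list(name = "null", scale = 3),
    list(name = "elevation", affinity = c(forest = 2), scale = 3)),
    seed = 7)
  is_forest <- as.numeric(m$grid == 2L)
  r_null <- cor(as.vector(ds$layers$null), is_forest)
  r_elev <- cor(as.vector(ds$layers$elevation), is_forest)
  expect_lt(abs(r_null), 0.1)
  expect_gt(r_elev, 0.3)
  expect_gt(mean(ds$layers$elevation[m$grid == 2L]),
            mean(ds$layers$elevation[m$grid != 2L]))
  expect_error(generate_drivers(m, list()), "empty")
})

test_that("evolution plants exact transition counts and conserves the mask", {
  fr <- c(farmland = 0.5, forest = 0.3, grassland = 0.2)
  t0 <- generate_landscape(c(50, 50), fr, 3, seed = 4)
  t0$grid[1:5] <- 0L  # nodata corner
  ds <- generate_drivers(t0, list(
    list(name = "gdp", affinity = c(settlement = 2), scale = 3)), seed = 5)

  same <- evolve_landscape(t0, ds, list(), seed = 1)
  expect_map_equal(same, t0)

  t1 <- evolve_landscape(t0, ds, list(
    list(from = "farmland", to = "settlement", count = 50,
         affinity = c(gdp = 1))), seed = 1)
  tm <- transition_matrix(t0, t1)
  expect_equal(tm["farmland", "settlement"], 50)
  expect_equal(sum(tm) + 5 * t0$cell_area,
               prod(dim(t0$grid)) * t0$cell_area)
  expect_identical(which(t1$grid == 0L), which(t0$grid == 0L))

  # steered conversions sit on high-affinity source cells
  conv <- t0$grid == 1L & t1$grid == 5L
  stay <- t0$grid == 1L & t1$grid == 1L
  expect_gt(mean(ds$layers$gdp[conv]), mean(ds$layers$gdp[stay]))

  expect_error(evolve_landscape(t0, ds, list(
    list(from = "other", to = "forest", count = 10))), "available")
  allowed <- diag(6); allowed[1, 5] <- 0
  expect_error(evolve_landscape(t0, ds, list(
    list(from = "farmland", to = "settlement", count = 1)),
    allowed = allowed), "mask")
})

test_that("carbon accounting reproduces planted transitions exactly", {
  fr <- c(farmland = 0.5, forest = 0.3, grassland = 0.2)
  t0 <- generate_landscape(c(40, 40), fr, 3, seed = 6)
  moves <- list(list(from = "farmland", to = "forest", count = 30),
                list(from = "grassland", to = "farmland", count = 12))
  t1 <- evolve_landscape(t0, NULL, moves, seed = 2)
  dens <- guizhou_carbon_density()
  ct <- setNames(dens$c_tot, dens$class_name)
  expected <- 30 * (ct["forest"] - ct["farmland"]) * 100 +
    12 * (ct["farmland"] - ct["grassland"]) * 100
  expect_equal(sum(carbon_change_map(t0, t1, dens), na.rm = TRUE),
               unname(expected))
})

test_that("indicator tables support planted dominance and degenerate rows", {
  specs <- list(list(name = "a", orientation = "positive"),
                list(name = "b", orientation = "negative"))
  it <- generate_indicator_table(5, specs, seed = 3, dominant = 2)
  expect_equal(which.max(it$values$a), 2L)
  expect_equal(which.min(it$values$b), 2L)
  res <- sustainability_index(it$values, it$orientations)
  expect_equal(which.max(res$scores$score), 2L)
  expect_error(generate_indicator_table(1, specs), "2 regions")
})
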