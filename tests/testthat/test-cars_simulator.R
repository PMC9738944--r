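test_that("neighbourhood effect counts window fractions, centre excluded", {
  g <- matrix(1L, 5, 5)
  g[3, 3] <- 2L
  m <- class_map(g)
  om <- neighborhood_effect(m, "farmland")
  expect_equal(om[3, 3], 1)          # fully surrounded by farmland
  om2 <- neighborhood_effect(m, "forest")
  expect_equal(om2[3, 3], 0)         # centre excluded from its own count
  expect_equal(om2[2, 2], 1 / 8)

  # hand-enumerated: 3 forest cells among the 8 neighbours
  g3 <- matrix(1L, 3, 3)
  g3[1, 1] <- 2L; g3[1, 2] <- 2L; g3[2, 1] <- 2L
  expect_equal(neighborhood_effect(class_map(g3), "forest")[2, 2], 0.375)

  # truncated window at a corner: 3 neighbours
  expect_equal(neighborhood_effect(class_map(g3), "forest")[3, 3], 0)
  expect_equal(neighborhood_effect(class_map(g3), "farmland")[1, 1], 1 / 3)

  # nodata excluded from numerator and denominator
  g4 <- matrix(1L, 3, 3); g4[1, 1] <- 0L; g4[1, 2] <- 2L
  expect_equal(neighborhood_effect(class_map(g4), "forest")[2, 2], 1 / 7)

  expect_error(neighborhood_effect(m, 1, window = 4), "odd")
  expect_error(ca_config(neighborhood_size = 4))
})

make_sim_fixture <- function(seed = 21, shape = c(80, 80)) {
  cs <- synthetic_case_study(seed = seed, shape = shape)
  tm <- transition_matrix(cs$t0, cs$t1)
  samples <- lapply(CLASS_CODES[1:5], function(k)
    suppressWarnings(extract_expansion(cs$t0, cs$t1, k, sampling_rate = 1,
                                       seed = seed)))
  samples <- Filter(function(s) s$n_expansion > 0, samples)
  suit <- suppressWarnings(fit_suitability(samples, cs$drivers, cs$t0,
                                           seed = seed))
  c(cs, list(tm = tm, suit = suit,
             weights = expansion_share_weights(tm)))
}

fx <- make_sim_fixture()

test_that("null demand leaves the map untouched", {
  cfg <- ca_config(rng_seed = 1)
  res <- simulate_ca(fx$t0, fx$suit, class_counts(fx$t0), cfg)
  expect_identical(res$map$grid, fx$t0$grid)
  expect_equal(res$rounds, 0L)
  expect_true(res$converged)
})

test_that("demand is met exactly, conserving cells and the mask", {
  cfg <- ca_config(allowed = fx$allowed, domain_weights = fx$weights,
                   rng_seed = 7)
  dem <- class_counts(fx$t1)
  res <- simulate_ca(fx$t0, fx$suit, dem, cfg)
  expect_true(res$converged)
  expect_equal(res$achieved, dem)                       # tolerance 0
  expect_equal(sum(class_counts(res$map)), sum(class_counts(fx$t0)))
  expect_equal(sum(res$realized_flows[fx$allowed == 0]), 0)
  # frozen classes are bit-identical
  frozen <- fx$t0$grid %in% c(4L, 5L)
  expect_identical(res$map$grid[frozen], fx$t0$grid[frozen])
})

test_that("simulation is seed-deterministic and genuinely stochastic", {
  cfg <- ca_config(allowed = fx$allowed, domain_weights = fx$weights,
                   rng_seed = 42)
  dem <- class_counts(fx$t1)
  a <- simulate_ca(fx$t0, fx$suit, dem, cfg)
  b <- simulate_ca(fx$t0, fx$suit, dem, cfg)
  expect_identical(a$map$grid, b$map$grid)
  cfg2 <- cfg; cfg2$rng_seed <- 43L
  c2 <- simulate_ca(fx$t0, fx$suit, dem, cfg2)
  expect_false(identical(a$map$grid, c2$map$grid))
  expect_lt(agreement(a$map, c2$map)$kappa, 1)
})

test_that("infeasible demand under the mask names the blocked class", {
  allowed <- diag(6)
  diag(allowed) <- 1
  cfg <- ca_config(allowed = allowed, rng_seed = 1)
  dem <- class_counts(fx$t0)
  moveable <- which(dem > 10)[1]
  target <- which(names(dem) == "aquatic")
  dem[moveable] <- dem[moveable] - 10L
  dem["aquatic"] <- dem["aquatic"] + 10L
  expect_error(simulate_ca(fx$t0, fx$suit, dem, cfg), "aquatic")
})

test_that("demand totals must match the valid cell count", {
  dem <- class_counts(fx$t0)
  dem[1] <- dem[1] + 5L
  expect_error(simulate_ca(fx$t0, fx$suit, dem, ca_config()), "valid cell")
})

test_that("the projection pipeline composes and satisfies each horizon", {
  cs <- synthetic_case_study(seed = 31, shape = c(60, 60))
  cfg <- ca_config(allowed = cs$allowed, rng_seed = 3)
  none <- suppressWarnings(run_projection(cs$t0, cs$t1, cs$drivers, cs$density, cfg,
                         steps = integer(0), sampling_rate = 1, seed = 5))
  expect_length(none$horizons, 0)
  expect_s3_class(none$model, "markov_model")
  expect_equal(sum(none$weights), 1)

  proj <- suppressWarnings(run_projection(cs$t0, cs$t1, cs$drivers, cs$density, cfg,
                         steps = c(1, 2), sampling_rate = 1, seed = 5))
  for (h in proj$horizons) {
    expect_true(h$result$converged)
    expect_equal(unname(h$result$achieved),
                 h$demand$target_cells)
    expect_equal(h$summary$area_km2[7], sum(class_areas(cs$t1)))
  }
  # settlement frozen + fed by others => non-decreasing across horizons
  sett <- sapply(proj$horizons, function(h) h$result$achieved["settlement"])
  expect_true(all(diff(sett) >= 0))
})
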