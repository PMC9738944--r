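test_that("expansion extraction finds exactly the planted cells", {
  p <- small_pair(n_convert = 50)
  s <- extract_expansion(p$t0, p$t1, "settlement", sampling_rate = 1)
  expect_equal(s$n_expansion, 50)
  expect_setequal(s$all_positives,
                  which(p$t0$grid != 5L & p$t1$grid == 5L & p$t0$grid != 0L))
  # positives never include cells already of class k at t0
  expect_length(intersect(s$all_positives, which(p$t0$grid == 5L)), 0)
  # negatives are never-class-k cells
  expect_true(all(p$t0$grid[s$all_negatives] != 5L &
                    p$t1$grid[s$all_negatives] != 5L))

  expect_warning(extract_expansion(p$t0, p$t0, "settlement"), "no expansion")

  sub <- extract_expansion(p$t0, p$t1, "settlement", sampling_rate = 0.1,
                           seed = 3)
  expect_true(all(sub$positives %in% s$all_positives))
  expect_true(all(sub$negatives %in% s$all_negatives))
  expect_lt(length(sub$positives), s$n_expansion)
})

test_that("an uninformative constant driver yields a flat surface", {
  fx <- leas_fixture(seed = 11)
  flat <- driver_stack(list(konst = matrix(1, 60, 60)))
  s <- extract_expansion(fx$t0, fx$t1, "settlement", sampling_rate = 1)
  suit <- fit_suitability(list(s), flat, fx$t1, seed = 1)
  surf <- suit$surfaces$settlement
  expect_lt(max(surf, na.rm = TRUE) - min(surf, na.rm = TRUE), 0.05)
})

test_that("a strongly planted driver dominates the contributions", {
  fx <- leas_fixture(seed = 12)
  s <- extract_expansion(fx$t0, fx$t1, "settlement", sampling_rate = 1)
  suit <- fit_suitability(list(s), fx$drivers, fx$t1, seed = 2)
  ct <- suit$contributions$settlement
  expect_equal(names(which.max(ct)), "gdp")
  expect_gt(ct["gdp"], 0.5)
  expect_equal(sum(ct), 1)
  expect_true(all(suit$surfaces$settlement >= 0 &
                    suit$surfaces$settlement <= 1, na.rm = TRUE))
})

test_that("a separable planted driver trains to high accuracy", {
  fx <- leas_fixture(seed = 13, strength = 4)
  s <- extract_expansion(fx$t0, fx$t1, "settlement", sampling_rate = 1)
  suit <- fit_suitability(list(s), fx$drivers, fx$t1, seed = 3)
  surf <- suit$surfaces$settlement
  pos <- s$all_positives
  neg <- withr::with_seed(4, sample(s$all_negatives, length(pos)))
  acc <- mean(c(surf[pos] > 0.5, surf[neg] <= 0.5))
  expect_gt(acc, 0.95)
})

test_that("suitability is invariant to driver-layer ordering", {
  fx <- leas_fixture(seed = 14)
  s <- extract_expansion(fx$t0, fx$t1, "settlement", sampling_rate = 1)
  a <- fit_suitability(list(s), fx$drivers, fx$t1, seed = 5)
  rev_stack <- driver_stack(rev(fx$drivers$layers))
  b <- fit_suitability(list(s), rev_stack, fx$t1, seed = 5)
  expect_equal(a$surfaces$settlement, b$surfaces$settlement)
})

test_that("classes with too few samples fall back to a flat 0.5 surface", {
  fx <- leas_fixture(seed = 15, n_expand = 5)
  s <- extract_expansion(fx$t0, fx$t1, "settlement", sampling_rate = 1)
  expect_warning(suit <- fit_suitability(list(s), fx$drivers, fx$t1),
                 "too few")
  expect_false(suit$fitted["settlement"])
  expect_equal(unique(na.omit(as.vector(suit$surfaces$settlement))), 0.5)
})

test_that("mtry follows the two-thirds rule below nine drivers", {
  expect_equal(carbonscape:::rf_mtry(13), 9L)
  expect_equal(carbonscape:::rf_mtry(9), 9L)
  expect_equal(carbonscape:::rf_mtry(6), 4)
  expect_equal(carbonscape:::rf_mtry(1), 1)
  expect_equal(carbonscape:::rf_mtry(13, mtry = 5), 5)
})

test_that("domain weights follow expansion shares or are stored verbatim", {
  counts <- matrix(0, 6, 6); diag(counts) <- 100
  counts[1, 2] <- 30; counts[3, 2] <- 0; counts[1, 3] <- 10
  w <- expansion_share_weights(counts)
  expect_equal(unname(w[c("forest", "grassland")]), c(0.75, 0.25))
  expect_equal(sum(w), 1)

  one <- matrix(0, 6, 6); one[2, 5] <- 7
  w1 <- expansion_share_weights(one)
  expect_equal(unname(w1["settlement"]), 1)

  given <- guizhou_domain_weights()
  wg <- expansion_share_weights(basis = "given", given = given)
  expect_identical(unname(wg), unname(given))
  expect_equal(sum(wg), 0.4258)  # published vector kept unnormalised
  expect_error(expansion_share_weights(diag(6) * 5), "zero total")
})
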