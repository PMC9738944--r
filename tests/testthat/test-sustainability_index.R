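test_that("standardisation maps endpoints by orientation, both forms", {
  v <- data.frame(region = c("A", "B"), x = c(10, 20), y = c(10, 20))
  ors <- c(x = "positive", y = "negative")
  conv <- standardize(v, ors)
  expect_equal(unname(conv$S[, "x"]), c(0, 1))   # positive: larger is better
  expect_equal(unname(conv$S[, "y"]), c(1, 0))   # negative: larger is worse
  lit <- standardize(v, ors, form = "as_printed")
  expect_equal(unname(lit$S[, "x"]), c(1, 0))    # literal form is swapped
  expect_equal(unname(lit$S[, "y"]), c(0, 1))

  cst <- data.frame(region = c("A", "B"), x = c(5, 5), y = c(1, 2))
  expect_warning(s <- standardize(cst, ors), "constant")
  expect_equal(unname(s$S[, "x"]), c(0.5, 0.5))
  expect_error(standardize(v[1, ], ors), "2 regions")
})

test_that("entropy hits its analytic extremes and the hand-worked value", {
  std <- structure(list(S = cbind(uniform = rep(0.2, 5),
                                  onehot = c(1, 0, 0, 0, 0)),
                        region = paste0("r", 1:5)),
                   class = "standardized_table")
  e <- indicator_entropy(std)
  expect_equal(unname(e["uniform"]), 1)
  expect_equal(unname(e["onehot"]), 0)

  std3 <- structure(list(S = cbind(a = c(0.5, 0.3, 0.2)),
                         region = paste0("r", 1:3)),
                    class = "standardized_table")
  hand <- -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)) / log(3)
  expect_equal(unname(indicator_entropy(std3)["a"]), hand)
  expect_equal(hand, 0.9372, tolerance = 1e-4)

  zero <- structure(list(S = cbind(z = c(0, 0, 0)), region = paste0("r", 1:3)),
                    class = "standardized_table")
  expect_warning(ez <- indicator_entropy(zero), "all-zero")
  expect_equal(unname(ez["z"]), 1)
})

test_that("weights are normalised information gains", {
  expect_equal(unname(entropy_weights(c(a = 0.9, b = 0.8))), c(1 / 3, 2 / 3))
  expect_equal(unname(entropy_weights(c(a = 0.5, b = 0.5))), c(0.5, 0.5))
  e13 <- withr::with_seed(8, runif(13, 0.2, 0.99))
  w <- entropy_weights(e13)
  expect_equal(sum(w), 1)
  expect_equal(unname(w), (1 - e13) / sum(1 - e13))  # brute-force oracle
  expect_warning(we <- entropy_weights(c(a = 1, b = 1)), "equal weights")
  expect_equal(unname(we), c(0.5, 0.5))
})

test_that("a dominating region scores 1 and identical regions tie", {
  specs <- lapply(1:4, function(i)
    list(name = paste0("i", i),
         orientation = if (i %% 2) "positive" else "negative"))
  it <- generate_indicator_table(6, specs, seed = 5, dominant = 3)
  res <- sustainability_index(it$values, it$orientations)
  expect_equal(res$scores$score[3], 1)
  expect_true(all(res$scores$score[-3] < 1))
  expect_equal(sum(res$weights), 1)

  same <- it$values
  for (j in 2:5) same[[j]] <- 7
  suppressWarnings(res2 <- sustainability_index(same, it$orientations))
  expect_equal(var(res2$scores$score), 0)
})

test_that("a 3x2 worked table matches the spreadsheet-style oracle", {
  v <- data.frame(region = c("A", "B", "C"),
                  ind1 = c(10, 20, 40), ind2 = c(5, 3, 1))
  ors <- c(ind1 = "positive", ind2 = "negative")
  # independent hand computation through the full chain
  s1 <- (v$ind1 - 10) / 30
  s2 <- (5 - v$ind2) / 4
  r1 <- s1 / sum(s1); r2 <- s2 / sum(s2)
  ent <- function(r) { r <- r[r > 0]; -sum(r * log(r)) / log(3) }
  e <- c(ent(r1), ent(r2))
  w <- (1 - e) / sum(1 - e)
  oracle <- s1 * w[1] + s2 * w[2]

  res <- sustainability_index(v, ors)
  expect_equal(unname(res$weights), w)
  expect_equal(res$scores$score, oracle)
  expect_equal(res$scores$score[3], 1)  # C dominates both indicators
})

test_that("scores are invariant to affine rescaling of an indicator", {
  it <- generate_indicator_table(
    7, list(list(name = "a", orientation = "positive"),
            list(name = "b", orientation = "negative"),
            list(name = "c", orientation = "positive")), seed = 9)
  base <- sustainability_index(it$values, it$orientations)
  scaled <- it$values
  scaled$b <- scaled$b * 37.5 + 1000
  res <- sustainability_index(scaled, it$orientations)
  expect_equal(res$scores$score, base$scores$score)
  expect_equal(res$weights, base$weights)
})

test_that("improving a positive indicator never lowers that region's score", {
  it <- generate_indicator_table(
    6, list(list(name = "a", orientation = "positive"),
            list(name = "b", orientation = "negative")), seed = 10)
  base <- sustainability_index(it$values, it$orientations)
  for (i in c(1, 4, 6)) {
    up <- it$values
    up$a[i] <- up$a[i] + 0.5
    res <- sustainability_index(up, it$orientations)
    expect_gte(res$scores$score[i] - base$scores$score[i], -1e-12)
  }
})

test_that("score bands follow quantile classification", {
  it <- generate_indicator_table(
    9, list(list(name = "a", orientation = "positive"),
            list(name = "b", orientation = "positive")), seed = 11)
  res <- sustainability_index(it$values, it$orientations, bands = 4)
  expect_true(all(res$scores$band %in% 1:4))
  expect_equal(res$scores$band[which.max(res$scores$score)], 4L)
})
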