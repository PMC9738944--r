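# Internal helpers shared across modules.

# Run `code` under a temporary RNG state; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sliding-window sums over a w x w window (w odd), truncated at edges.
# Computed with a summed-area table: O(cells) regardless of w.
box_sum <- function(m, w) {
  stopifnot(w %% 2 == 1, w >= 1)
  nr <- nrow(m); nc <- ncol(m); h <- (w - 1L) %/% 2L
  sat <- matrix(0, nr + 1L, nc + 1L)
  cs <- apply(m, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = nr)
  sat[-1L, -1L] <- t(apply(cs, 1L, cumsum))
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  sat[r2 + 1L, c2 + 1L, drop = FALSE] -
    sat[r1, c2 + 1L, drop = FALSE] -
    sat[r2 + 1L, c1, drop = FALSE] +
    sat[r1, c1, drop = FALSE]
}

# Iterated box blur of a matrix; each pass averages over a (2*scale+1) window.
smooth_field <- function(m, scale, passes = 2L) {
  if (scale < 1) return(m)
  w <- 2L * as.integer(scale) + 1L
  ones <- matrix(1, nrow(m), ncol(m))
  denom <- box_sum(ones, w)
  for (i in seq_len(passes)) m <- box_sum(m, w) / denom
  m
}

# Largest-remainder apportionment of `total` integer units proportional to x.
largest_remainder <- function(x, total) {
  stopifnot(all(x >= 0), total >= 0)
  if (sum(x) == 0) {
    out <- integer(length(x))
    if (total > 0) out[1L] <- as.integer(total)
    return(out)
  }
  quota <- x / sum(x) * total
  base <- floor(quota)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    idx <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Half-up rounding to `digits` decimals (base round() is banker's rounding).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Moran's I spatial autocorrelation of a matrix (rook neighbours)
#'
#' A diagnostic used to verify that generated landscapes are spatially
#' clustered. Computed over the 4-neighbour (rook) graph with binary weights.
#'
#' @param m numeric matrix; `NA` cells are excluded together with their links.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(m) {
  stopifnot(is.matrix(m))
  mu <- mean(m, na.rm = TRUE)
  z <- m - mu
  zz <- z; zz[is.na(zz)] <- 0
  ok <- !is.na(m)
  nr <- nrow(m); nc <- ncol(m)
  num <- 0; wsum <- 0
  # vertical links
  a <- zz[-nr, , drop = FALSE] * zz[-1L, , drop = FALSE]
  va <- ok[-nr, , drop = FALSE] & ok[-1L, , drop = FALSE]
  num <- num + 2 * sum(a[va]); wsum <- wsum + 2 * sum(va)
  # horizontal links
  b <- zz[, -nc, drop = FALSE] * zz[, -1L, drop = FALSE]
  vb <- ok[, -nc, drop = FALSE] & ok[, -1L, drop = FALSE]
  num <- num + 2 * sum(b[vb]); wsum <- wsum + 2 * sum(vb)
  n <- sum(ok)
  denom <- sum(z[ok]^2)
  if (denom == 0 || wsum == 0) return(0)
  (n / wsum) * (num / denom)
}
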