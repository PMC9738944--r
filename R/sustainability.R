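# Entropy-weight multi-criteria sustainability scoring.
#
# Pipeline: orientation-aware min-max standardisation -> per-indicator
# information entropy of the standardised shares -> weights proportional to
# 1 - entropy -> weighted composite score per region. Two literal variants
# ("as_printed") are kept alongside the conventional forms; see the methods
# vignette for why the conventional orientation is the default.

#' Orientation-aware min-max standardisation
#'
#' Conventional form: positive indicators (larger is better) map to
#' (P - Pmin) / (Pmax - Pmin), negative indicators to
#' (Pmax - P) / (Pmax - Pmin), so 1 is always "best". The `as_printed` form
#' applies the formulas with the orientations swapped (some published
#' write-ups state them that way); it equals 1 minus the conventional form.
#' Constant columns (Pmax = Pmin) are set to 0.5 with a warning.
#'
#' @param values data.frame or matrix of regions x indicators; a character
#'   `region` column is carried through.
#' @param orientations named character vector, `"positive"` / `"negative"`
#'   per indicator (`"+"` / `"-"` also accepted).
#' @param form `"conventional"` (default) or `"as_printed"`.
#' @return List of class `standardized_table` with `S` (regions x indicators
#'   matrix in [0,1]) and `region` names.
#' @export
standardize <- function(values, orientations,
                        form = c("conventional", "as_printed")) {
  form <- match.arg(form)
  region <- NULL
  if (is.data.frame(values) && "region" %in% names(values)) {
    region <- values$region
    values <- values[setdiff(names(values), "region")]
  }
  m <- as.matrix(values)
  if (nrow(m) < 2) stop("need at least 2 regions to standardize")
  if (anyNA(m)) stop("indicator table contains missing values")
  ors <- orientations[colnames(m)]
  if (anyNA(ors)) stop("orientation missing for some indicator(s)")
  ors <- ifelse(ors %in% c("positive", "+"), "positive", "negative")
  S <- m
  for (j in seq_len(ncol(m))) {
    rng <- range(m[, j])
    if (diff(rng) == 0) {
      warning("indicator ", colnames(m)[j], " is constant; standardized to 0.5")
      S[, j] <- 0.5
      next
    }
    up <- (m[, j] - rng[1]) / diff(rng)
    conv <- if (ors[j] == "positive") up else 1 - up
    S[, j] <- if (form == "conventional") conv else 1 - conv
  }
  structure(list(S = S, region = region %||% rownames(m) %||%
                   paste0("region_", seq_len(nrow(m)))),
            class = "standardized_table")
}

#' Per-indicator information entropy
#'
#' S_j = -k * sum_i R_ij * ln(R_ij) with k = 1 / ln(n), where R_ij is
#' region i's share of indicator j's standardised column sum. Zero shares
#' contribute 0 (the 0 * ln 0 := 0 convention); an all-zero column gets
#' entropy 1 (maximal uncertainty) with a warning. A uniform column has
#' entropy exactly 1, a one-hot column exactly 0.
#'
#' @param std a `standardized_table` from [standardize()].
#' @return Named numeric vector of entropies in [0, 1].
#' @export
indicator_entropy <- function(std) {
  stopifnot(inherits(std, "standardized_table"))
  S <- std$S
  n <- nrow(S)
  if (n < 2) stop("entropy needs at least 2 regions")
  k <- 1 / log(n)
  apply(S, 2L, function(col) {
    tot <- sum(col)
    if (tot == 0) {
      warning("all-zero standardized column; entropy set to 1")
      return(1)
    }
    r <- col / tot
    r <- r[r > 0]
    -k * sum(r * log(r))
  })
}

#' Entropy weights
#'
#' W_j = (1 - S_j) / sum_j (1 - S_j): indicators with more cross-region
#' dispersion (lower entropy) weigh more. If every entropy is 1 the weights
#' are undefined; equal weights are returned with a warning.
#'
#' @param entropies named entropy vector from [indicator_entropy()].
#' @return Named weight vector summing to 1.
#' @export
entropy_weights <- function(entropies) {
  d <- 1 - entropies
  if (all(abs(d) < 1e-12)) {
    warning("all entropies equal 1; falling back to equal weights")
    return(stats::setNames(rep(1 / length(d), length(d)), names(entropies)))
  }
  d / sum(d)
}

#' Composite sustainability scores
#'
#' Default basis scores each region as the weighted sum of its standardised
#' values, E_i = sum_j S_ij W_j, which lies in [0, 1] and equals 1 only for
#' a region that is best on every indicator. The `as_printed` basis uses the
#' raw values P_ij instead (a scale-dependent literal variant).
#'
#' @param std a `standardized_table`.
#' @param weights weight vector from [entropy_weights()].
#' @param basis `"standardized"` (default) or `"as_printed"`.
#' @param raw raw values matrix, required for `basis = "as_printed"`.
#' @return data.frame with `region` and `score`.
#' @export
sustainability_scores <- function(std, weights,
                                  basis = c("standardized", "as_printed"),
                                  raw = NULL) {
  basis <- match.arg(basis)
  stopifnot(inherits(std, "standardized_table"))
  w <- weights[colnames(std$S)]
  stopifnot(!anyNA(w))
  M <- if (basis == "standardized") std$S else {
    if (is.null(raw)) stop("basis='as_printed' needs the raw value matrix")
    as.matrix(raw)[, colnames(std$S), drop = FALSE]
  }
  data.frame(region = std$region, score = as.numeric(M %*% w))
}

#' Entropy-weight evaluation in one call
#'
#' Runs [standardize()], [indicator_entropy()], [entropy_weights()] and
#' [sustainability_scores()] and optionally bands the scores into quantile
#' classes (the banding used for choropleth display).
#'
#' @param values regions x indicators data.frame (with a `region` column).
#' @param orientations named orientation vector.
#' @param form,basis passed through to the stages.
#' @param bands number of quantile bands to attach (0 = none).
#' @return List with `standardized`, `entropy`, `weights`, `scores`.
#' @export
sustainability_index <- function(values, orientations,
                                 form = "conventional",
                                 basis = "standardized", bands = 0) {
  std <- standardize(values, orientations, form = form)
  ent <- indicator_entropy(std)
  w <- entropy_weights(ent)
  raw <- if (is.data.frame(values) && "region" %in% names(values))
    values[setdiff(names(values), "region")] else values
  sc <- sustainability_scores(std, w, basis = basis, raw = raw)
  if (bands > 0) {
    br <- stats::quantile(sc$score, probs = seq(0, 1, length.out = bands + 1))
    sc$band <- cut(sc$score, breaks = unique(br), include.lowest = TRUE,
                   labels = FALSE)
  }
  list(standardized = std, entropy = ent, weights = w, scores = sc)
}
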