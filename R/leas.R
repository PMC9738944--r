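# Land Expansion Analysis Strategy: expansion sampling and random-forest
# development-probability surfaces.

#' Extract expansion samples for one class between two epochs
#'
#' Positives are cells that were not class k at t0 but are class k at t1
#' (the class's expansion); negatives are cells that are class k at neither
#' epoch. Both sets are randomly subsampled at `sampling_rate` (seeded);
#' rate 1 keeps everything. Cells nodata in either epoch are excluded.
#'
#' @param map_t0,map_t1 aligned [class_map()]s.
#' @param class_k class code or name.
#' @param sampling_rate fraction of each set kept (default 0.01).
#' @param seed integer seed.
#' @return List of class `expansion_sample` with `class_code`, cell indices
#'   `positives` / `negatives` (after subsampling), the full pre-subsampling
#'   sets `all_positives` / `all_negatives`, and `n_expansion`.
#' @export
extract_expansion <- function(map_t0, map_t1, class_k, sampling_rate = 0.01,
                              seed = 1) {
  stop_unless_aligned(t0 = map_t0, t1 = map_t1)
  stopifnot(sampling_rate > 0, sampling_rate <= 1)
  k <- resolve_class(class_k)
  ok <- valid_mask(map_t0) & valid_mask(map_t1)
  pos <- which(ok & map_t0$grid != k & map_t1$grid == k)
  neg <- which(ok & map_t0$grid != k & map_t1$grid != k)
  sub <- function(x, r) {
    if (length(x) == 0 || r >= 1) return(x)
    n <- max(1L, as.integer(round(r * length(x))))
    sort(x[sample.int(length(x), n)])
  }
  picked <- with_seed(seed, list(p = sub(pos, sampling_rate),
                                 n = sub(neg, sampling_rate)))
  if (length(pos) == 0)
    warning("class ", k, " has no expansion cells between the epochs")
  structure(list(class_code = k, positives = picked$p, negatives = picked$n,
                 all_positives = pos, all_negatives = neg,
                 n_expansion = length(pos)),
            class = "expansion_sample")
}

rf_mtry <- function(n_drivers, mtry = NULL) {
  if (!is.null(mtry)) return(min(mtry, n_drivers))
  if (n_drivers >= 9) 9L else max(1L, floor(2 * n_drivers / 3))
}

driver_frame <- function(drivers, idx) {
  as.data.frame(lapply(drivers$layers, function(l) l[idx]))
}

#' Fit per-class development-probability surfaces
#'
#' For each class with enough expansion samples, a random forest
#' (class-vote probability, impurity importance) is trained on the planted
#' positives against an equal number of randomly matched negatives, then
#' predicted over every valid cell to give the class's development
#' probability surface. Defaults follow common patch-generating-simulation
#' practice: 20 trees, mtry 9 when at least 9 drivers exist (otherwise
#' two-thirds of the driver count), sampling rate 0.01 at extraction time.
#' Classes with fewer than `min_samples` positives or negatives are skipped
#' with a warning and get a flat 0.5 surface.
#'
#' @param samples list of `expansion_sample`s (one per class to fit).
#' @param drivers [driver_stack()] supplying the features.
#' @param map [class_map()] giving the valid mask for prediction.
#' @param num_trees,mtry forest settings (see above).
#' @param min_samples minimum positives and negatives per fitted class.
#' @param seed integer seed (negative matching and forest growth).
#' @return List of class `suitability_stack`: `surfaces` (named list of
#'   probability matrices in [0,1]), `contributions` (driver importance per
#'   class, normalised to sum 1; `NA` for skipped classes), `fitted`
#'   (logical per class), `settings`.
#' @export
fit_suitability <- function(samples, drivers, map, num_trees = 20,
                            mtry = NULL, min_samples = 20, seed = 1) {
  stopifnot(inherits(drivers, "driver_stack"), inherits(map, "class_map"))
  stop_unless_aligned(map = map, drv = drivers)
  # canonical layer order makes the fit invariant to how the stack was built
  drivers$layers <- drivers$layers[order(names(drivers$layers))]
  d <- dim(map$grid)
  ok <- valid_mask(map)
  for (l in drivers$layers) ok <- ok & !is.na(l)
  valid_idx <- which(ok)
  pred_frame <- driver_frame(drivers, valid_idx)
  k_drivers <- length(drivers$layers)
  use_mtry <- rf_mtry(k_drivers, mtry)
  surfaces <- list(); contribs <- list(); fitted <- logical(0)
  for (s in samples) {
    nm <- names(CLASS_CODES)[s$class_code]
    pos <- intersect(s$positives, valid_idx)
    negpool <- intersect(s$negatives, valid_idx)
    if (length(pos) < min_samples || length(negpool) < min_samples) {
      warning("class ", nm, ": too few samples (", length(pos), " positives, ",
              length(negpool), " negatives); flat 0.5 surface used")
      surf <- matrix(NA_real_, d[1], d[2]); surf[ok] <- 0.5
      surfaces[[nm]] <- surf
      contribs[[nm]] <- stats::setNames(rep(NA_real_, k_drivers),
                                        names(drivers$layers))
      fitted[nm] <- FALSE
      next
    }
    neg <- with_seed(seed + s$class_code, {
      if (length(negpool) > length(pos))
        negpool[sample.int(length(negpool), length(pos))] else negpool
    })
    idx <- c(pos, neg)
    df <- driver_frame(drivers, idx)
    df$y <- factor(rep(c(1L, 0L), c(length(pos), length(neg))),
                   levels = c(0L, 1L))
    fit <- ranger::ranger(y ~ ., data = df, num.trees = num_trees,
                          mtry = use_mtry, probability = TRUE,
                          importance = "impurity",
                          seed = seed + s$class_code, num.threads = 1)
    pr <- stats::predict(fit, data = pred_frame,
                         num.threads = 1)$predictions[, "1"]
    surf <- matrix(NA_real_, d[1], d[2]); surf[valid_idx] <- pr
    surfaces[[nm]] <- surf
    imp <- pmax(fit$variable.importance, 0)
    contribs[[nm]] <- if (sum(imp) > 0) imp / sum(imp) else imp
    fitted[nm] <- TRUE
  }
  structure(list(surfaces = surfaces, contributions = contribs,
                 fitted = fitted,
                 settings = list(num_trees = num_trees, mtry = use_mtry,
                                 min_samples = min_samples, seed = seed)),
            class = "suitability_stack")
}

#' Neighbourhood (domain) weights from expansion shares
#'
#' With `basis = "expansion"`, class k's weight is its share of total
#' expansion area: (column sum k - diagonal k) / total off-diagonal flow,
#' so the weights sum to 1. With `basis = "given"` a user-supplied vector
#' (e.g. a published one) is stored verbatim, without renormalisation -- the
#' published Guizhou vector sums to 0.4258 and is only reproducible this way.
#'
#' @param counts 6 x 6 transition flow matrix (ignored for `basis="given"`).
#' @param basis `"expansion"` or `"given"`.
#' @param given named weight vector when `basis = "given"`.
#' @return Named non-negative weight vector over the six classes.
#' @export
expansion_share_weights <- function(counts = NULL,
                                    basis = c("expansion", "given"),
                                    given = NULL) {
  basis <- match.arg(basis)
  if (basis == "given") {
    stopifnot(!is.null(given), length(given) == 6, all(given >= 0))
    w <- as.numeric(given)
    nm <- names(given) %||% names(CLASS_CODES)
    return(stats::setNames(w, nm))
  }
  counts <- as.matrix(counts)
  exp_area <- colSums(counts) - diag(counts)
  if (sum(exp_area) <= 0) stop("zero total expansion; weights undefined")
  stats::setNames(exp_area / sum(exp_area), names(CLASS_CODES))
}
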