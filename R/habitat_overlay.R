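#' Categorical maximum-entropy soil suitability model
#'
#' For a single categorical predictor the maximum-entropy
#' presence-background solution reduces to per-category relative
#' occurrence rates: the ratio of (smoothed) presence frequency to
#' (smoothed) background frequency. Scores are mapped to `[0, 1]` by the
#' logistic output `S = ratio / (ratio + 1)`, so a category used exactly
#' in proportion to its availability scores 0.5. Laplace smoothing adds 1
#' to every presence and background category count (and the category
#' count to each denominator), which also gives unseen categories a
#' finite background prior.
#'
#' Ten replicate 75/25 presence splits are scored by held-out AUC
#' (held-out presences versus the background cells, background weighted
#' to equal total presence weight); the final per-category scores are fit
#' on all presences.
#'
#' @param occ occurrence data frame (`lon`, `lat`).
#' @param soil integer-coded `chs_grid` of soil categories.
#' @param region a [build_background_region()] result (the soil
#'   background).
#' @param split training fraction for the replicate evaluation (default
#'   0.75).
#' @param replicates evaluation replicates (default 10).
#' @param seed integer seed.
#' @return object of class `soil_maxent`: list with `scores` (named
#'   per-category suitabilities), `raw_rates` (normalized unsmoothed
#'   relative rates), `prior` (score for unseen categories), `auc`
#'   (per-replicate held-out AUC), `categories`.
#' @export
fit_soil_maxent <- function(occ, soil, region, split = 0.75,
                            replicates = 10, seed = 1) {
  stopifnot(inherits(soil, "chs_grid"), inherits(region, "background_region"))
  pres_cells <- grid_cell_index(soil, occ$lon, occ$lat)
  pres_cat <- soil$values[pres_cells]
  ok <- !is.na(pres_cat)
  if (sum(!ok)) message("dropped ", sum(!ok), " presences on NoData soil")
  pres_cat <- pres_cat[ok]
  bg_cat <- soil$values[region$cells]
  bg_cat <- bg_cat[!is.na(bg_cat)]
  cats <- sort(unique(c(pres_cat, bg_cat)))
  if (length(cats) < 2)
    stop("need at least 2 soil categories among presences and background")
  k <- length(cats)
  score_from <- function(p_counts, b_counts) {
    p <- (p_counts + 1) / (sum(p_counts) + k)
    b <- (b_counts + 1) / (sum(b_counts) + k)
    ratio <- p / b
    ratio / (ratio + 1)
  }
  count_in <- function(x) {
    tab <- table(factor(x, levels = cats))
    as.numeric(tab)
  }
  b_counts <- count_in(bg_cat)
  missing_bg <- cats[b_counts == 0]
  if (length(missing_bg))
    warning("categories absent from background (smoothed prior applied): ",
            paste(missing_bg, collapse = ", "))
  # replicate held-out AUC
  auc <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed(derive_seed(seed, "soil", r))
    n_tr <- round(split * length(pres_cat))
    n_tr <- min(max(n_tr, 1), length(pres_cat) - 1)
    idx <- sample(seq_along(pres_cat), n_tr)
    sc <- score_from(count_in(pres_cat[idx]), b_counts)
    names(sc) <- as.character(cats)
    test_scores <- sc[as.character(pres_cat[-idx])]
    bg_scores <- sc[as.character(bg_cat)]
    scores <- c(test_scores, bg_scores)
    labels <- rep(c(1, 0), c(length(test_scores), length(bg_scores)))
    w <- rep(c(1, length(test_scores) / length(bg_scores)),
             c(length(test_scores), length(bg_scores)))
    auc[r] <- auc_weighted(scores, labels, w)
  }
  p_counts <- count_in(pres_cat)
  scores <- score_from(p_counts, b_counts)
  names(scores) <- as.character(cats)
  raw_ratio <- (p_counts / sum(p_counts)) / (b_counts / sum(b_counts))
  raw_ratio[!is.finite(raw_ratio)] <- NA
  raw_rates <- raw_ratio / sum(raw_ratio, na.rm = TRUE)
  names(raw_rates) <- as.character(cats)
  prior_ratio <- (1 / (sum(p_counts) + k)) / (1 / (sum(b_counts) + k))
  structure(list(scores = scores, raw_rates = raw_rates,
                 prior = prior_ratio / (prior_ratio + 1),
                 auc = auc, categories = cats, split = split),
            class = "soil_maxent")
}

#' @export
print.soil_maxent <- function(x, ...) {
  cat(sprintf("<soil_maxent> %d categories, mean held-out AUC %.3f\n",
              length(x$categories), mean(x$auc)))
  invisible(x)
}

#' Predict soil suitability over a grid
#'
#' Per-cell category lookup; categories unseen at fit time receive the
#' smoothed prior; NoData propagates.
#'
#' @param model a [fit_soil_maxent()] result.
#' @param soil integer-coded `chs_grid`.
#' @return a `chs_grid` `S` in `[0, 1]`.
#' @export
predict_soil_suitability <- function(model, soil) {
  v <- soil$values
  s <- model$scores[as.character(v)]
  s[is.na(s) & !is.na(v)] <- model$prior
  out <- matrix(as.numeric(s), nrow(v), ncol(v))
  out[is.na(v)] <- NA_real_
  grid_create(out, soil$xll, soil$yll, soil$cellsize, soil$crs_label,
              soil$nodata)
}

#' Binary vegetation mask
#'
#' Cells of a suitable vegetation class get 1, all others 0.
#'
#' @param veg integer-coded vegetation `chs_grid`.
#' @param suitable_classes nonempty vector of suitable class ids.
#' @return a `chs_grid` with values in `{0, 1}`.
#' @export
binarize_vegetation <- function(veg, suitable_classes) {
  if (length(suitable_classes) == 0)
    stop("suitable_classes must be nonempty")
  v <- veg$values
  m <- matrix(as.numeric(v %in% suitable_classes), nrow(v), ncol(v))
  m[is.na(v)] <- NA_real_
  grid_create(m, veg$xll, veg$yll, veg$cellsize, veg$crs_label, veg$nodata)
}

#' Three-class comprehensive habitat suitability
#'
#' Intersects the ensemble suitability `BT`, the soil suitability `S`
#' and the vegetation gate `V`: a cell is unsuitable (0) when `V = 0` or
#' either of `BT`, `S` falls below `t_low`; suitable (2) when `V = 1` and
#' both are at least `t_high`; marginally suitable (1) otherwise (both at
#' least `t_low`, at least one below `t_high`). Boundary values follow
#' the `>=` convention.
#'
#' @param BT ensemble suitability `chs_grid` in `[0, 1]`.
#' @param S soil suitability `chs_grid` in `[0, 1]`.
#' @param V vegetation mask `chs_grid` in `{0, 1}`.
#' @param t_low,t_high class thresholds (defaults 0.3 and 0.5;
#'   `t_low < t_high` required).
#' @return a `chs_grid` with classes 0/1/2; NoData where any input lacks
#'   data.
#' @export
classify_chs <- function(BT, S, V, t_low = 0.3, t_high = 0.5) {
  if (t_low >= t_high) stop("t_low must be below t_high")
  for (g in list(S, V)) if (!same_geometry(BT, g))
    stop("BT, S and V must be co-registered")
  bt <- BT$values; s <- S$values; v <- V$values
  cls <- matrix(NA_real_, nrow(bt), ncol(bt))
  valid <- !is.na(bt) & !is.na(s) & !is.na(v)
  cls[valid] <- ifelse(
    v[valid] == 0 | bt[valid] < t_low | s[valid] < t_low, 0,
    ifelse(bt[valid] >= t_high & s[valid] >= t_high, 2, 1))
  grid_create(cls, BT$xll, BT$yll, BT$cellsize, BT$crs_label, BT$nodata)
}
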