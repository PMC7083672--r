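#' Drop algorithms with low mean TSS
#'
#' An algorithm whose mean TSS over all its runs falls below the cutoff
#' is removed wholesale (all its runs), mirroring the exclusion of the
#' surface range envelope from the ensemble when its average TSS is
#' below 0.5.
#'
#' @param runs a `chs_runs` object.
#' @param min_mean_tss cutoff (default 0.5).
#' @return filtered `chs_runs`; attribute `excluded_algorithms` names the
#'   dropped algorithms.
#' @export
filter_runs <- function(runs, min_mean_tss = 0.5) {
  df <- as.data.frame(runs)
  means <- tapply(df$tss, df$algorithm, mean)
  excluded <- names(means)[means < min_mean_tss]
  keep <- !(df$algorithm %in% excluded)
  if (!any(keep)) stop("all algorithms fall below the mean-TSS cutoff")
  out <- structure(unclass(runs)[keep], class = "chs_runs",
                   failures = attr(runs, "failures"))
  attr(out, "excluded_algorithms") <- excluded
  out
}

#' TSS-proportional ensemble weights
#'
#' `w_j = r_j / sum(r_k)` over the retained runs, `r_j` being run `j`'s
#' held-out TSS. Runs with nonpositive TSS are dropped with a warning
#' before normalization so all weights are nonnegative.
#'
#' @param runs a `chs_runs` object (already filtered).
#' @return object of class `ensemble_weights`: data frame with
#'   `algorithm`, `dataset`, `repeat_id`, `tss`, `weight`; attribute `h`
#'   is the number of contributing runs.
#' @export
compute_weights <- function(runs) {
  df <- as.data.frame(runs)
  df$run <- seq_len(nrow(df))
  bad <- df$tss <= 0
  if (any(bad)) {
    warning(sum(bad), " run(s) with nonpositive TSS dropped from weighting")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no runs with positive TSS")
  df$weight <- df$tss / sum(df$tss)
  out <- df[, c("run", "algorithm", "dataset", "repeat_id", "tss", "weight")]
  attr(out, "h") <- nrow(out)
  class(out) <- c("ensemble_weights", "data.frame")
  out
}

#' Weighted ensemble suitability map
#'
#' Cell-wise convex combination `BT_i = sum_j w_j x_ij` of the
#' contributing prediction grids. NoData in any contributor propagates.
#'
#' @param weights numeric weights (nonnegative, summing to 1 within
#'   1e-12), or an `ensemble_weights` object whose `weight` column is
#'   used.
#' @param grids list of co-registered `chs_grid`s, aligned with
#'   `weights`.
#' @return a `chs_grid` (the BT surface).
#' @export
ensemble_map <- function(weights, grids) {
  if (inherits(weights, "ensemble_weights")) weights <- weights$weight
  if (length(weights) != length(grids))
    stop("length of weights (", length(weights),
         ") does not match number of grids (", length(grids), ")")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  ref <- grids[[1]]
  for (g in grids[-1]) if (!same_geometry(ref, g))
    stop("contributor grids are not co-registered")
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  na <- matrix(FALSE, nrow(ref$values), ncol(ref$values))
  for (j in seq_along(grids)) {
    v <- grids[[j]]$values
    na <- na | is.na(v)
    v[is.na(v)] <- 0
    acc <- acc + weights[j] * v
  }
  acc[na] <- NA_real_
  grid_create(acc, ref$xll, ref$yll, ref$cellsize, ref$crs_label,
              ref$nodata)
}

#' Ensemble prediction over a stack
#'
#' Convenience wrapper: predicts every retained run on the stack and
#' accumulates the weighted sum without materializing all contributor
#' grids at once.
#'
#' @param runs a `chs_runs` object.
#' @param weights matching [compute_weights()] result.
#' @param stack a `chs_stack`.
#' @return a `chs_grid` (the BT surface).
#' @export
ensemble_predict_stack <- function(runs, weights, stack) {
  stopifnot(inherits(weights, "ensemble_weights"))
  ref <- stack_ref(stack)
  acc <- matrix(0, grid_nrow(ref), grid_ncol(ref))
  na <- matrix(FALSE, grid_nrow(ref), grid_ncol(ref))
  for (k in seq_len(nrow(weights))) {
    g <- predict_grid(runs[[weights$run[k]]]$model, stack)
    v <- g$values
    na <- na | is.na(v)
    v[is.na(v)] <- 0
    acc <- acc + weights$weight[k] * v
  }
  acc[na] <- NA_real_
  grid_create(acc, ref$xll, ref$yll, ref$cellsize, ref$crs_label,
              ref$nodata)
}

#' Ensemble prediction at points
#'
#' @param runs a `chs_runs` object.
#' @param weights matching [compute_weights()] result.
#' @param newdata data frame with the predictor columns.
#' @return numeric vector of ensemble suitabilities in `[0, 1]`.
#' @export
ensemble_predict_points <- function(runs, weights, newdata) {
  stopifnot(inherits(weights, "ensemble_weights"))
  acc <- rep(0, nrow(newdata))
  for (k in seq_len(nrow(weights)))
    acc <- acc + weights$weight[k] *
      predict_points(runs[[weights$run[k]]]$model, newdata)
  acc
}

#' Average ensemble maps across GCMs, then RCPs
#'
#' Per-RCP map = unweighted mean of that RCP's per-GCM maps; final map =
#' unweighted mean of the per-RCP maps.
#'
#' @param maps list of `chs_grid`s, one per GCM x RCP combination.
#' @param grouping data frame with columns `gcm` and `rcp`, one row per
#'   map.
#' @return list with `per_rcp` (named list of `chs_grid`s) and `final`
#'   (a `chs_grid`).
#' @export
scenario_ensemble <- function(maps, grouping) {
  if (length(maps) != nrow(grouping))
    stop("one grouping row per map required")
  mean_grids <- function(gs) {
    n <- length(gs)
    if (n == 0) stop("empty scenario group")
    w <- rep(1 / n, n)
    ensemble_map(w, gs)
  }
  rcps <- unique(grouping$rcp)
  per_rcp <- lapply(rcps, function(r) mean_grids(maps[grouping$rcp == r]))
  names(per_rcp) <- rcps
  list(per_rcp = per_rcp, final = mean_grids(per_rcp))
}

#' Evaluate the ensemble on labelled data
#'
#' @param runs,weights retained runs and their weights.
#' @param data labelled table (`label`, `weight`, predictor columns).
#' @return list as from [evaluate_scores()].
#' @export
evaluate_ensemble <- function(runs, weights, data) {
  scores <- ensemble_predict_points(runs, weights, data)
  ok <- !is.na(scores)
  evaluate_scores(scores[ok], data$label[ok], data$weight[ok])
}
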