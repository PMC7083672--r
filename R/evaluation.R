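#' Stratified train/test split
#'
#' Repeated random resampling: each call draws a fresh stratified split
#' preserving class proportions (rounded per class), carrying case
#' weights through unchanged.
#'
#' @param train training table (`label`, `weight` columns).
#' @param fraction training fraction (default 0.7).
#' @param seed integer seed; same seed, same split.
#' @return list with `train` and `test` data frames.
#' @export
split_train_test <- function(train, fraction = 0.7, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  set.seed(seed)
  idx_tr <- integer()
  for (lab in unique(train$label)) {
    rows <- which(train$label == lab)
    if (length(rows) < 2) stop("class ", lab, " too small to stratify")
    n_tr <- round(fraction * length(rows))
    n_tr <- min(max(n_tr, 1), length(rows) - 1)
    idx_tr <- c(idx_tr, sample(rows, n_tr))
  }
  out_tr <- train[sort(idx_tr), , drop = FALSE]
  out_te <- train[setdiff(seq_len(nrow(train)), idx_tr), , drop = FALSE]
  attr(out_tr, "vars") <- attr(train, "vars")
  attr(out_te, "vars") <- attr(train, "vars")
  list(train = out_tr, test = out_te)
}

#' Weighted confusion counts at a threshold
#'
#' A point is predicted positive iff its score is greater than or equal
#' to the threshold.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 1 = presence, 0 = absence.
#' @param weights nonnegative case weights (default 1).
#' @param threshold decision threshold.
#' @return list with weighted counts `a` (true positives), `b` (false
#'   positives), `c` (false negatives), `d` (true negatives).
#' @export
confusion <- function(scores, labels, weights = rep(1, length(scores)),
                      threshold) {
  pos <- scores >= threshold
  list(a = sum(weights[pos & labels == 1]),
       b = sum(weights[pos & labels == 0]),
       c = sum(weights[!pos & labels == 1]),
       d = sum(weights[!pos & labels == 0]))
}

#' Sensitivity, specificity and the true skill statistic
#'
#' `sensitivity = a / (a + c)`, `specificity = d / (b + d)`,
#' `TSS = sensitivity + specificity - 1`.
#'
#' @param conf confusion counts from [confusion()].
#' @return list with `sensitivity`, `specificity`, `tss`.
#' @export
tss_stats <- function(conf) {
  if (conf$a + conf$c <= 0)
    stop("no presences in evaluation set (a + c = 0)")
  if (conf$b + conf$d <= 0)
    stop("no absences in evaluation set (b + d = 0)")
  sens <- conf$a / (conf$a + conf$c)
  spec <- conf$d / (conf$b + conf$d)
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1)
}

#' Weighted ROC AUC (Mann-Whitney form)
#'
#' Probability that a random presence outscores a random absence, with
#' half credit for ties, weighting each presence-absence pair by the
#' product of its case weights.
#'
#' @param scores numeric scores.
#' @param labels 1 = presence, 0 = absence (both classes required).
#' @param weights nonnegative case weights (default 1).
#' @return AUC in `[0, 1]`.
#' @export
auc_weighted <- function(scores, labels, weights = rep(1, length(scores))) {
  sp <- scores[labels == 1]; wp <- weights[labels == 1]
  sa <- scores[labels == 0]; wa <- weights[labels == 0]
  if (length(sp) == 0 || length(sa) == 0)
    stop("both classes required for AUC")
  cmp <- outer(sp, sa, function(p, a) (p > a) + 0.5 * (p == a))
  w <- outer(wp, wa)
  sum(cmp * w) / sum(w)
}

#' Threshold maximizing the TSS
#'
#' Scans thresholds 0.00 to 1.00 in steps of 0.01 and returns the lowest
#' threshold attaining the maximal TSS.
#'
#' @param scores,labels,weights as in [auc_weighted()].
#' @return list with `threshold` and `tss`.
#' @export
optimal_threshold <- function(scores, labels,
                              weights = rep(1, length(scores))) {
  thresholds <- seq(0, 1, by = 0.01)
  tss <- vapply(thresholds, function(t)
    tss_stats(confusion(scores, labels, weights, t))$tss, 0)
  best <- which.max(tss)  # which.max takes the first (lowest) maximizer
  list(threshold = thresholds[best], tss = tss[best])
}

#' Evaluate scores against labels
#'
#' TSS at the optimal threshold plus AUC, the per-run summary the
#' ensemble weighting consumes.
#'
#' @param scores,labels,weights as in [auc_weighted()].
#' @return list with `sensitivity`, `specificity`, `tss`, `auc`,
#'   `threshold`.
#' @export
evaluate_scores <- function(scores, labels,
                            weights = rep(1, length(scores))) {
  opt <- optimal_threshold(scores, labels, weights)
  st <- tss_stats(confusion(scores, labels, weights, opt$threshold))
  list(sensitivity = st$sensitivity, specificity = st$specificity,
       tss = st$tss, auc = auc_weighted(scores, labels, weights),
       threshold = opt$threshold)
}

#' Run the full single-model evaluation protocol
#'
#' For every combination of pseudo-absence dataset, algorithm and repeat:
#' draw a fresh stratified 70/30 split (one split per dataset x repeat,
#' shared by all algorithms), fit on the training part, score the held-out
#' part, and record TSS (at the optimal threshold) and AUC. With 3
#' datasets, 10 algorithms and 10 repeats this yields 300 model runs.
#' Failed fits are flagged, logged and excluded from the returned run
#' list.
#'
#' @param datasets list of training tables (one per pseudo-absence
#'   replicate), from [build_training_set()].
#' @param algorithms algorithm ids (default: the full registry).
#' @param n_repeats repeats per dataset x algorithm (default 10).
#' @param fraction training fraction (default 0.7).
#' @param seed master seed; splits use `derive_seed(seed, "split", d, r)`
#'   and fits `derive_seed(seed, "fit", d, a, r)`.
#' @param sre_tail SRE tail quantile.
#' @return object of class `chs_runs`: list of model runs, each with
#'   `algorithm`, `dataset`, `repeat_id`, `model`, `tss`, `auc`,
#'   `threshold`; attribute `failures` lists flagged runs.
#' @export
run_protocol <- function(datasets, algorithms = sdm_algorithm_ids(),
                         n_repeats = 10, fraction = 0.7, seed = 1,
                         sre_tail = 0.025) {
  if (length(datasets) < 1 || length(algorithms) < 1)
    stop("need at least one dataset and one algorithm")
  runs <- list()
  failures <- list()
  for (d in seq_along(datasets)) {
    for (r in seq_len(n_repeats)) {
      sp <- split_train_test(datasets[[d]], fraction,
                             seed = derive_seed(seed, "split", d, r))
      for (alg in algorithms) {
        model <- fit_model(alg, sp$train,
                           seed = derive_seed(seed, "fit", d, alg, r),
                           sre_tail = sre_tail)
        if (inherits(model, "chs_model_failure")) {
          message("run flagged (", alg, ", dataset ", d, ", repeat ", r,
                  "): ", model$error)
          failures[[length(failures) + 1]] <-
            list(algorithm = alg, dataset = d, repeat_id = r,
                 error = model$error)
          next
        }
        scores <- predict_points(model, sp$test)
        ev <- evaluate_scores(scores, sp$test$label, sp$test$weight)
        runs[[length(runs) + 1]] <- list(
          algorithm = alg, dataset = d, repeat_id = r, model = model,
          tss = ev$tss, auc = ev$auc, threshold = ev$threshold,
          sensitivity = ev$sensitivity, specificity = ev$specificity)
      }
    }
  }
  structure(runs, class = "chs_runs", failures = failures)
}

#' @export
print.chs_runs <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<chs_runs> %d runs (%d flagged failures)\n", length(x),
              length(attr(x, "failures"))))
  print(stats::aggregate(cbind(tss, auc) ~ algorithm, df, mean))
  invisible(x)
}

#' Run-level metric table
#'
#' @param x a `chs_runs` object.
#' @param ... unused.
#' @return data frame `algorithm, dataset, repeat_id, tss, auc, threshold`.
#' @export
as.data.frame.chs_runs <- function(x, ...) {
  do.call(rbind, lapply(x, function(r)
    data.frame(algorithm = r$algorithm, dataset = r$dataset,
               repeat_id = r$repeat_id, tss = r$tss, auc = r$auc,
               threshold = r$threshold)))
}
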