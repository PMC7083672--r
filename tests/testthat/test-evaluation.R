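test_that("stratified splits preserve class proportions and reproduce", {
  tr <- data.frame(x = rnorm(100), label = rep(c(1, 0), c(30, 70)),
                   weight = 1)
  sp <- split_train_test(tr, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  expect_equal(sum(sp$train$label == 1), 21)
  expect_equal(sum(sp$train$label == 0), 49)
  sp2 <- split_train_test(tr, 0.7, seed = 1)
  expect_identical(sp$train, sp2$train)
  expect_false(identical(sp$train,
                         split_train_test(tr, 0.7, seed = 2)$train))
  # per-class counts within one record of the target fraction, small n
  for (n1 in 5:9) {
    tr2 <- data.frame(label = rep(c(1, 0), c(n1, 10)), weight = 1)
    sp3 <- split_train_test(tr2, 0.7, seed = 3)
    expect_lte(abs(sum(sp3$train$label == 1) - 0.7 * n1), 1)
  }
  expect_error(split_train_test(data.frame(label = c(1, 0, 0), weight = 1),
                                0.7), "too small")
  expect_error(split_train_test(tr, 1.2), "in \\(0, 1\\)")
})

test_that("confusion counts match a hand tally and the threshold edges", {
  scores <- c(0.9, 0.7, 0.5, 0.4, 0.2, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  w <- rep(1, 6)
  cf <- confusion(scores, labels, w, 0.5)
  expect_equal(cf, list(a = 2, b = 1, c = 1, d = 2))
  cf0 <- confusion(scores, labels, w, 0)
  expect_equal(cf0$b, 3); expect_equal(cf0$c, 0)
  cfh <- confusion(scores, labels, w, 0.95)
  expect_equal(cfh$a, 0); expect_equal(cfh$d, 3)
})

test_that("TSS equals sensitivity plus specificity minus one, per the formulas", {
  expect_equal(tss_stats(list(a = 50, b = 0, c = 0, d = 500)),
               list(sensitivity = 1, specificity = 1, tss = 1))
  expect_equal(tss_stats(list(a = 25, b = 250, c = 25, d = 250)),
               list(sensitivity = 0.5, specificity = 0.5, tss = 0))
  expect_equal(tss_stats(list(a = 45, b = 50, c = 5, d = 450)),
               list(sensitivity = 0.9, specificity = 0.9,
                    tss = 0.8000000000000000444))
  expect_error(tss_stats(list(a = 0, b = 1, c = 0, d = 1)), "no presences")
  # identity holds on random confusion tables
  set.seed(50)
  for (i in 1:20) {
    cf <- as.list(setNames(rpois(4, 20) + 1, c("a", "b", "c", "d")))
    st <- tss_stats(cf)
    expect_equal(st$tss, st$sensitivity + st$specificity - 1)
    expect_true(st$tss >= -1 && st$tss <= 1)
  }
})

test_that("AUC matches the exhaustive pairwise oracle and its invariances", {
  pair_oracle <- function(s, l, w) {
    tot <- 0; den <- 0
    for (i in which(l == 1)) for (j in which(l == 0)) {
      tot <- tot + w[i] * w[j] *
        ((s[i] > s[j]) + 0.5 * (s[i] == s[j]))
      den <- den + w[i] * w[j]
    }
    tot / den
  }
  s <- c(0.9, 0.8, 0.8, 0.6, 0.5, 0.4, 0.3, 0.3)
  l <- c(1, 1, 0, 1, 0, 1, 0, 0)
  w <- c(1, 2, 1, 1, 0.5, 1, 2, 1)
  expect_equal(auc_weighted(s, l, w), pair_oracle(s, l, w))
  expect_equal(auc_weighted(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_weighted(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # invariant under strictly monotone transforms of the scores
  set.seed(51)
  s2 <- runif(30); l2 <- rbinom(30, 1, 0.5); w2 <- runif(30, 0.5, 2)
  if (all(l2 == l2[1])) l2[1] <- 1 - l2[1]
  expect_equal(auc_weighted(plogis(5 * s2 - 2), l2, w2),
               auc_weighted(s2, l2, w2))
  # binary scores: AUC = (sens + spec) / 2 = (TSS + 1) / 2
  sb <- round(runif(40)); lb <- rbinom(40, 1, 0.5)
  if (all(lb == lb[1])) lb[1] <- 1 - lb[1]
  st <- tss_stats(confusion(sb, lb, rep(1, 40), 1))
  expect_equal(auc_weighted(sb, lb, rep(1, 40)),
               (st$sensitivity + st$specificity) / 2)
  expect_equal(auc_weighted(sb, lb, rep(1, 40)), (st$tss + 1) / 2)
  expect_error(auc_weighted(c(1, 0), c(1, 1)), "both classes")
  # unweighted case agrees with an established ROC implementation
  set.seed(54)
  s4 <- runif(60); l4 <- rbinom(60, 1, 0.5)
  if (all(l4 == l4[1])) l4[1] <- 1 - l4[1]
  ref <- as.numeric(suppressMessages(pROC::auc(l4, s4,
                                               direction = "<")))
  expect_equal(auc_weighted(s4, l4), ref)
})

test_that("the threshold grid scan finds the TSS-optimal cut", {
  # separable: perfect TSS at some threshold between the classes
  s <- c(0.95, 0.93, 0.9, 0.1, 0.05)
  l <- c(1, 1, 1, 0, 0)
  opt <- optimal_threshold(s, l)
  expect_equal(opt$tss, 1)
  expect_gt(opt$threshold, 0.1)
  expect_lte(opt$threshold, 0.9)
  # grid scan attains the all-midpoints optimum (grid includes 0.01 steps,
  # so compare achieved TSS values, not thresholds)
  set.seed(52)
  s2 <- round(runif(50), 2); l2 <- rbinom(50, 1, 0.4)
  if (all(l2 == l2[1])) l2[1] <- 1 - l2[1]
  w2 <- rep(1, 50)
  cand <- sort(unique(c(0, s2, 1)))
  mid_tss <- max(vapply(cand, function(t)
    tss_stats(confusion(s2, l2, w2, t))$tss, 0))
  expect_equal(optimal_threshold(s2, l2, w2)$tss, mid_tss)
  # label-score independence: near-zero optimum TSS at large n
  set.seed(53)
  s3 <- runif(1000); l3 <- rbinom(1000, 1, 0.5)
  expect_lt(optimal_threshold(s3, l3)$tss, 0.15)
  # ties broken toward the lower threshold
  expect_equal(optimal_threshold(c(1, 1), c(1, 0))$threshold, 0)
})

test_that("the evaluation protocol produces one scored run per combination", {
  sw <- small_world()
  datasets <- lapply(sw$pa, function(pa)
    build_training_set(sw$occ, pa, sw$env, c("bio1", "bio4", "bio12")))
  runs <- run_protocol(datasets, algorithms = c("GLM", "SRE"),
                       n_repeats = 2, seed = 60)
  expect_length(runs, 2 * 2 * 2)
  df <- as.data.frame(runs)
  expect_equal(anyDuplicated(df[, c("algorithm", "dataset", "repeat_id")]), 0L)
  expect_true(all(df$tss >= -1 & df$tss <= 1))
  expect_true(all(df$auc >= 0 & df$auc <= 1))
  runs1 <- run_protocol(datasets[1], algorithms = "GLM", n_repeats = 1,
                        seed = 60)
  expect_length(runs1, 1)
  expect_error(run_protocol(list(), "GLM"), "at least one")
})
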