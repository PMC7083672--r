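#' The ten-algorithm registry
#'
#' @return character vector of the supported algorithm ids.
#' @export
sdm_algorithm_ids <- function() {
  c("ANN", "CTA", "FDA", "GAM", "GBM", "GLM", "MAXENT", "MARS", "RF", "SRE")
}

#' Assemble a labelled training table
#'
#' Extracts the selected variables at presence and pseudo-absence points
#' and attaches labels and case weights. Presences weigh 1 each; each
#' pseudo-absence weighs `n_presence / n_absence`, so the two classes
#' contribute equal total weight. Points falling on NoData cells are
#' dropped (weights are recomputed afterwards so the totals still match
#' exactly).
#'
#' @param occ occurrence data frame (`lon`, `lat`).
#' @param pa pseudo-absence data frame (`lon`, `lat`).
#' @param stack a `chs_stack` holding the predictor layers.
#' @param vars character vector of predictor names.
#' @return data frame of predictors plus `label` (1/0) and `weight`;
#'   attribute `vars` carries the predictor names.
#' @export
build_training_set <- function(occ, pa, stack, vars) {
  missing <- setdiff(vars, names(stack$layers))
  if (length(missing))
    stop("variables missing from stack: ", paste(missing, collapse = ", "))
  sub <- stack_create(stack$layers[vars])
  ex_p <- extract_values(sub, occ$lon, occ$lat)
  ex_a <- extract_values(sub, pa$lon, pa$lat)
  p <- ex_p[!ex_p$nodata, vars, drop = FALSE]
  a <- ex_a[!ex_a$nodata, vars, drop = FALSE]
  n_drop <- sum(ex_p$nodata) + sum(ex_a$nodata)
  if (n_drop > 0) message("dropped ", n_drop, " points on NoData cells")
  if (nrow(p) == 0 || nrow(a) == 0)
    stop("a class is empty after extraction")
  out <- rbind(p, a)
  out$label <- rep(c(1, 0), c(nrow(p), nrow(a)))
  out$weight <- rep(c(1, nrow(p) / nrow(a)), c(nrow(p), nrow(a)))
  rownames(out) <- NULL
  attr(out, "vars") <- vars
  out
}

training_vars <- function(train) {
  v <- attr(train, "vars")
  if (is.null(v)) setdiff(names(train), c("label", "weight")) else v
}

#' Fit a surface range envelope (BIOCLIM)
#'
#' Stores, per variable, the presence interval between the `tail` and
#' `1 - tail` quantiles; a point is predicted 1 when every variable falls
#' inside its interval and 0 otherwise.
#'
#' @param train training table from [build_training_set()] (uses presences
#'   only; at least 5 required).
#' @param tail_quantile per-side trimmed tail in `[0, 0.5)`; default
#'   0.025, the conventional envelope trim.
#' @return a fitted `chs_model`.
#' @export
fit_sre <- function(train, tail_quantile = 0.025) {
  if (tail_quantile < 0 || tail_quantile >= 0.5)
    stop("tail_quantile must be in [0, 0.5)")
  vars <- training_vars(train)
  pres <- train[train$label == 1, vars, drop = FALSE]
  if (nrow(pres) < 5) stop("SRE needs at least 5 presences")
  env <- lapply(pres, function(x)
    stats::quantile(x, c(tail_quantile, 1 - tail_quantile), names = FALSE,
                    type = 7))
  structure(list(algorithm = "SRE", fit = env, vars = vars,
                 tail_quantile = tail_quantile),
            class = "chs_model")
}

# ---- internal fitters -------------------------------------------------

quad_formula <- function(vars, response = "label") {
  rhs <- paste(vapply(vars, function(v)
    sprintf("%s + I(%s^2)", v, v), ""), collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

fit_glm_learner <- function(train, vars) {
  dat <- train
  f <- quad_formula(vars)
  environment(f) <- environment()
  suppressWarnings(stats::glm(f, data = dat, weights = dat$weight,
                              family = stats::binomial()))
}

fit_gam_learner <- function(train, vars) {
  rhs <- paste(sprintf("s(%s, k = 4)", vars), collapse = " + ")
  f <- stats::as.formula(paste("label ~", rhs))
  dat <- train
  suppressWarnings(mgcv::gam(f, data = dat, weights = dat$weight,
                             family = stats::binomial(), select = FALSE))
}

fit_cta_learner <- function(train, vars) {
  dat <- train
  dat$label <- factor(dat$label, levels = c(0, 1))
  f <- stats::as.formula(paste("label ~", paste(vars, collapse = " + ")))
  rpart::rpart(f, data = dat, weights = dat$weight, method = "class",
               control = rpart::rpart.control(cp = 0.01, xval = 0))
}

fit_rf_learner <- function(train, vars, seed) {
  ranger::ranger(x = train[, vars, drop = FALSE],
                 y = factor(train$label, levels = c(0, 1)),
                 probability = TRUE, num.trees = 300,
                 case.weights = train$weight, seed = seed,
                 num.threads = 1)
}

fit_gbm_learner <- function(train, vars) {
  dm <- xgboost::xgb.DMatrix(as.matrix(train[, vars, drop = FALSE]),
                             label = train$label, weight = train$weight,
                             nthread = 1)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   eta = 0.1, max_depth = 3, nthread = 1),
                     data = dm, nrounds = 150)
}

fit_ann_learner <- function(train, vars) {
  x <- as.matrix(train[, vars, drop = FALSE])
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  fit <- nnet::nnet(xs, train$label, weights = train$weight, size = 5,
                    decay = 0.01, maxit = 300, trace = FALSE)
  list(net = fit, center = ctr, scale = scl)
}

fit_fda_learner <- function(train, vars) {
  # optimal-scoring linear discriminant with equal class priors (the
  # linear-basis flexible discriminant)
  MASS::lda(x = train[, vars, drop = FALSE],
            grouping = factor(train$label, levels = c(0, 1)),
            prior = c(0.5, 0.5))
}

# additive piecewise-linear hinge-basis logistic regression (MARS family):
# per variable, hinge pairs at the 1/3 and 2/3 presence-background
# quantiles, fitted by weighted maximum likelihood.
mars_basis <- function(x, knots) {
  out <- lapply(seq_along(knots), function(i)
    cbind(pmax(x - knots[i], 0), pmax(knots[i] - x, 0)))
  do.call(cbind, out)
}

fit_mars_learner <- function(train, vars) {
  knots <- lapply(train[, vars, drop = FALSE], function(x)
    unique(stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE, type = 7)))
  X <- do.call(cbind, lapply(vars, function(v)
    mars_basis(train[[v]], knots[[v]])))
  colnames(X) <- paste0("h", seq_len(ncol(X)))
  dat <- data.frame(label = train$label, X)
  fit <- suppressWarnings(stats::glm(label ~ ., data = dat,
                                     weights = train$weight,
                                     family = stats::binomial()))
  list(glm = fit, knots = knots)
}

fit_maxent_learner <- function(train, vars) {
  # presence-background penalized logistic on linear + quadratic features
  X <- as.matrix(train[, vars, drop = FALSE])
  X <- cbind(X, X^2)
  colnames(X) <- c(vars, paste0(vars, "_sq"))
  lam <- c(0.1, 0.01, 0.001)
  fit <- glmnet::glmnet(X, train$label, family = "binomial",
                        weights = train$weight, alpha = 1, lambda = lam)
  list(glmnet = fit, lambda = 0.001)
}

#' Fit one registry algorithm
#'
#' Dispatches to the learner named by `algorithm`, honouring case weights
#' where the underlying method supports them (FDA uses equal class priors
#' instead; SRE is presence-only). Fitting failures are caught and
#' returned as flagged `chs_model_failure` objects, which the evaluation
#' protocol excludes with a log entry rather than aborting.
#'
#' @param algorithm one of [sdm_algorithm_ids()].
#' @param train training table from [build_training_set()].
#' @param seed integer seed (fixed seed implies a reproducible fit).
#' @param sre_tail SRE tail quantile (only used for `"SRE"`).
#' @return a fitted `chs_model`, or a `chs_model_failure`.
#' @export
fit_model <- function(algorithm, train, seed = 1, sre_tail = 0.025) {
  algorithm <- toupper(algorithm)
  if (!algorithm %in% sdm_algorithm_ids())
    stop("unknown algorithm id: ", algorithm)
  vars <- training_vars(train)
  set.seed(seed)
  res <- tryCatch({
    fit <- switch(algorithm,
      GLM = fit_glm_learner(train, vars),
      GAM = fit_gam_learner(train, vars),
      CTA = fit_cta_learner(train, vars),
      RF = fit_rf_learner(train, vars, seed),
      GBM = fit_gbm_learner(train, vars),
      ANN = fit_ann_learner(train, vars),
      FDA = fit_fda_learner(train, vars),
      MARS = fit_mars_learner(train, vars),
      MAXENT = fit_maxent_learner(train, vars),
      SRE = return(fit_sre(train, sre_tail))
    )
    structure(list(algorithm = algorithm, fit = fit, vars = vars),
              class = "chs_model")
  }, error = function(e) {
    structure(list(algorithm = algorithm, error = conditionMessage(e)),
              class = "chs_model_failure")
  })
  res
}

#' @export
print.chs_model <- function(x, ...) {
  cat(sprintf("<chs_model> %s on %d variables\n", x$algorithm,
              length(x$vars)))
  invisible(x)
}

#' Predict suitability at points
#'
#' @param model a fitted `chs_model`.
#' @param newdata data frame containing the model's variables; rows with
#'   missing values yield `NA`.
#' @return numeric vector of suitabilities in `[0, 1]`.
#' @export
predict_points <- function(model, newdata) {
  stopifnot(inherits(model, "chs_model"))
  nd <- newdata[, model$vars, drop = FALSE]
  ok <- stats::complete.cases(nd)
  out <- rep(NA_real_, nrow(nd))
  if (!any(ok)) return(out)
  d <- nd[ok, , drop = FALSE]
  p <- switch(model$algorithm,
    GLM = stats::predict(model$fit, newdata = d, type = "response"),
    GAM = as.numeric(stats::predict(model$fit, newdata = d,
                                    type = "response")),
    CTA = stats::predict(model$fit, newdata = d, type = "prob")[, "1"],
    RF = stats::predict(model$fit, data = d,
                        num.threads = 1)$predictions[, "1"],
    GBM = stats::predict(model$fit, as.matrix(d)),
    ANN = {
      xs <- scale(as.matrix(d), model$fit$center, model$fit$scale)
      as.numeric(stats::predict(model$fit$net, xs))
    },
    FDA = stats::predict(model$fit, d)$posterior[, "1"],
    MARS = {
      X <- do.call(cbind, lapply(model$vars, function(v)
        mars_basis(d[[v]], model$fit$knots[[v]])))
      colnames(X) <- paste0("h", seq_len(ncol(X)))
      stats::predict(model$fit$glm, newdata = as.data.frame(X),
                     type = "response")
    },
    MAXENT = {
      X <- as.matrix(d)
      X <- cbind(X, X^2)
      colnames(X) <- c(model$vars, paste0(model$vars, "_sq"))
      as.numeric(stats::predict(model$fit$glmnet, newx = X,
                                s = model$fit$lambda, type = "response"))
    },
    SRE = {
      inside <- rep(TRUE, nrow(d))
      for (v in model$vars) {
        q <- model$fit[[v]]
        inside <- inside & d[[v]] >= q[1] & d[[v]] <= q[2]
      }
      as.numeric(inside)
    }
  )
  out[ok] <- clip01(as.numeric(p))
  out
}

#' Predict a suitability grid
#'
#' @param model a fitted `chs_model`.
#' @param stack a `chs_stack` containing the model's variables.
#' @return a `chs_grid` in `[0, 1]`; NoData propagates.
#' @export
predict_grid <- function(model, stack) {
  missing <- setdiff(model$vars, names(stack$layers))
  if (length(missing))
    stop("variables missing from stack: ", paste(missing, collapse = ", "))
  sub <- stack_create(stack$layers[model$vars])
  ref <- stack_ref(sub)
  mask <- stack_valid_mask(sub)
  cells <- which(mask)
  nd <- as.data.frame(lapply(sub$layers, function(g) g$values[cells]))
  v <- matrix(NA_real_, grid_nrow(ref), grid_ncol(ref))
  v[cells] <- predict_points(model, nd)
  grid_create(v, ref$xll, ref$yll, ref$cellsize, ref$crs_label, ref$nodata)
}
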