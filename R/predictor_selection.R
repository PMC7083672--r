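#' Pearson correlation matrix of a predictor table
#'
#' @param values_table data frame / matrix of numeric predictors (at
#'   least 2 variables, 3 complete records).
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   variables yield `NA` rows/columns and a warning.
#' @export
pearson_matrix <- function(values_table) {
  x <- as.matrix(values_table)
  if (ncol(x) < 2) stop("need at least 2 variables")
  if (nrow(x) < 3) stop("need at least 3 records")
  if (anyNA(x)) stop("values_table must not contain missing values")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance variables (correlation undefined): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
  suppressWarnings(stats::cor(x, method = "pearson"))
}

#' PCA loadings and explained-variance shares
#'
#' Principal component analysis of the standardized predictor table.
#'
#' @param values_table numeric predictor table.
#' @return list with `loadings` (orthonormal columns), `shares`
#'   (explained-variance fractions summing to 1) and `sdev`.
#' @export
pca_loadings <- function(values_table) {
  x <- as.matrix(values_table)
  if (anyNA(x)) stop("values_table must not contain missing values")
  if (nrow(x) < ncol(x))
    warning("fewer records than variables; components truncated to ",
            nrow(x) - 1)
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  shares <- p$sdev^2 / sum(p$sdev^2)
  list(loadings = p$rotation, shares = shares, sdev = p$sdev)
}

# Encode a circular aspect variable (degrees, -1 = flat sentinel) as
# cos/sin components for correlation work. Flat cells get (0, 0).
encode_aspect <- function(a) {
  rad <- a * pi / 180
  flat <- a < 0
  out <- cbind(aspect_cos = cos(rad), aspect_sin = sin(rad))
  out[flat, ] <- 0
  out
}

#' Collinearity-screened variable selection
#'
#' Greedy Pearson elimination guided by PCA: while any variable pair has
#' `|r| >= r_threshold`, the member of the worst (highest `|r|`) pair with
#' the smaller priority score is dropped. The default priority of a
#' variable is the share-weighted sum of its absolute PCA loadings, so
#' variables that carry more of the table's variance survive. A circular
#' `aspect` column (degrees; -1 flat sentinel) is internally encoded as
#' cos/sin and treated as one variable, its correlation with another
#' variable being the larger of the two component correlations.
#'
#' @param values_table numeric predictor table (named columns).
#' @param r_threshold pairwise absolute-correlation ceiling in (0, 1);
#'   default 0.8, a conventional collinearity screen for distribution
#'   models.
#' @param priority optional named numeric vector overriding the PCA
#'   priority (larger = keep).
#' @return list with `selected` (names, original order), `report` (data
#'   frame: variable, kept, reason) and `priority`.
#' @export
select_variables <- function(values_table, r_threshold = 0.8,
                             priority = NULL) {
  if (r_threshold <= 0 || r_threshold >= 1)
    stop("r_threshold must be in (0, 1)")
  x <- as.data.frame(values_table)
  vars <- names(x)
  enc <- x
  aspect_cols <- NULL
  if ("aspect" %in% vars) {
    ae <- encode_aspect(x$aspect)
    enc$aspect <- NULL
    enc <- cbind(enc, ae)
    aspect_cols <- colnames(ae)
  }
  if (is.null(priority)) {
    p <- pca_loadings(enc)
    sc <- as.numeric(abs(p$loadings) %*% p$shares[seq_len(ncol(p$loadings))])
    names(sc) <- rownames(p$loadings)
    priority <- vapply(vars, function(v) {
      if (v == "aspect") max(sc[aspect_cols]) else sc[[v]]
    }, 0)
  } else {
    if (!all(vars %in% names(priority)))
      stop("priority must cover every variable")
    priority <- priority[vars]
  }
  cm <- suppressWarnings(pearson_matrix(enc))
  pair_r <- function(a, b) {
    ca <- if (a == "aspect") aspect_cols else a
    cb <- if (b == "aspect") aspect_cols else b
    max(abs(cm[ca, cb, drop = FALSE]), na.rm = TRUE)
  }
  kept <- vars
  dropped <- character()
  reason <- stats::setNames(rep("kept", length(vars)), vars)
  repeat {
    if (length(kept) < 2) break
    pairs <- utils::combn(kept, 2)
    rs <- apply(pairs, 2, function(p) pair_r(p[1], p[2]))
    if (all(rs < r_threshold)) break
    worst <- pairs[, which.max(rs)]
    # drop the lower-priority member; alphabetical tie-break (later name drops)
    pr <- priority[worst]
    drop_var <- if (pr[1] < pr[2]) worst[1]
      else if (pr[2] < pr[1]) worst[2]
      else sort(worst)[2]
    other <- setdiff(worst, drop_var)
    kept <- setdiff(kept, drop_var)
    dropped <- c(dropped, drop_var)
    reason[drop_var] <- sprintf("dropped: |r|=%.3f with %s", max(rs), other)
  }
  if (length(kept) < 2)
    warning("fewer than 2 variables survive the screen")
  list(
    selected = vars[vars %in% kept],
    report = data.frame(variable = vars, kept = vars %in% kept,
                        reason = reason[vars], row.names = NULL,
                        stringsAsFactors = FALSE),
    priority = priority
  )
}

#' Default predictor set
#'
#' The nine-variable preset used by the pipeline when variable screening
#' is bypassed: seven bioclimatic variables (annual mean temperature,
#' temperature seasonality, warmest/coldest quarter temperatures, annual
#' precipitation, precipitation seasonality, coldest-quarter
#' precipitation) plus slope and aspect.
#'
#' @return character vector of layer names.
#' @export
default_predictors <- function() {
  c("bio1", "bio4", "bio10", "bio11", "bio12", "bio15", "bio19",
    "slope", "aspect")
}

#' Write a variable-selection report
#'
#' @param selection result of [select_variables()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(selection, path) {
  utils::write.csv(selection$report, path, row.names = FALSE)
  invisible(path)
}
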