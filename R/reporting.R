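#' Per-cell area grid
#'
#' For geographic grids the spherical cell area is
#' `R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))` per row (R = 6371
#' km); planar grids get a declared constant cell area.
#'
#' @param grid a `chs_grid`.
#' @param cell_area_km2 declared area for planar grids; required when
#'   `grid$crs_label == "planar"`.
#' @return a `chs_grid` of km^2 per cell.
#' @export
cell_area_grid <- function(grid, cell_area_km2 = NULL) {
  nr <- grid_nrow(grid); nc <- grid_ncol(grid)
  if (identical(grid$crs_label, "planar")) {
    if (is.null(cell_area_km2))
      stop("planar grid needs a declared cell_area_km2")
    m <- matrix(cell_area_km2, nr, nc)
  } else {
    R <- 6371
    lat_top <- grid$yll + (nr:1) * grid$cellsize
    lat_bot <- lat_top - grid$cellsize
    dlam <- grid$cellsize * pi / 180
    row_area <- R^2 * dlam * (sin(lat_top * pi / 180) -
                              sin(lat_bot * pi / 180))
    m <- matrix(row_area, nr, nc)
  }
  grid_create(m, grid$xll, grid$yll, grid$cellsize, grid$crs_label,
              grid$nodata)
}

#' Zonal area accounting of a classified map
#'
#' Per-zone, per-class area sums and percentages of the zone's valid
#' area, plus a totals block (`zone = "total"`). All arithmetic is at
#' full precision; rounding belongs to serialization.
#'
#' @param chs classified `chs_grid` (e.g. 0/1/2 from [classify_chs()]).
#' @param zones integer-coded zone `chs_grid`, co-registered.
#' @param cell_areas `chs_grid` of km^2 per cell (from
#'   [cell_area_grid()]).
#' @param classes class codes to report (default: those observed); classes
#'   absent from the map get zero rows, keeping multi-period reports
#'   aligned.
#' @return data frame `zone, class, area_km2, percent_of_zone`.
#' @export
zonal_area_table <- function(chs, zones, cell_areas, classes = NULL) {
  for (g in list(zones, cell_areas)) if (!same_geometry(chs, g))
    stop("chs, zones and cell_areas must be co-registered")
  cls <- chs$values; zn <- zones$values; ar <- cell_areas$values
  valid <- !is.na(cls) & !is.na(zn)
  df <- data.frame(zone = as.character(zn[valid]), class = cls[valid],
                   area = ar[valid])
  if (is.null(classes)) classes <- sort(unique(df$class))
  zones_u <- c(sort(unique(df$zone)), "total")
  rows <- list()
  for (z in zones_u) {
    sub <- if (z == "total") df else df[df$zone == z, , drop = FALSE]
    tot <- sum(sub$area)
    for (k in classes) {
      a <- sum(sub$area[sub$class == k])
      rows[[length(rows) + 1]] <- data.frame(
        zone = z, class = k, area_km2 = a,
        percent_of_zone = 100 * a / tot)
    }
  }
  do.call(rbind, rows)
}

#' Class-transition areas between two periods
#'
#' Cross-tabulates class membership cell by cell, weighting by cell
#' area, producing the "class A became class B" accounting between two
#' classified maps.
#'
#' @param chs_a,chs_b classified `chs_grid`s of the two periods.
#' @param cell_areas `chs_grid` of km^2 per cell.
#' @param classes class codes to cross-tabulate (default: union of those
#'   observed).
#' @return square matrix of areas (rows = classes in A, columns = classes
#'   in B); row sums reproduce period A's class areas, column sums period
#'   B's.
#' @export
transition_table <- function(chs_a, chs_b, cell_areas, classes = NULL) {
  for (g in list(chs_b, cell_areas)) if (!same_geometry(chs_a, g))
    stop("maps must be co-registered")
  a <- chs_a$values; b <- chs_b$values; ar <- cell_areas$values
  valid <- !is.na(a) & !is.na(b)
  if (is.null(classes)) classes <- sort(unique(c(a[valid], b[valid])))
  m <- matrix(0, length(classes), length(classes),
              dimnames = list(from = classes, to = classes))
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    sel <- valid & a == classes[i] & b == classes[j]
    m[i, j] <- sum(ar[sel])
  }
  m
}

#' Response curve of a predictor variable
#'
#' Evaluation-strip profile: the target variable sweeps its observed
#' range over `n_points` while every other variable is held at a fixed
#' anchor value; the predictor is evaluated on the strip and the
#' suitable range is the set of maximal intervals where the predicted
#' probability exceeds the cutoff. The anchor defaults to each
#' variable's median over valid cells; supplying the medians of the
#' presence records instead (as the pipeline does) anchors the profile
#' inside the occupied niche, which keeps the curve identifiable when
#' the species occupies one tail of the landscape.
#'
#' @param predict_fun function mapping a data frame of predictor columns
#'   to probabilities in `[0, 1]` (e.g. an ensemble closure).
#' @param stack a `chs_stack` supplying variable ranges and medians.
#' @param variable target variable name.
#' @param vars predictor set (default: all stack layers).
#' @param n_points strip resolution (default 100).
#' @param cutoff suitability cutoff defining the suitable range (default
#'   0.3).
#' @param at optional named vector of anchor values for the non-target
#'   variables.
#' @return object of class `response_curve`: data frame `value,
#'   probability`; attribute `suitable_range` is a 2-column matrix of
#'   interval endpoints (possibly 0 rows).
#' @export
response_curve <- function(predict_fun, stack, variable,
                           vars = names(stack$layers), n_points = 100,
                           cutoff = 0.3, at = NULL) {
  if (!variable %in% names(stack$layers))
    stop("variable not in stack: ", variable)
  mask <- stack_valid_mask(stack_create(stack$layers[vars]))
  vals <- stack$layers[[variable]]$values[mask]
  if (length(unique(vals)) < 2) {
    warning("constant variable; empty response curve")
    out <- data.frame(value = numeric(), probability = numeric())
    attr(out, "suitable_range") <- matrix(numeric(), 0, 2)
    class(out) <- c("response_curve", "data.frame")
    return(out)
  }
  strip <- seq(min(vals), max(vals), length.out = n_points)
  anchor <- vapply(vars, function(w) {
    if (!is.null(at) && w %in% names(at)) at[[w]]
    else stats::median(stack$layers[[w]]$values[mask])
  }, 0)
  nd <- as.data.frame(lapply(anchor, rep, n_points))
  nd[[variable]] <- strip
  prob <- predict_fun(nd)
  above <- prob > cutoff
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  iv <- cbind(lower = strip[starts[runs$values]],
              upper = strip[ends[runs$values]])
  out <- data.frame(value = strip, probability = prob)
  attr(out, "suitable_range") <- iv
  class(out) <- c("response_curve", "data.frame")
  out
}

#' Permutation variable importance
#'
#' biomod2-style shuffling importance: for each variable, predictions on
#' the intact table are correlated with predictions after shuffling that
#' variable; importance is `1 - |Pearson r|` averaged over shuffles, then
#' normalized across variables to sum to 1.
#'
#' @param predict_fun prediction closure as in [response_curve()].
#' @param data data frame of predictor values (e.g. valid-cell sample of
#'   a stack).
#' @param vars variables to score (default: all columns).
#' @param n_shuffles shuffles per variable (default 3).
#' @param seed integer seed.
#' @return named numeric vector of normalized importance scores.
#' @export
variable_importance <- function(predict_fun, data, vars = names(data),
                                n_shuffles = 3, seed = 1) {
  base <- predict_fun(data)
  raw <- vapply(vars, function(v) {
    drops <- vapply(seq_len(n_shuffles), function(s) {
      set.seed(derive_seed(seed, "importance", v, s))
      d <- data
      d[[v]] <- sample(d[[v]])
      p <- predict_fun(d)
      if (stats::sd(p) == 0 || stats::sd(base) == 0) return(0)
      1 - abs(stats::cor(base, p))
    }, 0)
    mean(drops)
  }, 0)
  if (sum(raw) == 0) return(raw)
  raw / sum(raw)
}

#' Sample a predictor table from a stack
#'
#' Uniform sample of valid cells, as input for
#' [variable_importance()].
#'
#' @param stack a `chs_stack`.
#' @param vars layers to include.
#' @param n maximum rows (default 2000).
#' @param seed integer seed.
#' @return data frame of predictor values.
#' @export
sample_stack_cells <- function(stack, vars = names(stack$layers),
                               n = 2000, seed = 1) {
  sub <- stack_create(stack$layers[vars])
  cells <- which(stack_valid_mask(sub))
  if (length(cells) > n) {
    set.seed(derive_seed(seed, "cells"))
    cells <- sample(cells, n)
  }
  as.data.frame(lapply(sub$layers, function(g) g$values[cells]))
}

#' Published regional habitat-area summaries
#'
#' Loads the packaged table of current-climate habitat areas and
#' percentages for Notopterygium incisum by Chinese province/autonomous
#' region (suitable, marginally suitable and unsuitable classes; areas in
#' 10^3 km^2). Percentage entries are absent for the aggregate
#' "other" row.
#'
#' @return data frame with columns `region`, `suitable_pct`,
#'   `marginal_pct`, `unsuitable_pct`, `suitable_km2e3`,
#'   `marginal_km2e3`, `unsuitable_km2e3`.
#' @export
published_region_areas <- function() {
  path <- system.file("extdata", "nincisum_region_areas_current.csv",
                      package = "chsdm")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Consistency summary of a regional area table
#'
#' Recomputes, at full precision, the national class totals (summing the
#' per-region areas) and each region's class percentages from its three
#' areas — the internal-consistency arithmetic any zonal area report must
#' satisfy.
#'
#' @param tab table in the layout of [published_region_areas()].
#' @return list with `total_suitable_km2e3`, `total_marginal_km2e3` and
#'   `recomputed_pct` (data frame `region, suitable_pct, marginal_pct,
#'   unsuitable_pct` for rows with complete class areas).
#' @export
region_area_consistency <- function(tab) {
  total_s <- sum(tab$suitable_km2e3, na.rm = TRUE)
  total_m <- sum(tab$marginal_km2e3, na.rm = TRUE)
  full <- stats::complete.cases(
    tab[, c("suitable_km2e3", "marginal_km2e3", "unsuitable_km2e3")])
  sub <- tab[full, , drop = FALSE]
  zone_total <- sub$suitable_km2e3 + sub$marginal_km2e3 +
    sub$unsuitable_km2e3
  list(
    total_suitable_km2e3 = total_s,
    total_marginal_km2e3 = total_m,
    recomputed_pct = data.frame(
      region = sub$region,
      suitable_pct = 100 * sub$suitable_km2e3 / zone_total,
      marginal_pct = 100 * sub$marginal_km2e3 / zone_total,
      unsuitable_pct = 100 * sub$unsuitable_km2e3 / zone_total)
  )
}
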