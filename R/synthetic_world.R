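#' Synthetic study-system specification
#'
#' Describes the synthetic landscape on which the pipeline is exercised: a
#' rectangular lon/lat grid carrying spatially autocorrelated climate
#' surfaces, synthetic terrain, and categorical soil/vegetation mosaics.
#' Defaults emulate a 10 x 10 degree alpine-margin window at 0.1 degree
#' resolution.
#'
#' @param n_rows,n_cols grid size in cells (each at least 10).
#' @param xmin,ymin lower-left corner (degrees).
#' @param cell_size cell edge (degrees).
#' @param autocorr_length Gaussian correlation length of the random
#'   fields, in cells; 0 gives per-cell independent noise.
#' @param n_soil_classes,n_veg_classes number of categorical classes.
#' @param suitable_veg_classes vegetation class ids treated as habitat
#'   (high-elevation classes by default, mimicking alpine forest,
#'   shrubland and meadow).
#' @param seed integer seed controlling every random surface.
#' @return an object of class `world_spec`.
#' @export
world_spec <- function(n_rows = 100, n_cols = 100, xmin = 95, ymin = 28,
                       cell_size = 0.1, autocorr_length = 6,
                       n_soil_classes = 6, n_veg_classes = 6,
                       suitable_veg_classes = c(4, 5, 6), seed = 1) {
  if (n_rows < 10 || n_cols < 10)
    stop("degenerate grid: need at least 10 cells per side")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (n_soil_classes < 2 || n_veg_classes < 2)
    stop("need at least 2 soil and 2 vegetation classes")
  if (length(suitable_veg_classes) == 0 ||
      length(suitable_veg_classes) >= n_veg_classes)
    stop("suitable_veg_classes must be a proper, non-empty subset of classes")
  if (autocorr_length < 0) stop("autocorr_length must be >= 0")
  structure(list(
    n_rows = n_rows, n_cols = n_cols, xmin = xmin, ymin = ymin,
    cell_size = cell_size, autocorr_length = autocorr_length,
    n_soil_classes = n_soil_classes, n_veg_classes = n_veg_classes,
    suitable_veg_classes = as.integer(suitable_veg_classes),
    seed = as.integer(seed)
  ), class = "world_spec")
}

# Gaussian random field: white noise smoothed by a separable Gaussian
# kernel (sigma in cells), restandardized to mean 0 / sd 1.
gaussian_field <- function(n_rows, n_cols, sigma) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (sigma > 0) {
    smoother <- function(n) {
      idx <- seq_len(n)
      w <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
      w / rowSums(w)
    }
    z <- smoother(n_rows) %*% z %*% t(smoother(n_cols))
  }
  (z - mean(z)) / stats::sd(z)
}

#' Slope and aspect from elevation (Horn's method)
#'
#' Eight-neighbour finite differences on a 3 x 3 window with
#' edge-replication padding. For geographic grids cell sizes are converted
#' to metres per row (111,320 m/degree in longitude scaled by cos(lat),
#' 111,132 m/degree in latitude); planar grids use the cell size as the
#' metric unit directly.
#'
#' @param elev a `chs_grid` of elevations (metres).
#' @return list with `slope` (degrees) and `aspect` (compass degrees in
#'   `[0, 360)`; flat cells carry the sentinel `-1`) as `chs_grid`s.
#' @export
terrain_slope_aspect <- function(elev) {
  z <- elev$values
  nr <- nrow(z); nc <- ncol(z)
  pad <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(dr, dc) pad[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  a <- sh(0, 0); b <- sh(0, 1); cc <- sh(0, 2)
  d <- sh(1, 0);               f <- sh(1, 2)
  g <- sh(2, 0); h <- sh(2, 1); i <- sh(2, 2)
  if (identical(elev$crs_label, "planar")) {
    dx <- matrix(elev$cellsize, nr, nc)
    dy <- elev$cellsize
  } else {
    lat <- grid_cell_centers(elev)[, "lat"]
    lat_row <- matrix(lat, nr, nc)  # column-major: rows vary fastest
    dx <- 111320 * cos(lat_row * pi / 180) * elev$cellsize
    dy <- 111132 * elev$cellsize
  }
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * dx)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * dy)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  asp <- (450 - atan2(dzdy, -dzdx) * 180 / pi) %% 360
  asp[dzdx == 0 & dzdy == 0] <- -1
  na <- is.na(z)
  slope[na] <- NA; asp[na] <- NA
  list(
    slope = grid_create(slope, elev$xll, elev$yll, elev$cellsize,
                        elev$crs_label, elev$nodata),
    aspect = grid_create(asp, elev$xll, elev$yll, elev$cellsize,
                         elev$crs_label, elev$nodata)
  )
}

#' Generate the continuous environmental layers
#'
#' Builds a bioclim-style stack: temperature layers with a latitudinal
#' gradient and an elevation lapse, nonnegative precipitation layers, a
#' synthetic elevation surface, and slope/aspect derived from elevation by
#' Horn's finite differences. All stochastic structure comes from Gaussian
#' random fields seeded by `spec$seed`, so the output is deterministic.
#'
#' @param spec a [world_spec()].
#' @return a `chs_stack` with layers `bio1`, `bio4`, `bio10`, `bio11`,
#'   `bio12`, `bio15`, `bio19`, `elev`, `slope`, `aspect`.
#' @export
generate_environment <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(derive_seed(spec$seed, "environment"))
  nr <- spec$n_rows; nc <- spec$n_cols; s <- spec$autocorr_length
  gf <- function() gaussian_field(nr, nc, s)
  mk <- function(v) grid_create(v, spec$xmin, spec$ymin, spec$cell_size)
  lat <- matrix(spec$ymin + (nr - row(matrix(0, nr, nc)) + 0.5) *
                  spec$cell_size, nr, nc)
  elev <- 3000 + 800 * gf()
  bio1 <- 22 - 1.1 * (lat - spec$ymin) - 0.004 * (elev - 2500) + 1.5 * gf()
  bio4 <- 7.3 + 1.2 * gf()
  bio10 <- bio1 + 8 + 0.6 * gf()
  bio11 <- bio1 - 10 + 0.6 * gf()
  bio12 <- pmax(800 + 20 * (lat - spec$ymin) + 250 * gf(), 0)
  bio15 <- 85 + 10 * gf()
  bio19 <- pmax(60 + 25 * gf(), 0)
  elev_g <- mk(elev)
  terr <- terrain_slope_aspect(elev_g)
  stack_create(list(
    bio1 = mk(bio1), bio4 = mk(bio4), bio10 = mk(bio10), bio11 = mk(bio11),
    bio12 = mk(bio12), bio15 = mk(bio15), bio19 = mk(bio19),
    elev = elev_g, slope = terr$slope, aspect = terr$aspect
  ))
}

#' Generate categorical soil and vegetation mosaics
#'
#' Soil classes are quantile bins of an independent autocorrelated field
#' (spatially coherent patches). Vegetation classes are quantile bins of
#' elevation plus optional noise, so vegetation bands track elevation and
#' the virtual species' suitable vegetation is spatially coherent.
#'
#' @param spec a [world_spec()].
#' @param elevation a `chs_grid` co-registered with the spec grid.
#' @param veg_noise sd of the noise added to standardized elevation before
#'   binning (0 = bins exactly at elevation quantiles).
#' @return list with integer-coded `soil` and `vegetation` `chs_grid`s
#'   (classes `1..n`).
#' @export
generate_categorical_layers <- function(spec, elevation, veg_noise = 0.3) {
  stopifnot(inherits(spec, "world_spec"), inherits(elevation, "chs_grid"))
  if (nrow(elevation$values) != spec$n_rows ||
      ncol(elevation$values) != spec$n_cols)
    stop("elevation is not co-registered with the spec grid")
  set.seed(derive_seed(spec$seed, "categorical"))
  nr <- spec$n_rows; nc <- spec$n_cols
  bin <- function(z, n) {
    br <- stats::quantile(z, probs = seq(0, 1, length.out = n + 1),
                          na.rm = TRUE, type = 7)
    br <- unique(br)
    matrix(as.numeric(cut(z, breaks = br, include.lowest = TRUE,
                          labels = FALSE)), nr, nc)
  }
  soil_f <- gaussian_field(nr, nc, max(spec$autocorr_length, 1))
  soil <- bin(soil_f, spec$n_soil_classes)
  ez <- (elevation$values - mean(elevation$values, na.rm = TRUE)) /
    stats::sd(elevation$values, na.rm = TRUE)
  if (all(is.na(ez)) || !any(is.finite(ez))) ez <- elevation$values * 0
  vz <- ez + if (veg_noise > 0) veg_noise * gaussian_field(nr, nc, max(spec$autocorr_length, 1)) else 0
  veg <- bin(vz, spec$n_veg_classes)
  mk <- function(v) grid_create(v, spec$xmin, spec$ymin, spec$cell_size)
  list(soil = mk(soil), vegetation = mk(veg))
}

#' Virtual species specification
#'
#' A product-Gaussian niche: suitability is the product over variables of
#' `exp(-(x - mu)^2 / (2 sigma^2))` — smooth, unimodal, and recoverable,
#' mirroring bell-shaped response curves.
#'
#' @param response_means named vector of niche optima (variable units).
#' @param response_widths named vector of niche breadths (sd, same units);
#'   all positive.
#' @param n_presences number of occurrence points to sample (>= 20);
#'   default 99.
#' @param prevalence_scale multiplier in (0, 1] applied to suitability
#'   when sampling.
#' @return an object of class `virtual_species`.
#' @export
virtual_species_spec <- function(response_means, response_widths,
                                 n_presences = 99, prevalence_scale = 1) {
  if (is.null(names(response_means)) || is.null(names(response_widths)))
    stop("response_means and response_widths must be named")
  if (!setequal(names(response_means), names(response_widths)))
    stop("response_means and response_widths must cover the same variables")
  if (any(response_widths <= 0)) stop("response_widths must be positive")
  if (n_presences < 20) stop("n_presences must be at least 20")
  if (prevalence_scale <= 0 || prevalence_scale > 1)
    stop("prevalence_scale must be in (0, 1]")
  structure(list(response_means = response_means,
                 response_widths = response_widths[names(response_means)],
                 n_presences = as.integer(n_presences),
                 prevalence_scale = prevalence_scale),
            class = "virtual_species")
}

#' Default virtual species
#'
#' Temperature-driven niche with its optimum in the cold tail of the
#' default landscape (so uniform warming shrinks the pool of suitable
#' cells) and a deliberately broad precipitation response, making
#' temperature the dominant variable group.
#'
#' @param n_presences number of occurrences to sample; default 99.
#' @return a [virtual_species_spec()].
#' @export
default_virtual_species <- function(n_presences = 99) {
  virtual_species_spec(
    response_means  = c(bio1 = 8,  bio4 = 7.3, bio12 = 800),
    response_widths = c(bio1 = 2,  bio4 = 1.5, bio12 = 400),
    n_presences = n_presences
  )
}

#' True suitability surface of a virtual species
#'
#' @param env a `chs_stack` containing every niche variable.
#' @param vs a [virtual_species_spec()].
#' @return a `chs_grid` in `[0, 1]`; NoData propagates.
#' @export
true_suitability <- function(env, vs) {
  stopifnot(inherits(env, "chs_stack"), inherits(vs, "virtual_species"))
  missing <- setdiff(names(vs$response_means), names(env$layers))
  if (length(missing))
    stop("niche variables missing from stack: ", paste(missing, collapse = ", "))
  ref <- stack_ref(env)
  s <- matrix(1, grid_nrow(ref), grid_ncol(ref))
  for (v in names(vs$response_means)) {
    x <- env$layers[[v]]$values
    s <- s * exp(-(x - vs$response_means[[v]])^2 /
                   (2 * vs$response_widths[[v]]^2))
  }
  grid_create(s, ref$xll, ref$yll, ref$cellsize, ref$crs_label, ref$nodata)
}

#' Sample occurrence points from a suitability surface
#'
#' Draws distinct cells with probability proportional to suitability
#' (times the prevalence scale) and returns their centers, so no two
#' occurrences share a coordinate.
#'
#' @param suit a `chs_grid` in `[0, 1]`.
#' @param vs a [virtual_species_spec()]; `vs$n_presences` points drawn.
#' @param seed integer seed.
#' @return a `chs_occurrences` data frame with `species`, `lon`, `lat`,
#'   `cell`, `true_suitability`.
#' @export
sample_occurrences <- function(suit, vs, seed = 1) {
  v <- suit$values
  if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
    stop("suitability must lie in [0, 1]")
  eligible <- which(!is.na(v) & v > 0)
  if (length(eligible) < vs$n_presences)
    stop("only ", length(eligible), " eligible cells for ",
         vs$n_presences, " presences")
  set.seed(seed)
  cells <- if (length(eligible) == 1) eligible else
    sample(eligible, vs$n_presences,
           prob = v[eligible] * vs$prevalence_scale)
  xy <- grid_cell_centers(suit, cells)
  out <- data.frame(species = "virtual", lon = xy[, "lon"], lat = xy[, "lat"],
                    cell = cells, true_suitability = v[cells],
                    stringsAsFactors = FALSE)
  class(out) <- c("chs_occurrences", "data.frame")
  out
}

#' Climate-scenario delta
#'
#' A spatially uniform per-layer shift/scale representing one GCM x RCP
#' climate projection.
#'
#' @param gcm_id,rcp_id scenario labels.
#' @param additive_shift named vector of per-layer offsets (layer units).
#' @param multiplicative_shift named vector of per-layer factors (all
#'   positive); layers absent from both vectors are left untouched.
#' @return an object of class `scenario_delta`.
#' @export
scenario_delta <- function(gcm_id, rcp_id, additive_shift = numeric(),
                           multiplicative_shift = numeric()) {
  if (length(multiplicative_shift) && any(multiplicative_shift <= 0))
    stop("multiplicative_shift must be positive")
  structure(list(gcm_id = gcm_id, rcp_id = rcp_id,
                 additive_shift = additive_shift,
                 multiplicative_shift = multiplicative_shift),
            class = "scenario_delta")
}

#' Default future-scenario deltas
#'
#' CMIP5-like spatially uniform warming for two future periods under four
#' forcing pathways and three climate models: end-of-century warming of
#' 1.0/1.8/2.2/3.7 degrees C for the four RCPs (2050s at 60 percent of the
#' 2070s signal), a fixed inter-model spread of -0.3/0/+0.3 degrees C, and
#' precipitation scaling of +3 percent per degree of warming.
#'
#' @param periods period labels.
#' @param rcps named vector of 2070s warming per RCP (degrees C).
#' @param gcms named vector of per-model temperature offsets (degrees C).
#' @return nested list: `deltas[[period]][[i]]` is a [scenario_delta()].
#' @export
default_scenario_deltas <- function(
    periods = c("2050s", "2070s"),
    rcps = c(rcp26 = 1.0, rcp45 = 1.8, rcp60 = 2.2, rcp85 = 3.7),
    gcms = c(gcmA = -0.3, gcmB = 0, gcmC = 0.3)) {
  period_frac <- stats::setNames(
    seq(0.6, 1, length.out = length(periods)), periods)
  out <- list()
  for (p in periods) {
    out[[p]] <- list()
    for (r in names(rcps)) for (g in names(gcms)) {
      dT <- rcps[[r]] * period_frac[[p]] + gcms[[g]]
      out[[p]][[paste(r, g, sep = "_")]] <- scenario_delta(
        gcm_id = g, rcp_id = r,
        additive_shift = c(bio1 = dT, bio10 = dT, bio11 = dT,
                           bio4 = 0.1 * dT),
        multiplicative_shift = c(bio12 = 1 + 0.03 * dT,
                                 bio19 = 1 + 0.03 * dT)
      )
    }
  }
  out
}

#' Apply a scenario delta to an environment stack
#'
#' Shifts/scales the named climate layers; every other layer (soil,
#' vegetation, topography) is returned untouched, reflecting that soil and
#' vegetation change lags climate change.
#'
#' @param env a `chs_stack`.
#' @param delta a [scenario_delta()].
#' @return a new `chs_stack` with the same layer names.
#' @export
generate_future_stack <- function(env, delta) {
  stopifnot(inherits(env, "chs_stack"), inherits(delta, "scenario_delta"))
  touched <- union(names(delta$additive_shift),
                   names(delta$multiplicative_shift))
  missing <- setdiff(touched, names(env$layers))
  if (length(missing))
    stop("delta names layers absent from stack: ",
         paste(missing, collapse = ", "))
  layers <- env$layers
  for (nm in touched) {
    g <- layers[[nm]]
    v <- g$values
    if (nm %in% names(delta$multiplicative_shift))
      v <- v * delta$multiplicative_shift[[nm]]
    if (nm %in% names(delta$additive_shift))
      v <- v + delta$additive_shift[[nm]]
    layers[[nm]] <- grid_create(v, g$xll, g$yll, g$cellsize, g$crs_label,
                                g$nodata)
  }
  stack_create(layers)
}

#' Partition the grid into rectangular zones
#'
#' Splits the grid into `r x c` near-equal rectangular blocks where
#' `r * c = n_zones` and the factor pair is as square as possible
#' (`n_zones = 4` gives quadrants; a prime count gives vertical strips).
#' Every cell belongs to exactly one zone.
#'
#' @param spec a [world_spec()].
#' @param n_zones number of zones (>= 1, <= number of cells).
#' @return an integer-coded `chs_grid` of zone ids `1..n_zones`.
#' @export
generate_zones <- function(spec, n_zones) {
  stopifnot(inherits(spec, "world_spec"))
  if (n_zones < 1) stop("n_zones must be >= 1")
  if (n_zones > spec$n_rows * spec$n_cols)
    stop("n_zones exceeds the number of cells")
  divs <- which(n_zones %% seq_len(floor(sqrt(n_zones))) == 0)
  r <- max(divs); cc <- n_zones / r
  band <- function(n, k) rep(seq_len(k), times = diff(round(seq(0, n, length.out = k + 1))))
  row_band <- band(spec$n_rows, r)
  col_band <- band(spec$n_cols, cc)
  z <- outer(row_band, col_band, function(a, b) (a - 1) * cc + b)
  grid_create(z, spec$xmin, spec$ymin, spec$cell_size)
}
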