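#' Background region: buffered convex hull around occurrences
#'
#' The background from which pseudo-absences are drawn is the set of grid
#' cells whose centers lie inside the convex hull of the occurrence
#' points or within `buffer_km` great-circle kilometres of its boundary,
#' excluding cells that contain a presence and cells with NoData. With
#' fewer than 3 distinct (or collinear) occurrences the hull degenerates
#' and the region falls back to the union of point buffers.
#'
#' @param occ occurrence data frame (`lon`, `lat`).
#' @param grid a `chs_grid` (its NoData cells are excluded).
#' @param buffer_km buffer distance in km (default 200).
#' @return object of class `background_region`: list with `cells`
#'   (integer indices into `grid`), `grid`, and provenance fields.
#' @export
build_background_region <- function(occ, grid, buffer_km = 200) {
  stopifnot(inherits(grid, "chs_grid"))
  pts <- unique(cbind(lon = occ$lon, lat = occ$lat))
  centers <- grid_cell_centers(grid)
  valid <- !is.na(grid$values)
  R_m <- 6371000  # spherical haversine convention
  hav <- function(p1, p2) geosphere::distHaversine(p1, p2, r = R_m)
  hull_idx <- if (nrow(pts) >= 3) grDevices::chull(pts) else integer()
  degenerate <- length(hull_idx) < 3
  if (degenerate) {
    d <- geosphere::distm(centers, pts, fun = hav)
    dist_m <- apply(d, 1, min)
    inside <- rep(FALSE, nrow(centers))
  } else {
    hull <- pts[hull_idx, , drop = FALSE]
    ring <- rbind(hull, hull[1, , drop = FALSE])
    inside <- mgcv::in.out(ring, centers)
    dist_m <- rep(Inf, nrow(centers))
    outside <- which(!inside)
    if (length(outside))
      dist_m[outside] <- geosphere::dist2Line(centers[outside, , drop = FALSE],
                                              ring, distfun = hav)[, "distance"]
    dist_m[inside] <- 0
  }
  in_buffer <- inside | dist_m <= buffer_km * 1000
  presence_cells <- unique(grid_cell_index(grid, occ$lon, occ$lat))
  presence_cells <- presence_cells[!is.na(presence_cells)]
  cells <- which(in_buffer & as.vector(valid))
  cells <- setdiff(cells, presence_cells)
  if (length(cells) == 0) stop("background region is empty")
  structure(list(cells = as.integer(cells), grid = grid,
                 buffer_km = buffer_km,
                 hull = if (degenerate) "point-buffer fallback"
                        else "convex hull + great-circle buffer",
                 presence_cells = presence_cells),
            class = "background_region")
}

#' @export
print.background_region <- function(x, ...) {
  cat(sprintf("<background_region> %d cells (%s, %g km buffer)\n",
              length(x$cells), x$hull, x$buffer_km))
  invisible(x)
}

#' Sample replicate pseudo-absence sets
#'
#' Each replicate draws `n` distinct background cells uniformly without
#' replacement, using a replicate-derived seed, and returns their
#' centers. No pseudo-absence can share a cell with a presence because
#' presence cells are excluded from the region at construction.
#'
#' @param region a [build_background_region()] result.
#' @param n points per replicate (default 500).
#' @param replicates number of replicate sets (default 3).
#' @param seed master seed; replicate `r` uses
#'   `derive_seed(seed, "pa", r)`.
#' @return list of data frames (`replicate`, `lon`, `lat`, `cell`), one
#'   per replicate.
#' @export
sample_pseudo_absences <- function(region, n = 500, replicates = 3,
                                   seed = 1) {
  stopifnot(inherits(region, "background_region"))
  if (length(region$cells) < n)
    stop("background region has ", length(region$cells),
         " cells; cannot draw ", n, " pseudo-absences")
  lapply(seq_len(replicates), function(r) {
    set.seed(derive_seed(seed, "pa", r))
    cells <- sample(region$cells, n)
    xy <- grid_cell_centers(region$grid, cells)
    data.frame(replicate = r, lon = xy[, "lon"], lat = xy[, "lat"],
               cell = cells)
  })
}

#' Write pseudo-absence replicates to CSV
#'
#' @param pa_sets result of [sample_pseudo_absences()].
#' @param path output CSV path (`replicate,lon,lat`).
#' @return `path`, invisibly.
#' @export
write_pseudo_absences <- function(pa_sets, path) {
  all <- do.call(rbind, pa_sets)
  utils::write.csv(all[, c("replicate", "lon", "lat")], path,
                   row.names = FALSE)
  invisible(path)
}
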