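# Shared fixtures, built once per test session.

.chsdm_fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .chsdm_fixtures))
    assign(name, builder(), envir = .chsdm_fixtures)
  get(name, envir = .chsdm_fixtures)
}

# a small but realistic world: 30 x 30 cells, 50 presences
small_world <- function() fixture("small_world", function() {
  spec <- world_spec(n_rows = 30, n_cols = 30, cell_size = 0.3, seed = 2)
  env <- generate_environment(spec)
  cats <- generate_categorical_layers(spec, env$layers$elev)
  vs <- default_virtual_species(n_presences = 50)
  suit <- true_suitability(env, vs)
  occ <- sample_occurrences(suit, vs, seed = 3)
  region <- build_background_region(occ, env$layers$bio1, 200)
  pa <- sample_pseudo_absences(region, n = 100, replicates = 2, seed = 4)
  train <- build_training_set(occ, pa[[1]], env, default_predictors())
  list(spec = spec, env = env, cats = cats, vs = vs, suit = suit,
       occ = occ, region = region, pa = pa, train = train)
})

# hand-coded haversine, independent of geosphere
haversine_km <- function(lon1, lat1, lon2, lat2, R = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# brute-force Moran's I with rook neighbours
morans_i <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  x <- m - mean(m)
  num <- 0; wsum <- 0
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    for (d in list(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))) {
      r2 <- r + d[1]; c2 <- cl + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        num <- num + x[r, cl] * x[r2, c2]
        wsum <- wsum + 1
      }
    }
  }
  (length(m) / wsum) * num / sum(x^2)
}
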