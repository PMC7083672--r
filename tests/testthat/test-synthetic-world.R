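test_that("environment generation is deterministic and validates its spec", {
  spec <- world_spec(n_rows = 12, n_cols = 15, cell_size = 0.2, seed = 11)
  a <- generate_environment(spec)
  b <- generate_environment(spec)
  for (nm in names(a$layers))
    expect_identical(a$layers[[nm]]$values, b$layers[[nm]]$values)
  expect_gte(length(a$layers), 9)
  expect_true(all(a$layers$bio12$values >= 0))
  expect_true(all(a$layers$bio19$values >= 0))
  expect_error(world_spec(n_rows = 5), "degenerate")
  expect_error(world_spec(cell_size = 0), "positive")
  expect_error(world_spec(suitable_veg_classes = 1:6), "subset")
})

test_that("temperature decreases with latitude on average", {
  env <- small_world()$env
  t_by_row <- rowMeans(env$layers$bio1$values)  # row 1 = north
  expect_lt(mean(t_by_row[1:5]), mean(t_by_row[26:30]))
})

test_that("zero autocorrelation length gives spatially independent noise", {
  spec <- world_spec(n_rows = 40, n_cols = 40, autocorr_length = 0, seed = 5)
  env <- generate_environment(spec)
  # bio4 is pure noise around its constant mean
  expect_lt(abs(morans_i(env$layers$bio4$values)), 0.08)
  # and a smoothed world is strongly autocorrelated by comparison
  spec2 <- world_spec(n_rows = 40, n_cols = 40, autocorr_length = 5, seed = 5)
  env2 <- generate_environment(spec2)
  expect_gt(morans_i(env2$layers$bio4$values), 0.5)
})

test_that("flat elevation yields zero slope and the flat-aspect sentinel", {
  flat <- grid_create(matrix(1000, 10, 10), 0, 0, 0.1)
  terr <- terrain_slope_aspect(flat)
  expect_true(all(terr$slope$values == 0))
  expect_true(all(terr$aspect$values == -1))
})

test_that("slope responds to a known planar gradient", {
  # plane rising 1 m per metre eastward on a planar grid: slope = 45 degrees
  z <- matrix(rep(seq(0, 90, by = 10), each = 10), 10, 10)  # z = 10 * (col - 1)
  g <- grid_create(z, 0, 0, 10, crs_label = "planar")
  terr <- terrain_slope_aspect(g)
  expect_equal(terr$slope$values[5, 5], 45, tolerance = 1e-6)
  # steepest descent points west: compass aspect 270 degrees
  expect_equal(terr$aspect$values[5, 5], 270, tolerance = 1e-6)
})

test_that("categorical layers have the declared codomain and track elevation", {
  sw <- small_world()
  spec <- world_spec(n_rows = 30, n_cols = 30, cell_size = 0.3,
                     n_soil_classes = 4, seed = 2)
  cats <- generate_categorical_layers(spec, sw$env$layers$elev)
  expect_true(all(cats$soil$values %in% 1:4))
  expect_error(world_spec(n_veg_classes = 1), "at least 2")
  # vegetation classes increase with elevation on average
  by_class <- tapply(sw$env$layers$elev$values, sw$cats$vegetation$values, mean)
  expect_true(all(diff(by_class) > 0))
})

test_that("noise-free vegetation bins sit exactly at elevation terciles", {
  spec <- world_spec(n_rows = 12, n_cols = 12, n_veg_classes = 3,
                     suitable_veg_classes = 3, seed = 7)
  ramp <- grid_create(matrix(seq(100, 3000, length.out = 144), 12, 12),
                      spec$xmin, spec$ymin, spec$cell_size)
  cats <- generate_categorical_layers(spec, ramp, veg_noise = 0)
  terc <- quantile(ramp$values, c(1 / 3, 2 / 3), type = 7)
  expected <- matrix(cut(ramp$values, c(-Inf, terc, Inf), labels = FALSE),
                     12, 12)
  expect_identical(cats$vegetation$values, expected * 1)
})

test_that("true suitability follows the product-Gaussian closed form", {
  g1 <- grid_create(matrix(5, 3, 3), 0, 0, 1)
  g2 <- grid_create(matrix(8, 3, 3), 0, 0, 1)
  env <- stack_create(list(a = g1, b = g2))
  vs <- virtual_species_spec(c(a = 5, b = 8), c(a = 1, b = 2),
                             n_presences = 20)
  expect_equal(true_suitability(env, vs)$values[1, 1], 1.0)
  # one variable displaced by exactly one niche width
  env2 <- stack_create(list(a = grid_create(matrix(6, 3, 3), 0, 0, 1),
                            b = g2))
  expect_equal(true_suitability(env2, vs)$values[1, 1], exp(-0.5))
  # product structure: joint equals product of marginals
  sw <- small_world()
  vs1 <- virtual_species_spec(c(bio1 = 8), c(bio1 = 2), 20)
  vs2 <- virtual_species_spec(c(bio12 = 800), c(bio12 = 400), 20)
  vs12 <- virtual_species_spec(c(bio1 = 8, bio12 = 800),
                               c(bio1 = 2, bio12 = 400), 20)
  expect_equal(true_suitability(sw$env, vs12)$values,
               true_suitability(sw$env, vs1)$values *
                 true_suitability(sw$env, vs2)$values)
  expect_error(true_suitability(sw$env, virtual_species_spec(
    c(nope = 1), c(nope = 1), 20)), "missing")
})

test_that("occurrence sampling returns unique cells enriched in suitability", {
  sw <- small_world()
  # forced one-hot surface
  v <- matrix(0, 30, 30); v[7, 9] <- 1
  onehot <- grid_create(v, 0, 0, 1)
  vs1 <- virtual_species_spec(c(x = 0), c(x = 1), n_presences = 20)
  vs1$n_presences <- 1L
  occ1 <- sample_occurrences(onehot, vs1, seed = 1)
  expect_equal(occ1$cell, 7L + 8L * 30L)
  # default study size: 99 unique points
  vs99 <- default_virtual_species(n_presences = 99)
  occ99 <- sample_occurrences(sw$suit, vs99, seed = 5)
  expect_equal(nrow(occ99), 99)
  expect_equal(anyDuplicated(occ99[, c("lon", "lat")]), 0L)
  # enrichment: sampled cells are markedly more suitable than background
  vs200 <- default_virtual_species(n_presences = 200)
  occ200 <- sample_occurrences(sw$suit, vs200, seed = 6)
  expect_gt(mean(occ200$true_suitability),
            mean(sw$suit$values, na.rm = TRUE))
  expect_error(sample_occurrences(onehot, vs99, seed = 1), "eligible")
})

test_that("scenario deltas shift the named layers and leave the rest byte-identical", {
  env <- small_world()$env
  idd <- scenario_delta("g", "r")
  expect_identical(generate_future_stack(env, idd)$layers$bio1$values,
                   env$layers$bio1$values)
  d <- scenario_delta("g", "r", additive_shift = c(bio1 = 2),
                      multiplicative_shift = c(bio12 = 1.1))
  fut <- generate_future_stack(env, d)
  expect_equal(fut$layers$bio1$values - env$layers$bio1$values,
               matrix(2, 30, 30))
  expect_equal(fut$layers$bio12$values, env$layers$bio12$values * 1.1)
  for (nm in c("elev", "slope", "aspect"))
    expect_identical(fut$layers[[nm]]$values, env$layers[[nm]]$values)
  expect_error(generate_future_stack(env, scenario_delta(
    "g", "r", additive_shift = c(nope = 1))), "absent")
  expect_error(scenario_delta("g", "r", multiplicative_shift = c(bio12 = 0)),
               "positive")
})

test_that("zones partition all cells, with quadrants for n = 4", {
  spec <- world_spec(n_rows = 10, n_cols = 10, seed = 1)
  z1 <- generate_zones(spec, 1)
  expect_true(all(z1$values == 1))
  z4 <- generate_zones(spec, 4)
  expect_equal(sort(unique(as.vector(z4$values))), 1:4)
  expect_true(all(table(z4$values) == 25))
  expect_equal(z4$values[1, 1], 1)
  expect_equal(z4$values[1, 10], 2)
  expect_equal(z4$values[10, 1], 3)
  expect_equal(z4$values[10, 10], 4)
  z7 <- generate_zones(spec, 7)
  expect_equal(sum(table(z7$values)), 100)
  expect_equal(length(unique(as.vector(z7$values))), 7)
  expect_error(generate_zones(spec, 101), "exceeds")
})
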