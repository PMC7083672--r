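test_that("cell areas follow the spherical band formula", {
  # planar grid: declared constant
  gp <- grid_create(matrix(0, 5, 5), 0, 0, 1, crs_label = "planar")
  expect_true(all(cell_area_grid(gp, cell_area_km2 = 1)$values == 1))
  expect_error(cell_area_grid(gp), "declared")
  # equatorial 30-arc-second cell vs numeric integration of R^2 cos(phi)
  cs <- 30 / 3600
  g <- grid_create(matrix(0, 2, 2), 0, -cs, cs)  # rows straddle the equator
  a <- cell_area_grid(g)
  R <- 6371
  dlam <- cs * pi / 180
  oracle <- R^2 * dlam *
    integrate(function(phi) cos(phi), 0, cs * pi / 180)$value
  expect_equal(a$values[1, 1], oracle, tolerance = 1e-9)
  # roughly the nominal "1 km^2" of a 30-arc-second cell
  expect_equal(a$values[1, 1], 0.86, tolerance = 0.01)
  # row areas shrink toward the pole
  g2 <- grid_create(matrix(0, 10, 10), 0, 30, 0.5)
  a2 <- cell_area_grid(g2)
  expect_true(all(diff(a2$values[, 1]) > 0))  # row 1 = north = smaller
})

test_that("zonal area tables match brute-force tallies and close to 100%", {
  # all-suitable single zone on a planar grid
  chs <- grid_create(matrix(2, 10, 10), 0, 0, 1, crs_label = "planar")
  zones <- grid_create(matrix(1, 10, 10), 0, 0, 1, crs_label = "planar")
  areas <- cell_area_grid(chs, cell_area_km2 = 1)
  tab <- zonal_area_table(chs, zones, areas)
  expect_equal(tab$area_km2[tab$zone == "1"], 100)
  expect_equal(tab$percent_of_zone[tab$zone == "1"], 100)
  # two equal zones, classes split 50/50 inside each
  cls <- grid_create(matrix(rep(c(0, 2), each = 5), 10, 10), 0, 0, 1,
                     crs_label = "planar")
  zn <- grid_create(matrix(rep(c(1, 2), each = 50), 10, 10), 0, 0, 1,
                    crs_label = "planar")
  tab2 <- zonal_area_table(cls, zn, areas)
  for (z in c("1", "2"))
    expect_true(all(tab2$percent_of_zone[tab2$zone == z] == 50))
  # random map: totals equal per-cell enumeration
  set.seed(90)
  cm <- matrix(sample(0:2, 400, replace = TRUE), 20, 20)
  zm <- matrix(sample(1:3, 400, replace = TRUE), 20, 20)
  chs3 <- grid_create(cm, 100, 30, 0.1)
  zones3 <- grid_create(zm, 100, 30, 0.1)
  ar3 <- cell_area_grid(chs3)
  tab3 <- zonal_area_table(chs3, zones3, ar3)
  for (z in 1:3) for (k in 0:2) {
    oracle <- sum(ar3$values[zm == z & cm == k])
    expect_equal(tab3$area_km2[tab3$zone == as.character(z) &
                                 tab3$class == k], oracle)
  }
  # percentages within a zone sum to 100
  for (z in unique(tab3$zone))
    expect_equal(sum(tab3$percent_of_zone[tab3$zone == z]), 100)
  # per-class zone sums equal the totals row
  for (k in 0:2)
    expect_equal(sum(tab3$area_km2[tab3$zone != "total" & tab3$class == k]),
                 tab3$area_km2[tab3$zone == "total" & tab3$class == k])
})

test_that("transition tables cross-tabulate areas with exact marginals", {
  ar <- cell_area_grid(grid_create(matrix(0, 10, 10), 0, 0, 1,
                                   crs_label = "planar"), 1)
  same <- grid_create(matrix(sample(0:2, 100, TRUE), 10, 10), 0, 0, 1,
                      crs_label = "planar")
  tt <- transition_table(same, same, ar)
  expect_true(all(tt[upper.tri(tt) | lower.tri(tt)] == 0))
  # all-suitable to all-unsuitable: one off-diagonal cell holds everything
  a <- grid_create(matrix(2, 10, 10), 0, 0, 1, crs_label = "planar")
  b <- grid_create(matrix(0, 10, 10), 0, 0, 1, crs_label = "planar")
  tt2 <- transition_table(a, b, ar)
  expect_equal(tt2["2", "0"], 100)
  expect_equal(sum(tt2), 100)
  # random pair: entries match brute force, marginals match area tables
  set.seed(91)
  ma <- matrix(sample(0:2, 100, TRUE), 10, 10)
  mb <- matrix(sample(0:2, 100, TRUE), 10, 10)
  ga <- grid_create(ma, 0, 0, 1, crs_label = "planar")
  gb <- grid_create(mb, 0, 0, 1, crs_label = "planar")
  tt3 <- transition_table(ga, gb, ar)
  for (i in 0:2) for (j in 0:2)
    expect_equal(tt3[as.character(i), as.character(j)],
                 sum(ma == i & mb == j))
  zones <- grid_create(matrix(1, 10, 10), 0, 0, 1, crs_label = "planar")
  ta <- zonal_area_table(ga, zones, ar)
  tb <- zonal_area_table(gb, zones, ar)
  expect_equal(unname(rowSums(tt3)),
               ta$area_km2[ta$zone == "total"])
  expect_equal(unname(colSums(tt3)),
               tb$area_km2[tb$zone == "total"])
})

test_that("response curves profile one variable with the rest at medians", {
  sw <- small_world()
  # a predictor that ignores everything: flat curve, all-or-nothing range
  flat <- response_curve(function(nd) rep(0.7, nrow(nd)), sw$env, "bio1")
  expect_true(all(flat$probability == 0.7))
  rng <- attr(flat, "suitable_range")
  expect_equal(nrow(rng), 1)
  expect_equal(unname(rng[1, "lower"]), min(flat$value))
  expect_equal(unname(rng[1, "upper"]), max(flat$value))
  # a predictor equal to the species' bio1 response recovers the optimum
  # (clipped to the landscape's observed bio1 range)
  f <- function(nd) exp(-(nd$bio1 - 8)^2 / (2 * 2^2))
  rc <- response_curve(f, sw$env, "bio1", n_points = 200)
  expect_true(all(rc$probability >= 0 & rc$probability <= 1))
  peak <- rc$value[which.max(rc$probability)]
  target <- min(max(8, min(rc$value)), max(rc$value))
  expect_lt(abs(peak - target), 0.05 * diff(range(rc$value)))
  # the suitable range covers the optimum side of the Gaussian
  rng2 <- attr(rc, "suitable_range")
  expect_equal(nrow(rng2), 1)
  expect_lte(unname(rng2[1, "lower"]), target)
  expect_gt(unname(rng2[1, "upper"]), target)
  # constant variable: empty curve with a warning
  cg <- stack_create(list(a = grid_create(matrix(1, 5, 5), 0, 0, 1),
                          b = grid_create(matrix(rnorm(25), 5, 5), 0, 0, 1)))
  expect_warning(rc3 <- response_curve(function(nd) rep(1, nrow(nd)),
                                       cg, "a"), "constant")
  expect_equal(nrow(rc3), 0)
})

test_that("permutation importance isolates the variables a predictor uses", {
  sw <- small_world()
  tab <- sample_stack_cells(sw$env, c("bio1", "bio4", "bio12"), n = 500,
                            seed = 1)
  # single-variable predictor: all importance on that variable
  f1 <- function(nd) plogis(nd$bio1)
  imp1 <- variable_importance(f1, tab, n_shuffles = 3, seed = 2)
  expect_equal(sum(imp1), 1)
  expect_gt(imp1[["bio1"]], 0.98)
  expect_lt(imp1[["bio4"]], 0.02)
  # unused variable scores near zero
  f2 <- function(nd) plogis(nd$bio1 + 0.5 * nd$bio4)
  imp2 <- variable_importance(f2, tab, n_shuffles = 3, seed = 3)
  expect_lt(imp2[["bio12"]], 0.02)
  expect_gt(imp2[["bio1"]], imp2[["bio4"]])
})

test_that("the shipped regional area table is internally consistent", {
  tab <- published_region_areas()
  expect_equal(nrow(tab), 6)
  cons <- region_area_consistency(tab)
  # national totals are sums of the regional areas
  expect_equal(cons$total_suitable_km2e3,
               sum(tab$suitable_km2e3, na.rm = TRUE))
  # recomputed percentages agree with the printed ones at 2 decimals
  printed <- tab[!is.na(tab$suitable_pct), ]
  expect_equal(round(cons$recomputed_pct$suitable_pct, 2),
               printed$suitable_pct)
})
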