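#' Pipeline configuration
#'
#' Bundles every knob of the comprehensive habitat suitability analysis
#' with the protocol defaults: 3 pseudo-absence sets of 500 points in a
#' 200 km buffered hull, 70/30 splits with 10 repeats over the
#' ten-algorithm registry (300 single models), mean-TSS filtering at 0.5,
#' TSS-weighted aggregation, a 75/25 x 10 soil model, 0.3/0.5 class
#' thresholds, and GCM-then-RCP scenario averaging.
#'
#' @param world a [world_spec()].
#' @param species a [virtual_species_spec()].
#' @param predictors predictor layer names (default
#'   [default_predictors()]).
#' @param select_predictors if `TRUE`, run the Pearson/PCA screen on the
#'   candidate predictors instead of using them as-is.
#' @param r_threshold collinearity ceiling for the screen.
#' @param buffer_km,n_pa,n_pa_sets pseudo-absence protocol.
#' @param algorithms algorithm ids to run.
#' @param split,repeats evaluation protocol.
#' @param min_mean_tss ensemble inclusion cutoff.
#' @param sre_tail SRE tail quantile.
#' @param t_low,t_high CHS class thresholds.
#' @param soil_split,soil_reps soil-model protocol.
#' @param scenarios nested delta list from [default_scenario_deltas()]
#'   (set to `list()` to skip future projections).
#' @param n_zones zones for the area reports.
#' @param n_eval_presences,n_eval_background size of the independent
#'   holdout used to score the ensemble.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional output directory (CSV tables + ASCII grids).
#' @return an object of class `chs_config`.
#' @export
chs_config <- function(world = world_spec(),
                       species = default_virtual_species(),
                       predictors = default_predictors(),
                       select_predictors = FALSE, r_threshold = 0.8,
                       buffer_km = 200, n_pa = 500, n_pa_sets = 3,
                       algorithms = sdm_algorithm_ids(),
                       split = 0.7, repeats = 10, min_mean_tss = 0.5,
                       sre_tail = 0.025, t_low = 0.3, t_high = 0.5,
                       soil_split = 0.75, soil_reps = 10,
                       scenarios = default_scenario_deltas(),
                       n_zones = 4, n_eval_presences = 200,
                       n_eval_background = 500, seed = 1,
                       out_dir = NULL) {
  structure(as.list(environment()), class = "chs_config")
}

#' Validate a pipeline configuration
#'
#' Reports every invariant violation at once rather than stopping at the
#' first.
#'
#' @param config a [chs_config()].
#' @return character vector of findings (empty when valid).
#' @export
validate_config <- function(config) {
  findings <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) findings <<- c(findings, msg)
  chk(inherits(config$world, "world_spec"), "world is not a world_spec")
  chk(inherits(config$species, "virtual_species"),
      "species is not a virtual_species")
  chk(config$split > 0 && config$split < 1, "split must be in (0, 1)")
  chk(config$soil_split > 0 && config$soil_split < 1,
      "soil_split must be in (0, 1)")
  chk(config$t_low >= 0 && config$t_low < config$t_high &&
        config$t_high <= 1,
      "class thresholds must satisfy 0 <= t_low < t_high <= 1")
  bad_alg <- setdiff(toupper(config$algorithms), sdm_algorithm_ids())
  chk(length(bad_alg) == 0,
      paste("unknown algorithm id(s):", paste(bad_alg, collapse = ", ")))
  chk(config$n_pa >= 1 && config$n_pa_sets >= 1 && config$repeats >= 1,
      "n_pa, n_pa_sets and repeats must be positive")
  chk(config$sre_tail >= 0 && config$sre_tail < 0.5,
      "sre_tail must be in [0, 0.5)")
  chk(config$buffer_km >= 0, "buffer_km must be nonnegative")
  chk(config$n_zones >= 1, "n_zones must be >= 1")
  findings
}

write_grid_out <- function(grid, dir, name, manifest) {
  path <- file.path(dir, paste0(name, ".asc"))
  write_ascii_grid(grid, path)
  c(manifest, stats::setNames(list(path), name))
}

#' Run the full comprehensive habitat suitability pipeline
#'
#' Executes every stage in dependency order: simulate the synthetic world
#' (environment, soil/vegetation mosaics, zones, virtual species,
#' occurrences), select predictors, build the buffered-hull background
#' and pseudo-absence replicates, fit and score the single-model
#' protocol, filter and weight the ensemble, fit the soil model and
#' vegetation mask, classify comprehensive habitat suitability for the
#' current period, project the fitted ensemble onto every future
#' GCM x RCP stack with GCM-then-RCP averaging, and assemble zonal area
#' and transition reports.
#'
#' @param config a [chs_config()]; rejected before any stage runs if
#'   [validate_config()] reports findings.
#' @return an object of class `chs_pipeline_result` (see fields in the
#'   examples of the package vignette); when `config$out_dir` is set,
#'   CSV tables and ASCII grids are written and listed in `$manifest`.
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  if (length(findings))
    stop("invalid config:\n", paste("-", findings, collapse = "\n"))
  seed <- config$seed
  manifest <- list()
  dir <- config$out_dir
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  # --- synthetic world ---------------------------------------------------
  env <- generate_environment(config$world)
  cats <- generate_categorical_layers(config$world, env$layers$elev)
  zones <- generate_zones(config$world, config$n_zones)
  suit <- true_suitability(env, config$species)
  occ <- sample_occurrences(suit, config$species,
                            seed = derive_seed(seed, "occurrences"))

  # --- predictor selection ----------------------------------------------
  if (config$select_predictors) {
    tab <- sample_stack_cells(env, config$predictors, n = 2000,
                              seed = derive_seed(seed, "selection"))
    sel <- select_variables(tab, config$r_threshold)
    vars <- sel$selected
  } else {
    sel <- NULL
    vars <- config$predictors
  }

  # --- pseudo-absences ---------------------------------------------------
  ref_grid <- env$layers[[vars[1]]]
  region <- build_background_region(occ, ref_grid, config$buffer_km)
  pa_sets <- sample_pseudo_absences(region, n = config$n_pa,
                                    replicates = config$n_pa_sets,
                                    seed = seed)

  # --- single-model protocol --------------------------------------------
  datasets <- lapply(pa_sets, function(pa)
    build_training_set(occ, pa, env, vars))
  runs <- run_protocol(datasets, config$algorithms,
                       n_repeats = config$repeats,
                       fraction = config$split, seed = seed,
                       sre_tail = config$sre_tail)

  # --- ensemble ----------------------------------------------------------
  retained <- filter_runs(runs, config$min_mean_tss)
  weights <- compute_weights(retained)
  bt_current <- ensemble_predict_stack(retained, weights, env)

  # independent holdout score for the ensemble
  eval_species <- config$species
  eval_species$n_presences <- as.integer(config$n_eval_presences)
  eval_occ <- sample_occurrences(suit, eval_species,
                                 seed = derive_seed(seed, "eval-occ"))
  set.seed(derive_seed(seed, "eval-bg"))
  bg_cells <- sample(region$cells, min(config$n_eval_background,
                                       length(region$cells)))
  bg_xy <- grid_cell_centers(ref_grid, bg_cells)
  eval_table <- build_training_set(
    eval_occ, data.frame(lon = bg_xy[, "lon"], lat = bg_xy[, "lat"]),
    env, vars)
  ensemble_eval <- evaluate_ensemble(retained, weights, eval_table)

  # --- habitat overlay ---------------------------------------------------
  soil_model <- fit_soil_maxent(occ, cats$soil, region,
                                split = config$soil_split,
                                replicates = config$soil_reps, seed = seed)
  S <- predict_soil_suitability(soil_model, cats$soil)
  V <- binarize_vegetation(cats$vegetation,
                           config$world$suitable_veg_classes)
  chs_maps <- list(current = classify_chs(bt_current, S, V,
                                          config$t_low, config$t_high))
  bt_maps <- list(current = bt_current)

  # --- scenario projection ----------------------------------------------
  for (period in names(config$scenarios)) {
    deltas <- config$scenarios[[period]]
    maps <- lapply(deltas, function(d)
      ensemble_predict_stack(retained, weights,
                             generate_future_stack(env, d)))
    grouping <- data.frame(
      gcm = vapply(deltas, function(d) d$gcm_id, ""),
      rcp = vapply(deltas, function(d) d$rcp_id, ""))
    sc <- scenario_ensemble(unname(maps), grouping)
    bt_maps[[period]] <- sc$final
    chs_maps[[period]] <- classify_chs(sc$final, S, V, config$t_low,
                                       config$t_high)
  }

  # --- reporting ---------------------------------------------------------
  cell_areas <- cell_area_grid(ref_grid)
  area_tables <- lapply(chs_maps, zonal_area_table, zones = zones,
                        cell_areas = cell_areas, classes = 0:2)
  periods <- names(chs_maps)
  transitions <- list()
  if (length(periods) > 1)
    for (i in seq_len(length(periods) - 1)) {
      key <- paste(periods[i], periods[i + 1], sep = "_to_")
      transitions[[key]] <- transition_table(chs_maps[[periods[i]]],
                                             chs_maps[[periods[i + 1]]],
                                             cell_areas, classes = 0:2)
    }
  predictor_tab <- sample_stack_cells(env, vars, n = 2000,
                                      seed = derive_seed(seed, "imp"))
  em_fun <- function(nd) ensemble_predict_points(retained, weights, nd)
  importance <- variable_importance(em_fun, predictor_tab, vars,
                                    n_shuffles = 3,
                                    seed = derive_seed(seed, "shuffle"))
  # anchor profiles at the presence medians so curves stay identifiable
  occ_vals <- extract_values(stack_create(env$layers[vars]),
                             occ$lon, occ$lat)
  anchor <- vapply(vars, function(w)
    stats::median(occ_vals[[w]], na.rm = TRUE), 0)
  curves <- lapply(stats::setNames(nm = names(config$species$response_means)),
                   function(v) response_curve(em_fun, env, v, vars = vars,
                                              at = anchor))

  # --- outputs -----------------------------------------------------------
  if (!is.null(dir)) {
    utils::write.csv(as.data.frame(runs),
                     file.path(dir, "run_metrics.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(weights),
                     file.path(dir, "ensemble_weights.csv"),
                     row.names = FALSE)
    write_occurrences(occ, file.path(dir, "occurrences.csv"))
    write_pseudo_absences(pa_sets, file.path(dir, "pseudo_absences.csv"))
    for (p in names(bt_maps)) {
      write_ascii_grid(bt_maps[[p]], file.path(dir, paste0("BT_", p, ".asc")))
      write_ascii_grid(chs_maps[[p]], file.path(dir, paste0("CHS_", p, ".asc")))
      utils::write.csv(area_tables[[p]],
                       file.path(dir, paste0("areas_", p, ".csv")),
                       row.names = FALSE)
    }
    manifest <- list(
      out_dir = dir,
      files = list.files(dir),
      n_runs = length(runs),
      n_retained = attr(weights, "h"))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  } else {
    manifest <- list(n_runs = length(runs),
                     n_retained = attr(weights, "h"))
  }

  structure(list(
    config = config, env = env, soil = cats$soil,
    vegetation = cats$vegetation, zones = zones,
    true_suitability = suit, occurrences = occ, selection = sel,
    vars = vars, region = region, pa_sets = pa_sets, runs = runs,
    retained = retained, weights = weights,
    excluded_algorithms = attr(retained, "excluded_algorithms"),
    ensemble_eval = ensemble_eval, soil_model = soil_model,
    S = S, V = V, bt_maps = bt_maps, chs_maps = chs_maps,
    cell_areas = cell_areas, area_tables = area_tables,
    transitions = transitions, importance = importance,
    response_curves = curves, manifest = manifest
  ), class = "chs_pipeline_result")
}

#' @export
print.chs_pipeline_result <- function(x, ...) {
  cat("<chs_pipeline_result>\n")
  cat(sprintf("  %d single-model runs; %d retained in ensemble (excluded: %s)\n",
              length(x$runs), attr(x$weights, "h"),
              if (length(x$excluded_algorithms))
                paste(x$excluded_algorithms, collapse = ", ") else "none"))
  cat(sprintf("  ensemble holdout TSS %.3f, AUC %.3f; soil AUC %.3f\n",
              x$ensemble_eval$tss, x$ensemble_eval$auc,
              mean(x$soil_model$auc)))
  for (p in names(x$area_tables)) {
    at <- x$area_tables[[p]]
    s <- at[at$zone == "total" & at$class == 2, ]
    cat(sprintf("  %s: suitable habitat %.1f km2 (%.2f%% of land)\n",
                p, s$area_km2, s$percent_of_zone))
  }
  invisible(x)
}
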