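#' Default pipeline configuration
#'
#' Every stage parameter in one nested list, with the study defaults:
#' 2015-2022 year window, 100 m maximum coordinate uncertainty, 10x
#' KDE-weighted background, 100 m focal radius and analysis resolution,
#' Spearman 0.7 collinearity screen, smooths capped at 4 df with
#' double-penalty shrinkage, 10-fold random and spatially blocked (5 km)
#' cross-validation, core thresholds 0.5/0.9 with 300 m linkage, top-1%
#' pinch clusters, top-10% corridor mask, and 20,000 validation background
#' points.
#'
#' @param seed global integer seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = "pollinet-output",
    scenario = list(
      extent = c(6400, 6400), fine_res = 10, analysis_res = 100,
      smoothness = 200, n_presence_per_species = 150, bias_strength = 1,
      contamination = c(duplicates = 0.05, uncertain = 0.05,
                        undated = 0.03, out_year = 0.03),
      years = c(2015L, 2022L)),
    filter = list(year_min = 2015, year_max = 2022, max_uncertainty_m = 100),
    background = list(multiplier = 10),
    covariates = list(radius_m = 100, rho_threshold = 0.7),
    model = list(df_max = 4, spatial_rank = 30, sweeps = 2),
    validation = list(k = 10, block_size_m = 5000),
    connectivity = list(tau = 0.5, tau_critical = 0.9, min_cells = 2,
                        link_dist_m = 300, epsilon = 1e-3, neighbourhood = 8,
                        max_nodes = 25),
    pinch = list(percentile = 99),
    comparison = list(top_fraction = 0.10, n_background = 20000,
                      n_independent_per_species = 100),
    planner = list(source_class = "grassland", min_patch_ha = 0.5,
                   buffer_m = 300)
  )
}

#' Demo configuration: a small synthetic study
#'
#' The bundled demonstration scenario: a 6.4 km x 6.4 km landscape (64 x 64
#' analysis cells at 100 m over a 10 m land-cover grid), three species, 150
#' clean presences each. Spatial CV blocks are 800 m so that enough blocks
#' exist at this extent.
#'
#' @param seed global integer seed.
#' @export
demo_config <- function(seed = 1L) {
  cfg <- default_config(seed)
  cfg$validation$block_size_m <- 800
  cfg
}

check_config_keys <- function(cfg, ref = default_config(), path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  for (nm in names(cfg))
    if (is.list(ref[[nm]]) && is.list(cfg[[nm]]))
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "$"))
  invisible(TRUE)
}

#' Read / write a pipeline configuration (YAML)
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path YAML file path.
#' @return full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  check_config_keys(user)
  cfg <- default_config()
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      v <- over[[nm]]
      # YAML maps come back as named lists; flat parameter vectors
      # (e.g. contamination) are restored to named numerics
      if (is.list(v) && length(v) && !any(vapply(v, is.list, logical(1))) &&
          !is.list(base[[nm]]))
        v <- unlist(v)
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(v))
        merge_in(base[[nm]], v) else v
    }
    base
  }
  cfg <- merge_in(cfg, user)
  cfg$scenario$years <- as.integer(cfg$scenario$years)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  # yaml drops the names of named atomic vectors; write them as maps
  mapify <- function(x) {
    if (is.list(x)) lapply(x, mapify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(mapify(config), path)
  invisible(path)
}

config_fingerprint <- function(config) {
  config$out_dir <- NULL      # fingerprint the science, not the file layout
  s <- yaml::as.yaml(config)
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read / write occurrence records (CSV)
#'
#' Columns: `species`, `x`, `y`, `year`, `uncertainty_m` (metres, projected
#' planar coordinates). Missing mandatory columns are reported by name.
#'
#' @param path CSV file path.
#' @export
read_records <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y", "year", "uncertainty_m")
  miss <- setdiff(need, names(r))
  if (length(miss))
    stop("records file is missing column(s): ", paste(miss, collapse = ", "))
  r
}

#' @rdname read_records
#' @param records data.frame of records.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Executes every stage in order: landscape synthesis, ground-truth
#' suitability and occurrence generation, record filtering (checked against
#' the contamination ledger), KDE background sampling, predictor stack and
#' collinearity screen, per-species model fitting with random and spatially
#' blocked cross-validation, map combination, resistance conversion, core
#' delineation, all-pairs circuit solve, pinch-point analysis, synthetic
#' planner corridors, and the four-category gap analysis with independent
#' records. Artefacts (rasters as .asc, polygons as GeoJSON, records as CSV,
#' reports as JSON) are written under `config$out_dir`, stamped with the
#' seed and a configuration fingerprint.
#'
#' @param config configuration list (see [default_config()], [demo_config()]).
#' @param quiet suppress progress messages?
#' @return (invisibly) a list with every intermediate and final object.
#' @export
run_pipeline <- function(config = demo_config(), quiet = FALSE) {
  check_config_keys(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  say("[1/9] synthesising landscape (seed %d, fingerprint %s)", seed,
      config_fingerprint(config))

  sc <- config$scenario
  scen <- synthetic_scenario(
    seed = seed, extent = sc$extent, fine_res = sc$fine_res,
    analysis_res = sc$analysis_res, smoothness = sc$smoothness,
    n_presence_per_species = sc$n_presence_per_species,
    bias_strength = sc$bias_strength, contamination = sc$contamination,
    years = sc$years)
  land <- generate_landscape(scen)
  write_raster(land$landcover, file.path(out_dir, "landcover.asc"))
  write_raster(land$elevation, file.path(out_dir, "elevation.asc"))
  write_raster(land$population, file.path(out_dir, "population.asc"))

  say("[2/9] ground truth + occurrence records")
  raw_stack <- build_predictor_stack(land, analysis_res = sc$analysis_res,
                                     radius_m = config$covariates$radius_m,
                                     standardise = FALSE)
  species <- names(scen$true_coefficients)
  truth <- lapply(species, function(sp)
    true_suitability(land, scen, sp, stack = raw_stack))
  names(truth) <- species
  bias <- bias_surface(raw_stack$layers[[1]], strength = sc$bias_strength)
  occ <- generate_occurrences(scen,
                              lapply(truth, `[[`, "suitability"), bias)
  write_records(occ$records, file.path(out_dir, "records_raw.csv"))

  say("[3/9] filtering records")
  filt <- filter_records(occ$records,
                         year_min = config$filter$year_min,
                         year_max = config$filter$year_max,
                         max_uncertainty_m = config$filter$max_uncertainty_m)
  say("      %d -> %d records (removed %d year, %d uncertainty, %d undated, %d duplicate)",
      filt$audit$n_input, filt$audit$n_output, filt$audit$n_removed_year,
      filt$audit$n_removed_uncertainty, filt$audit$n_removed_undated,
      filt$audit$n_removed_duplicate)
  write_records(filt$records, file.path(out_dir, "records_filtered.csv"))

  say("[4/9] KDE background points (x%d)", config$background$multiplier)
  template <- raw_stack$layers[[1]]
  bg <- kde_background(filt$records, template,
                       multiplier = config$background$multiplier, seed = seed)

  say("[5/9] predictor stack + collinearity screen")
  frame_pts <- rbind(
    data.frame(x = filt$records$x, y = filt$records$y),
    data.frame(x = bg$x, y = bg$y))
  screen <- correlation_screen(raw_stack, frame_pts$x, frame_pts$y,
                               rho_threshold = config$covariates$rho_threshold)
  say("      retained: %s", paste(screen$retained, collapse = ", "))
  stack <- raw_stack
  stack$layers <- stack$layers[screen$retained]
  stack <- standardise_stack(stack)

  say("[6/9] per-species models + cross-validation")
  models <- list(); maps <- list(); cv_random <- list(); cv_spatial <- list()
  for (sp in species) {
    pres <- filt$records[filt$records$species == sp, , drop = FALSE]
    bgs <- bg[bg$species == sp, , drop = FALSE]
    frame <- assemble_model_frame(pres, bgs, stack)
    # predictors too sparse at the model points cannot support a smooth
    usable <- Filter(function(nm) length(unique(frame[[nm]])) >= 10,
                     names(stack$layers))
    if (length(usable) < length(stack$layers))
      say("      %s: dropping sparse predictor(s): %s", sp,
          paste(setdiff(names(stack$layers), usable), collapse = ", "))
    m <- fit_model(frame, predictors = usable, df_max = config$model$df_max,
                   spatial_rank = config$model$spatial_rank,
                   sweeps = config$model$sweeps, seed = seed,
                   constants = stack$constants, species = sp)
    fr <- make_folds(frame, "random", k = config$validation$k, seed = seed)
    fs <- make_folds(frame, "spatial_block", k = config$validation$k,
                     block_size_m = config$validation$block_size_m,
                     seed = seed)
    cv_random[[sp]] <- cross_validate(frame, fr, model = m)
    cv_spatial[[sp]] <- cross_validate(frame, fs, model = m)
    models[[sp]] <- m
    maps[[sp]] <- predict_map(m, stack)
    write_model(m, file.path(out_dir, sprintf("model_%s.json", sp)))
    write_raster(maps[[sp]], file.path(out_dir, sprintf("suitability_%s.asc", sp)))
    say("      %s: AUC %.2f (random) / %.2f (spatial); edf: %s", sp,
        cv_random[[sp]]$summary$mean[1], cv_spatial[[sp]]$summary$mean[1],
        paste(sprintf("%s %.1f", names(m$edf), m$edf), collapse = ", "))
  }

  say("[7/9] combined map, resistance, cores, circuit solve")
  comb <- combine_maps(maps)
  write_raster(comb$combined, file.path(out_dir, "suitability_combined.asc"))
  resist <- suitability_to_resistance(comb$combined,
                                      epsilon = config$connectivity$epsilon)
  write_raster(resist, file.path(out_dir, "resistance.asc"))
  cores <- delineate_core_areas(comb$combined,
                                tau = config$connectivity$tau,
                                min_cells = config$connectivity$min_cells,
                                link_dist_m = config$connectivity$link_dist_m,
                                neighbourhood = config$connectivity$neighbourhood)
  total_km2 <- sum(is.finite(comb$combined$values)) * comb$combined$res^2 / 1e6
  say("      %d core areas, %.2f km^2 (%.1f%% of the study area)",
      length(cores$groups), cores$area_km2, 100 * cores$area_km2 / total_km2)
  groups_used <- cores$groups
  if (length(groups_used) > config$connectivity$max_nodes) {
    keep <- order(lengths(groups_used), decreasing = TRUE)[
      seq_len(config$connectivity$max_nodes)]
    say("      (solving the %d largest of %d cores)",
        config$connectivity$max_nodes, length(groups_used))
    cores_used <- cores; cores_used$groups <- groups_used[sort(keep)]
  } else cores_used <- cores
  current <- cumulative_current(resist, cores_used,
                                neighbourhood = config$connectivity$neighbourhood)
  write_raster(current$current, file.path(out_dir, "current.asc"))
  utils::write.csv(current$effective_resistance,
                   file.path(out_dir, "effective_resistance.csv"),
                   row.names = FALSE)

  say("[8/9] pinch-point analysis (tau > %g)", config$connectivity$tau_critical)
  pinch <- pinch_point_analysis(resist, comb$combined,
                                tau_critical = config$connectivity$tau_critical,
                                percentile = config$pinch$percentile,
                                neighbourhood = config$connectivity$neighbourhood)
  say("      %d pinch clusters, %.3f km^2",
      nrow(pinch$clusters$clusters), sum(pinch$clusters$clusters$area_m2) / 1e6)
  write_raster(pinch$pinch_current, file.path(out_dir, "pinch_current.asc"))
  write_polygons(pinch_polygons(pinch$clusters, comb$combined),
                 file.path(out_dir, "pinch_clusters.geojson"),
                 properties = pinch$clusters$clusters)

  say("[9/9] planner corridors + gap analysis")
  planner <- generate_planner_corridors(land$landcover,
                                        source_class = config$planner$source_class,
                                        min_patch_ha = config$planner$min_patch_ha,
                                        buffer_m = config$planner$buffer_m)
  write_polygons(planner, file.path(out_dir, "planner_corridors.geojson"),
                 properties = attr(planner, "properties"))
  sp_mask <- top_fraction_mask(current$current,
                               fraction = config$comparison$top_fraction)
  partition <- gap_analysis(sp_mask, planner, comb$combined)
  indep_scen <- scen
  indep_scen$seed <- split_seed(seed, 901)
  indep_scen$contamination[] <- 0
  indep_scen$n_presence_per_species <-
    config$comparison$n_independent_per_species
  indep <- generate_occurrences(indep_scen,
                                lapply(truth, `[[`, "suitability"), bias)
  write_records(indep$records, file.path(out_dir, "records_independent.csv"))
  relprob <- relative_probability(partition, indep$records,
                                  n_background = config$comparison$n_background,
                                  seed = seed)
  centre <- c(template$xmin + grid_ncol(template) * template$res / 2,
              template$ymin + grid_nrow(template) * template$res / 2)
  descr <- corridor_descriptives(partition, land$landcover, centre)
  overlap <- pinch_overlap(pinch$clusters, planner, comb$combined)
  say("      overlap %.2f km^2; pinch clusters %d in / %d out of planner corridors",
      partition$areas_km2[["both"]], overlap$n_in, overlap$n_out)

  report <- list(
    seed = seed, config_fingerprint = config_fingerprint(config),
    filter_audit = unclass(filt$audit),
    contamination_ledger = as.list(occ$ledger$total),
    retained_predictors = screen$retained,
    cv = lapply(species, function(sp) list(
      species = sp,
      random = as.list(stats::setNames(cv_random[[sp]]$summary$mean,
                                       cv_random[[sp]]$summary$metric)),
      spatial = as.list(stats::setNames(cv_spatial[[sp]]$summary$mean,
                                        cv_spatial[[sp]]$summary$metric)))),
    combined_map_correlations = as.list(comb$correlations),
    core_area_km2 = cores$area_km2,
    core_area_fraction = cores$area_km2 / total_km2,
    n_core_areas = length(cores$groups),
    n_pinch_clusters = nrow(pinch$clusters$clusters),
    pinch_area_km2 = sum(pinch$clusters$clusters$area_m2) / 1e6,
    gap_areas_km2 = as.list(partition$areas_km2),
    relative_probability = stats::setNames(
      as.list(relprob$table$ratio), relprob$table$category),
    pinch_overlap = overlap[c("n_in", "n_out", "area_in_km2", "area_out_km2")]
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    config = config, scenario = scen, landscape = land, truth = truth,
    occurrences = occ, filtered = filt, background = bg, screen = screen,
    stack = stack, models = models, maps = maps, cv_random = cv_random,
    cv_spatial = cv_spatial, combined = comb, resistance = resist,
    cores = cores, current = current, pinch = pinch, planner = planner,
    species_mask = sp_mask, partition = partition, relprob = relprob,
    descriptives = descr, overlap = overlap, report = report))
}
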