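#!/usr/bin/env Rscript
# Stage 1 — synthesise the study system.
#
# Generates the demonstration landscape (10 m land cover, elevation,
# population density over 6.4 x 6.4 km), the known ground-truth suitability
# surface per species, an urban-biased observer-effort surface, and the
# contaminated occurrence records with their ledger. Everything downstream
# works from the files written here.

library(pollinet)

seed <- 1L
out <- "results/demo"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

scen <- synthetic_scenario(seed = seed)
land <- generate_landscape(scen)
write_raster(land$landcover, file.path(out, "landcover.asc"))
writeLines(land$landcover$levels, file.path(out, "landcover_classes.txt"))
write_raster(land$elevation, file.path(out, "elevation.asc"))
write_raster(land$population, file.path(out, "population.asc"))

raw <- build_predictor_stack(land, analysis_res = scen$analysis_res,
                             standardise = FALSE)
truth <- lapply(names(scen$true_coefficients), function(sp)
  true_suitability(land, scen, sp, stack = raw))
names(truth) <- names(scen$true_coefficients)
for (sp in names(truth))
  write_raster(truth[[sp]]$suitability,
               file.path(out, sprintf("true_suitability_%s.asc", sp)))

bias <- bias_surface(raw$layers[[1]], strength = scen$bias_strength)
write_raster(bias, file.path(out, "observer_bias.asc"))

occ <- generate_occurrences(scen, lapply(truth, `[[`, "suitability"), bias)
write_records(occ$records, file.path(out, "records_raw.csv"))
jsonlite::write_json(as.list(occ$ledger$total),
                     file.path(out, "contamination_ledger.json"),
                     auto_unbox = TRUE)

cat(sprintf("landscape %d x %d fine cells; %d raw records (%d clean + %d contaminated)\n",
            nrow(land$landcover$values), ncol(land$landcover$values),
            nrow(occ$records), occ$ledger$total[["n_clean"]],
            nrow(occ$records) - occ$ledger$total[["n_clean"]]))
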