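#!/usr/bin/env Rscript
# Stage 6 — resistance surface, core areas, circuit-theory current map.
#
# Resistance is the floored inverse of combined suitability; cores are
# groups of >= 2 adjacent cells with suitability >= 0.5 within 300 m of
# another group; cumulative current sums unit-injection solves over all
# unordered core pairs (largest 25 cores when there are more).

library(pollinet)

out <- "results/demo"
comb <- read_raster(file.path(out, "suitability_combined.asc"))

resist <- suitability_to_resistance(comb, epsilon = 1e-3)
write_raster(resist, file.path(out, "resistance.asc"))

cores <- delineate_core_areas(comb, tau = 0.5, min_cells = 2,
                              link_dist_m = 300)
total_km2 <- sum(is.finite(comb$values)) * comb$res^2 / 1e6
cat(sprintf("%d core areas, %.2f km^2 (%.1f%% of the study area)\n",
            length(cores$groups), cores$area_km2,
            100 * cores$area_km2 / total_km2))

if (length(cores$groups) > 25)
  cores$groups <- cores$groups[order(lengths(cores$groups),
                                     decreasing = TRUE)[1:25]]
current <- cumulative_current(resist, cores)
write_raster(current$current, file.path(out, "current.asc"))
write.csv(current$effective_resistance,
          file.path(out, "effective_resistance.csv"), row.names = FALSE)
reff <- current$effective_resistance
cat(sprintf("effective resistance over %d pairs: median %.2f, max %.2f\n",
            sum(is.finite(reff)) / 2,
            median(reff[upper.tri(reff)], na.rm = TRUE),
            max(reff[is.finite(reff)], na.rm = TRUE)))
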