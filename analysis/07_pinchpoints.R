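#!/usr/bin/env Rscript
# Stage 7 — least-cost corridors between critical cores and pinch points.
#
# Critical cores are suitability > 0.9 groups; corridors are bands of cells
# whose summed cost-weighted distance to a core pair is within the cutoff of
# the least-cost-path cost; pinch points are clusters of >= 2 neighbouring
# cells in the top 1% of corridor current, merged over all pairs.

library(pollinet)

out <- "results/demo"
comb <- read_raster(file.path(out, "suitability_combined.asc"))
resist <- suitability_to_resistance(comb, epsilon = 1e-3)

pa <- pinch_point_analysis(resist, comb, tau_critical = 0.9, percentile = 99)
cl <- pa$clusters$clusters
cat(sprintf("%d critical cores; %d pinch clusters covering %.3f km^2\n",
            length(pa$cores$groups), nrow(cl), sum(cl$area_m2) / 1e6))

write_raster(pa$pinch_current, file.path(out, "pinch_current.asc"))
write.csv(pa$pairs, file.path(out, "corridor_pairs.csv"), row.names = FALSE)
write_polygons(pinch_polygons(pa$clusters, comb),
               file.path(out, "pinch_clusters.geojson"), properties = cl)
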