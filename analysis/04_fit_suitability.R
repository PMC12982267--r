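#!/usr/bin/env Rscript
# Stage 4 — fit the per-species penalized additive models and map them.
#
# Binomial logit additive models: cubic-spline smooths capped at 4 effective
# df per predictor, a low-rank spatial smooth over (x, y), equal weighting of
# the presence and background classes, and double-penalty shrinkage for
# data-driven term removal. Per-species maps are summed and min-max
# normalised into the combined suitability surface.

library(pollinet)

seed <- 1L
out <- "results/demo"

constants <- read.csv(file.path(out, "standardisation_constants.csv"))
layers <- lapply(constants$layer, function(nm)
  read_raster(file.path(out, sprintf("predictor_%s.asc", nm))))
names(layers) <- constants$layer
stack <- structure(list(layers = layers, constants = constants,
                        radius_m = 100), class = "PredictorStack")

filt <- read_records(file.path(out, "records_filtered.csv"))
bg <- read.csv(file.path(out, "background.csv"))

maps <- list()
for (sp in unique(filt$species)) {
  frame <- assemble_model_frame(filt[filt$species == sp, ],
                                bg[bg$species == sp, ], stack)
  usable <- Filter(function(nm) length(unique(frame[[nm]])) >= 10,
                   names(stack$layers))
  m <- fit_model(frame, predictors = usable, seed = seed,
                 constants = constants, species = sp)
  print(m)
  write_model(m, file.path(out, sprintf("model_%s.json", sp)))
  maps[[sp]] <- predict_map(m, stack)
  write_raster(maps[[sp]], file.path(out, sprintf("suitability_%s.asc", sp)))
}

comb <- combine_maps(maps)
cat(sprintf("combined map correlations with species maps: %s\n",
            paste(sprintf("%s %.2f", names(comb$correlations),
                          comb$correlations), collapse = ", ")))
write_raster(comb$combined, file.path(out, "suitability_combined.asc"))
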