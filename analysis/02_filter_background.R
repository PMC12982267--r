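#!/usr/bin/env Rscript
# Stage 2 — clean the records and draw KDE-weighted background points.
#
# Applies the record rules (2015-2022 window, <= 100 m coordinate
# uncertainty, dated, de-duplicated), checks the audit against the
# generator's contamination ledger, and samples 10x background points per
# species weighted by a kernel density of that species' presences.

library(pollinet)

seed <- 1L
out <- "results/demo"

raw <- read_records(file.path(out, "records_raw.csv"))
filt <- filter_records(raw)
print(filt$audit)
write_records(filt$records, file.path(out, "records_filtered.csv"))
jsonlite::write_json(unclass(filt$audit), file.path(out, "filter_audit.json"),
                     auto_unbox = TRUE)

ledger <- jsonlite::read_json(file.path(out, "contamination_ledger.json"),
                              simplifyVector = TRUE)
stopifnot(filt$audit$n_removed_duplicate == ledger$duplicates,
          filt$audit$n_removed_uncertainty == ledger$uncertain,
          filt$audit$n_removed_undated == ledger$undated,
          filt$audit$n_removed_year == ledger$out_year)
cat("filter audit matches the contamination ledger exactly\n")

land <- read_raster(file.path(out, "landcover.asc"))
template <- raster_grid(matrix(0, nrow(land$values) %/% 10,
                               ncol(land$values) %/% 10),
                        land$xmin, land$ymin, res = land$res * 10)
bg <- kde_background(filt$records, template, multiplier = 10, seed = seed)
write.csv(bg, file.path(out, "background.csv"), row.names = FALSE)
cat(sprintf("%d background points (10x %d presences)\n",
            nrow(bg), nrow(filt$records)))
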