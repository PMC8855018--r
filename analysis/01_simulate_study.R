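#!/usr/bin/env Rscript
# Stage 1 -- simulate the study: a 1-km^2 agricultural landscape at 2-m
# resolution with 35 small semi-natural sites inside habitat patches, field
# polygons carrying herbicide treatment-frequency indices, and plant /
# butterfly / orthopteran communities with known embedded effects.
# Writes the raw inputs of the downstream stages under results/data/.

suppressPackageStartupMessages(library(patchlink))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = seed)
study <- generate_study(cfg)

write_asc(study$landscape$raster, file.path(out, "land_use.asc"))
utils::write.csv(study$landscape$sites, file.path(out, "sites.csv"),
                 row.names = FALSE)
write_fields_csv(study$landscape$fields, file.path(out, "fields.csv"))
utils::write.csv(study$covariates, file.path(out, "site_covariates.csv"),
                 row.names = FALSE)
for (tx in names(study$communities)) {
  write_community_csv(study$communities[[tx]]$records,
                      file.path(out, paste0("community_", tx, ".csv")))
  utils::write.csv(study$communities[[tx]]$traits,
                   file.path(out, paste0("traits_", tx, ".csv")),
                   row.names = FALSE)
}

message(sprintf(
  "simulated study (seed %d): %d sites, %d fields (%d with TFI), %d land-use cells",
  seed, nrow(study$landscape$sites), length(study$landscape$fields$tfi),
  sum(!is.na(study$landscape$fields$tfi)),
  length(study$landscape$raster$grid)))
for (tx in names(study$communities))
  message(sprintf("  %s: %d records over %d taxa", tx,
                  nrow(study$communities[[tx]]$records),
                  length(unique(study$communities[[tx]]$records$taxon))))
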