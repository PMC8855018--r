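#!/usr/bin/env Rscript
# Stage 4 -- explanatory variables: buffer-averaged herbicide TFI at 100 m
# and 300 m (missing where less than half of the surrounding land is
# documented), per-site connectivity (dPC of the containing patch), and the
# local variables (soil, floral availability, herbaceous cover classes).
# Writes the descriptive table of all candidates.

suppressPackageStartupMessages(library(patchlink))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- generate_study(synthetic_config(seed = seed))
covs <- study$covariates

num_vars <- c("tfi_100", "tfi_300", "dpc_flora_150", "dpc_flora_500",
              "dpc_insects_100", "dpc_insects_300", "floral", "cover_low",
              "cover_medium", "cover_high")
desc <- data.frame(
  variable = num_vars,
  mean = sapply(covs[num_vars], mean, na.rm = TRUE),
  sd = sapply(covs[num_vars], stats::sd, na.rm = TRUE),
  min = sapply(covs[num_vars], min, na.rm = TRUE),
  max = sapply(covs[num_vars], max, na.rm = TRUE),
  n = sapply(covs[num_vars], function(x) sum(!is.na(x))),
  row.names = NULL)
utils::write.csv(desc, file.path(out, "explanatory_descriptives.csv"),
                 row.names = FALSE)
utils::write.csv(covs, file.path(out, "site_covariates.csv"),
                 row.names = FALSE)

message(sprintf("TFI at 100 m: %.2f +/- %.2f (missing at %d/%d sites)",
                mean(covs$tfi_100, na.rm = TRUE),
                stats::sd(covs$tfi_100, na.rm = TRUE),
                sum(is.na(covs$tfi_100)), nrow(covs)))
message(sprintf("TFI at 300 m: %.2f +/- %.2f (missing at %d/%d sites)",
                mean(covs$tfi_300, na.rm = TRUE),
                stats::sd(covs$tfi_300, na.rm = TRUE),
                sum(is.na(covs$tfi_300)), nrow(covs)))
message(sprintf("site dPC (flora, 500 m): %.3g to %.3g",
                min(covs$dpc_flora_500), max(covs$dpc_flora_500)))
message("wrote results/explanatory_descriptives.csv")
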