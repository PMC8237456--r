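#!/usr/bin/env Rscript
# Stage 3: fit the regression catalog and check physical-vs-EQD2 concordance.
#
# A 20-member feature cohort (the study's cohort size) is generated from
# the synthetic reference catalog with link-scale noise, every model row of
# the specification table is refitted (multi-linear, S-type, inverse,
# cubic) and classified (high/moderate/poor at R^2 0.7/0.5), and the
# Spearman correlation between physical and EQD2 values of each parameter
# is tabulated with its band (high/moderate at r 0.8/0.6).

suppressPackageStartupMessages(library(hybridplan))
dir.create("results", showWarnings = FALSE)

rep <- suppressWarnings(run_pipeline(run_config(
  n_phantoms = 20, n_holdout = 0, cohort_source = "model",
  noise_sd = 0.05, seed = 42)))

write.csv(rep$fit_table, "results/model_fits.csv", row.names = FALSE)
write.csv(rep$spearman, "results/spearman_concordance.csv", row.names = FALSE)
write_catalog(rep$fitted_catalog, "results/fitted_catalog.json")

ft <- rep$fit_table
message(sprintf("fitted %d model rows: %d high, %d moderate, %d poor",
                nrow(ft), sum(ft$fit_class == "high"),
                sum(ft$fit_class == "moderate"), sum(ft$fit_class == "poor")))
d30 <- ft[ft$response == "heart_d30" & ft$domain == "physical", ]
message(sprintf("refitted physical heart-D30 R^2: %s (bundled equations carry 0.767 / 0.775)",
                paste(sprintf("%s %.3f", d30$regime, d30$r_squared),
                      collapse = ", ")))
sp <- rep$spearman
message(sprintf(
  "physical-vs-EQD2 Spearman: %d/%d parameter-regime pairs at least moderate (r >= 0.6)",
  sum(sp$corr_class != "below_moderate"), nrow(sp)))
message("wrote results/model_fits.csv, results/spearman_concordance.csv, results/fitted_catalog.json")
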