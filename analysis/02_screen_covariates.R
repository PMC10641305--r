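#!/usr/bin/env Rscript
# Stage 2: summarize the daily logger series into per-interval covariates
# (mean/max temperature; mean/max/min water level), standardize them, and
# screen for collinearity at |r| > 0.50 per stream.
#
# Outputs: results/covariates.csv, results/covariate_screen.json.

suppressMessages(library(cjsync))

ds <- load_dataset("scratch/analysis/data")
sc <- run_screen(ds$environment, ds$calendar)

write.csv(sc$table, "results/covariates.csv", row.names = FALSE)
jsonlite::write_json(
  lapply(sc$screen, function(s) list(retained = s$retained,
                                     dropped = s$dropped)),
  "results/covariate_screen.json", pretty = TRUE)

for (s in names(sc$screen)) {
  cat(sprintf("%s: retained [%s]; dropped [%s]\n", s,
              paste(sc$screen[[s]]$retained, collapse = ", "),
              paste(sc$screen[[s]]$dropped, collapse = ", ")))
  cat(sprintf("  r(mean_temp, max_temp) = %.2f\n",
              sc$screen[[s]]$correlations["mean_temp", "max_temp"]))
}
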