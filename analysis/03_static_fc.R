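#!/usr/bin/env Rscript
# Stage 3: stationary functional connectivity.
#
# Per-acquisition Pearson matrices are Fisher-transformed and every ROI
# pair is contrasted between thermal conditions with a linear mixed model
# (animal as random intercept), Benjamini-Hochberg corrected over the
# 45-edge family at FDR 0.05. Outputs: per-condition mean correlation
# matrices, per-edge result tables, significance and effect (delta-z)
# matrices per contrast.

suppressPackageStartupMessages(library(thermofc))

man <- read_manifest("results/cohort/manifest.csv")
out_dir <- "results/static"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

clean <- lapply(man$acquisition_id, function(id) {
  read_clean_series(file.path("results/clean", paste0(id, ".csv")))
})
names(clean) <- man$acquisition_id

for (cond in unique(man$condition)) {
  m <- condition_mean_matrix(clean, man, cond)
  write_matrix(m, file.path(out_dir, paste0("mean_correlation_", cond,
                                            ".csv")))
}

obs <- edge_observations(clean, man)
contrasts <- list(c("25C", "15C"), c("25C", "35C"), c("25C", "CFD"))
for (cp in contrasts) {
  cc <- compare_conditions(obs, cp, q = 0.05)
  tag <- paste(cp, collapse = "_vs_")
  write_table(cc$results, file.path(out_dir, paste0("edges_", tag, ".csv")))
  write_matrix(cc$significance * 1,
               file.path(out_dir, paste0("significance_", tag, ".csv")))
  write_matrix(cc$delta_z, file.path(out_dir, paste0("delta_z_", tag,
                                                     ".csv")))
  cat(sprintf("%s: %d of %d testable edges significant at FDR %.2f\n",
              tag, sum(cc$results$significant, na.rm = TRUE), cc$n_tested,
              cc$q))
}
cat("Static FC outputs written under", out_dir, "\n")
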