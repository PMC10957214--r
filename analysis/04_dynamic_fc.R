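#!/usr/bin/env Rscript
# Stage 4: dynamic functional connectivity and brain states.
#
# Cleaned series are z-scored per acquisition and expanded into per-frame
# cofluctuation vectors (55 values per frame), concatenated across the
# cohort, cleared of outlier frames (mean z-scored L1 distance > 3), and
# clustered with L1 k-means at K = 7 (best of many random restarts).
# Occurrence rates per acquisition feed mixed-model condition contrasts;
# the animal-by-state composition diagnostic guards against single-animal
# states.

suppressPackageStartupMessages(library(thermofc))

man <- read_manifest("results/cohort/manifest.csv")
out_dir <- "results/dynamic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20240115

clean <- lapply(man$acquisition_id, function(id) {
  read_clean_series(file.path("results/clean", paste0(id, ".csv")))
})
names(clean) <- man$acquisition_id
ok <- vapply(clean, function(cs) cs$status == "ok", logical(1))

series <- lapply(clean[ok], function(cs) {
  cofluctuation_series(zscore_series(cs), cs$source_id)
})
cofl <- concatenate_cohort(series)
cofl_kept <- filter_outliers(cofl, threshold = 3)
cat(sprintf("Cofluctuation frames: %d, outliers removed: %d (%.2f%%)\n",
            nrow(cofl$values), attr(cofl_kept, "outliers"),
            100 * attr(cofl_kept, "outliers") / nrow(cofl$values)))

model <- kmeans_l1(cofl_kept, k = 7, restarts = 20, seed = seed)
print(model)
for (s in seq_len(model$k)) {
  write_matrix(state_matrix(model, s),
               file.path(out_dir, sprintf("state_%02d_centroid.csv", s)))
}

occ <- occurrence_rates(model, cofl_kept$frames, man)
write_table(occ, file.path(out_dir, "occurrence_rates.csv"))

homo <- animal_state_homogeneity(model, cofl_kept$frames, man)
write_table(as.data.frame(homo$composition),
            file.path(out_dir, "animal_state_composition.csv"))
cat(sprintf("Animal/state homogeneity: chi-square %.1f on %d df\n",
            homo$chisq, homo$df))

stats <- compare_occurrence(occ, q = 0.05)
write_table(stats$omnibus, file.path(out_dir, "occurrence_omnibus.csv"))
if (!is.null(stats$pairwise)) {
  write_table(stats$pairwise, file.path(out_dir,
                                        "occurrence_pairwise.csv"))
  sig <- stats$pairwise[stats$pairwise$significant %in% TRUE, ]
  if (nrow(sig)) {
    cat("States with condition-dependent occurrence rates:\n")
    print(sig[, c("state", "condition_a", "condition_b", "estimate",
                  "p_adjusted")])
  } else {
    cat("No state shows a condition-dependent occurrence rate\n")
  }
} else {
  cat("No omnibus condition effect on any state's occurrence rate\n")
}
cat("Dynamic FC outputs written under", out_dir, "\n")
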