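#!/usr/bin/env Rscript
# Stage 2: scrub and condition every acquisition.
#
# Motion-artifact frames are flagged by robust z-thresholds on the tissue
# motion trace and the Doppler deviation, runs of at least 50 clean frames
# are concatenated, then the series is low-pass filtered (0.1 Hz,
# zero-phase), cubically detrended, z-scored and cleared of its leading
# global component. Cleaned series and a scrub report are written out.

suppressPackageStartupMessages(library(thermofc))

in_dir <- "results/cohort"
out_dir <- "results/clean"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

man <- read_manifest(file.path(in_dir, "manifest.csv"))
acqs <- lapply(seq_len(nrow(man)), function(r) {
  read_acquisition(man$path[r], man$acquisition_id[r], man$animal_id[r],
                   man$condition[r], man$fs_hz[r])
})
names(acqs) <- man$acquisition_id

pre <- preprocess_cohort(acqs, scrub_config())
for (cs in pre$clean) {
  write_clean_series(cs, file.path(out_dir, paste0(cs$source_id, ".csv")))
}
write_table(pre$report, file.path(out_dir, "scrub_report.csv"))

kept <- sum(pre$report$n_kept)
raw <- sum(pre$report$n_raw)
cat(sprintf("Scrubbing kept %d of %d frames (%.1f%%); %d of %d acquisitions retained\n",
            kept, raw, 100 * kept / raw,
            sum(pre$report$status == "ok"), nrow(pre$report)))
cat("Cleaned series written under", out_dir, "\n")
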