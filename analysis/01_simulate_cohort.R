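#!/usr/bin/env Rscript
# Simulate the study-condition cohort: 246-ROI parcellated BOLD-like scans
# (TR 0.72 s, 1200 timepoints) carrying a traveling ~24 s quasi-periodic
# pattern recurring every ~45 s, at SNR 1, with planted ground truth.
# Writes the series, parcellation and truth events under results/data/.

suppressPackageStartupMessages(library(spatiodyn))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synth_config()  # the package's standard study conditions
n_scans <- 5

for (s in seq_len(n_scans)) {
  ds <- generate_dataset(cfg, seed = s)
  write_roi_tsv(ds$series, file.path(out, sprintf("scan%02d.tsv", s)))
  write_events(ds$truth_events, file.path(out, sprintf("scan%02d_truth.txt", s)))
  if (s == 1) {
    write_parcellation(ds$parcellation, file.path(out, "parcellation.tsv"))
    write_roi_tsv(roi_ts(ds$template$waveform, tr = cfg$tr),
                  file.path(out, "planted_template.tsv"))
  }
  cat(sprintf("scan %d: %d planted events over %.0f s (mean interval %.1f s)\n",
              s, length(ds$truth_events),
              ncol(ds$series) * cfg$tr,
              mean(diff(ds$truth_events)) * cfg$tr))
}
cat("wrote", n_scans, "scans to", out, "\n")
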