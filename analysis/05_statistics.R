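#!/usr/bin/env Rscript
# Nonparametric comparison of sweep outcomes plus the dataset-accounting
# table for the published group delineations. Requires 03 and 04.

suppressPackageStartupMessages(library(spatiodyn))

out <- "results/statistics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## per-band recovery differences across replicates (from the band sweep)
band_tab <- read.delim("results/sweeps/band/sweep_table.tsv")
band_tab <- band_tab[!band_tab$skipped & band_tab$method == "qpp", ]
groups <- split(band_tab$recovery_corr, band_tab$level)
kw <- kruskal_wallis(groups)
cat(sprintf("Kruskal-Wallis on QPP recovery across bands: H = %.3f, p = %.3f\n",
            kw$statistic, kw$p_value))
res <- list(kruskal_wallis = c(statistic = kw$statistic, p = kw$p_value))
if (kw$p_value < 0.05 && length(groups) >= 3) {
  cat("post-hoc pairwise Dunn tests (Bonferroni-adjusted):\n")
  for (d in dunn_bonferroni(groups))
    cat(sprintf("  %s: z = %.2f, adj. p = %.3f\n", d$method, d$statistic,
                d$p_value))
}

## paired method comparison on the detection summary
det <- read.delim("results/patterns/detection_summary.tsv")
wsr <- wilcoxon_signed_rank(det$qpp_recovery, det$cpca_recovery)
cat(sprintf("Wilcoxon signed-rank, QPP vs cPCA recovery per scan: p = %.3f\n",
            wsr$p_value))

## published dataset delineations, recomputed
specs <- list(
  delineate_groups("HCP", 5, 4, 16, 1200, 0.72, total_scans = 80),
  delineate_groups("Videogamers", 6, 7, 28, 860, 0.535, total_scans = 168),
  delineate_groups("Musicians", 7, 6, 6, 937, 0.475, total_scans = 48, k_max = 7),
  delineate_groups("Meditators", 2, 7, 7, 213, 1.5, total_scans = 14, k_max = 2),
  delineate_groups("CABI Rest", 1, 20, 40, 146, 2.25, total_scans = 172, k_max = 1)
)
acct <- do.call(rbind, lapply(specs, function(s) data.frame(
  dataset = s$dataset_name, groups = s$n_groups,
  scans_per_group = s$scans_per_group, tr = s$tr,
  hours_per_group = s$scan_time_per_group_hours,
  total_timepoints = s$total_timepoints, total_hours = s$total_hours)))
write.table(acct, file.path(out, "dataset_accounting.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(acct, row.names = FALSE)
cat("wrote", out, "\n")
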