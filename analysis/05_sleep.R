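#!/usr/bin/env Rscript
# Sleep behavior: read the monitor file written by 01_simulate.R, trim the
# acclimation day, score 5-minute sleep bouts, compute daytime sleep and
# delta-sleep per genotype, and test the genotype x housing interaction
# (Type III ANOVA) that operationalizes "does the knockdown change the
# social effect on sleep".

suppressPackageStartupMessages(library(dopascape))

data_dir <- "results/data"
out_dir <- "results/sleep"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

traces <- read_monitor(file.path(data_dir, "monitor.tsv"),
                       file.path(data_dir, "monitor_meta.csv"),
                       lights_on_index = 1L, trim_minutes = 1440L)

per_fly <- data.frame(
  fly_id = vapply(traces, `[[`, character(1), "fly_id"),
  genotype = vapply(traces, `[[`, character(1), "genotype"),
  housing = vapply(traces, `[[`, character(1), "housing"),
  daytime_sleep = vapply(traces, daytime_sleep, numeric(1)))
write.table(per_fly, file.path(out_dir, "daytime_sleep.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Delta-sleep (GH daytime sleep minus SH) per genotype:\n")
ds_rows <- lapply(split(per_fly, per_fly$genotype), function(d) {
  ds <- delta_sleep(d$daytime_sleep[d$housing == "GH"],
                    d$daytime_sleep[d$housing == "SH"])
  cat(sprintf("  %-8s GH %5.1f +/- %4.1f  SH %5.1f +/- %4.1f  delta %6.1f min\n",
              d$genotype[1], ds$mean_gh, ds$sem_gh, ds$mean_sh, ds$sem_sh,
              ds$delta_sleep))
  data.frame(genotype = d$genotype[1], mean_gh = ds$mean_gh,
             sem_gh = ds$sem_gh, mean_sh = ds$mean_sh, sem_sh = ds$sem_sh,
             delta_sleep = ds$delta_sleep)
})
write.table(do.call(rbind, ds_rows), file.path(out_dir, "delta_sleep.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

av <- interaction_anova(per_fly$daytime_sleep,
                        per_fly[, c("genotype", "housing")])
cat("\nType III ANOVA on per-fly daytime sleep:\n")
print(as.data.frame(av), row.names = FALSE)
write.table(as.data.frame(av), file.path(out_dir, "sleep_anova.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
p_int <- av$p[av$term == "genotype:housing"]
cat(sprintf("\nGenotype x housing interaction p = %.2e: the RNAi genotype %s the social effect on daytime sleep\n",
            p_int, ifelse(p_int < 0.01, "significantly reduces",
                          "does not detectably change")))

# actogram-style export: mean sleep per 30-min bin for control flies
ctl <- vapply(traces, function(t) t$genotype == "control", logical(1))
gh_bins <- sleep_per_30min(traces[ctl & vapply(traces, function(t)
  t$housing == "GH", logical(1))])
sh_bins <- sleep_per_30min(traces[ctl & vapply(traces, function(t)
  t$housing == "SH", logical(1))])
write.table(data.frame(bin_start_zt = gh_bins$bin_start_zt,
                       gh_sleep = gh_bins$mean_sleep_min,
                       sh_sleep = sh_bins$mean_sleep_min),
            file.path(out_dir, "sleep_per_30min.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote sleep results to", out_dir, "\n")
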