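#!/usr/bin/env Rscript
# Cluster the z-scored GH-SH landscape: read the signal tables written by
# 01_simulate.R, keep the top 40% expressed genes, build the delta matrix,
# pick k by BIC (elbow reported alongside), cluster, and quantify cluster
# stability by maximum-overlap resampling.

suppressPackageStartupMessages(library(dopascape))

data_dir <- "results/data"
out_dir <- "results/landscape"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260111L

signals <- c("mRNA", "H3K4me3", "H3K27ac", "H3K9K14ac", "H3K36me3",
             "H3K9me3", "H3K27me3")
gh <- sh <- list()
for (s in signals) {
  gh[[s]] <- read_signal_table(file.path(data_dir, paste0(s, "_GH.tsv")),
                               s, "GH")
  sh[[s]] <- read_signal_table(file.path(data_dir, paste0(s, "_SH.tsv")),
                               s, "SH")
}

expr <- expression_table(gh$mRNA, sh$mRNA)
expressed <- select_expressed(expr, 0.4)
snr <- signal_to_noise_report(expr, 0.4)
cat(sprintf("Expressed-gene filter: kept %d of %d genes (top 40%% by TPM)\n",
            length(expressed), nrow(expr)))
cat(sprintf("  below-cutoff genes with signal-to-noise < 1: %.0f%%\n",
            100 * snr$share_snr_below_1))

delta <- make_delta(gh, sh, expressed)

kc_bic <- choose_k(delta, 2, 12, "bic", seed = seed)
kc_elbow <- choose_k(delta, 2, 12, "elbow", seed = seed)
cat(sprintf("Cluster number: BIC chose k=%d, elbow chose k=%d\n",
            kc_bic$k, kc_elbow$k))
write.table(kc_bic$curve, file.path(out_dir, "k_selection_curve.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

fit <- kmeans_fit(delta, kc_bic$k, seed = seed)
prof <- profile_clusters(delta, fit)
print(prof)
write.table(data.frame(gene = delta$genes, cluster = prof$labels),
            file.path(out_dir, "cluster_assignment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(cluster = seq_len(nrow(prof$means)),
                       n_genes = prof$sizes, prof$means),
            file.path(out_dir, "cluster_profiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# recovery against the generator truth
truth <- read.delim(file.path(data_dir, "landscape_truth.tsv"))
truth_lab <- truth$true_cluster[match(delta$genes, truth$gene)]
agree <- mean(vapply(split(seq_along(truth_lab), truth_lab), function(i)
  max(table(prof$labels[i])) / length(i), numeric(1)))
cat(sprintf("Planted-cluster purity of the recovered assignment: %.1f%%\n",
            100 * agree))

stab <- cluster_stability(delta, kc_bic$k, n_runs = 46, base_seed = seed,
                          restarts = 3)
print(stab)
jsonlite::write_json(
  list(n_runs = stab$n_runs, k = stab$k, pair_count = stab$pair_count,
       n_records = length(stab$overlap_records),
       median_overlap = stab$median_overlap,
       frac_above_99 = stab$frac_above_99),
  file.path(out_dir, "stability.json"), auto_unbox = TRUE, digits = NA)

long <- data.frame(gene = rep(delta$genes, times = length(delta$signals)),
                   signal = rep(delta$signals, each = length(delta$genes)),
                   z = as.vector(delta$z),
                   cluster = rep(prof$labels, times = length(delta$signals)))
write.table(long, file.path(out_dir, "delta_long.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote landscape results to", out_dir, "\n")
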