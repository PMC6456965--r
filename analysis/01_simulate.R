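#!/usr/bin/env Rscript
# Generate the synthetic study inputs with planted ground truth and write
# them in the interchange formats the rest of the workflow reads back:
# per-signal TSV quantification tables, promoter FASTA, MEME minimal motifs,
# and a beam-break monitor file with channel metadata.

suppressPackageStartupMessages(library(dopascape))

data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260101L

## Epigenetic landscape: 2500 genes, 8 planted clusters, 7 signals ----------
land_spec <- landscape_spec(n_genes = 2500, k = 8, separation = 5)
land <- gen_landscape(land_spec, seed = seed)
for (s in names(land$gh)) {
  write_signal_table(land$gh[[s]], file.path(data_dir, paste0(s, "_GH.tsv")))
  write_signal_table(land$sh[[s]], file.path(data_dir, paste0(s, "_SH.tsv")))
}
write.table(data.frame(gene = land$truth$genes,
                       true_cluster = land$truth$labels),
            file.path(data_dir, "landscape_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## Promoter panel: 300 genes with planted TF binding sites -------------------
m_spec <- motif_spec()
prom <- gen_promoters(m_spec, n_genes = 300, seed = seed + 1L)
fa <- file.path(data_dir, "promoters.fa")
writeLines(paste0(">", names(prom$sequences), "\n", prom$sequences), fa)
write_meme(prom$motifs, file.path(data_dir, "motifs.meme"))
write.table(data.frame(gene = names(prom$truth$log_fc),
                       log_fc = prom$truth$log_fc, prom$truth$counts),
            file.path(data_dir, "promoter_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## Behavior: 32 flies per genotype x housing cell, 2 days --------------------
b_spec <- behavior_spec(flies_per_group = 32)
act <- gen_activity(b_spec, seed = seed + 2L)
write_monitor(act$traces, file.path(data_dir, "monitor.tsv"),
              file.path(data_dir, "monitor_meta.csv"))

cat("Wrote synthetic inputs to", data_dir, "\n")
cat(sprintf("  landscape: %d genes in %d planted clusters\n",
            land_spec$n_genes, land_spec$k))
cat(sprintf("  promoters: %d genes x %d motifs; planted coefficients: %s\n",
            length(prom$sequences), length(prom$motifs),
            paste(sprintf("%s=%.2f", names(m_spec$beta), m_spec$beta),
                  collapse = " ")))
cat(sprintf("  behavior: %d traces; planted delta-sleep %.0f min (control), %.0f min (RNAi)\n",
            length(act$traces), planted_delta_sleep(b_spec, "control"),
            planted_delta_sleep(b_spec, "RNAi")))
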