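#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()], with
#' every stage's parameters at their documented defaults. Pass overrides as
#' a named list (nested lists merge shallowly per stage).
#'
#' @param overrides Named list of stage -> parameter overrides.
#' @return Config list.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    out_dir = "results/pipeline",
    simulate = list(enabled = TRUE, n_genes = 1000L, k = 8L, separation = 5,
                    n_promoter_genes = 300L, flies_per_group = 32L),
    inputs = list(signal_dir = NULL, promoter_fasta = NULL, meme = NULL,
                  monitor = NULL, monitor_meta = NULL),
    filter = list(expressed_fraction = 0.4, rank_by = "pooled",
                  pseudocount = 0.5),
    cluster = list(k_min = 2L, k_max = 12L, criterion = "bic", restarts = 5L),
    stability = list(n_runs = 46L, restarts = 3L),
    motifs = list(p_threshold = 1e-4, enrich_alpha = 1e-10,
                  min_pct_change = 33.3),
    regression = list(alpha = 0.05, alpha_marginal = 0.10,
                      drop_gate = "alpha"),
    sleep = list(min_bout = 5L)
  )
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(overrides[[nm]])) cfg[[nm]][[k]] <- overrides[[nm]][[k]]
    } else cfg[[nm]] <- overrides[[nm]]
  }
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [default_config()].
#' @return Config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  default_config(yaml::read_yaml(path))
}

#' @keywords internal
validate_config <- function(cfg) {
  if (!isTRUE(cfg$simulate$enabled)) {
    needed <- c(cfg$inputs$promoter_fasta, cfg$inputs$meme,
                cfg$inputs$monitor, cfg$inputs$monitor_meta)
    needed <- c(needed, if (!is.null(cfg$inputs$signal_dir))
      cfg$inputs$signal_dir)
    missing <- needed[!vapply(needed, function(p)
      is.null(p) || file.exists(p), logical(1))]
    if (length(missing) > 0) {
      stop("config error: missing input file(s): ",
           paste(missing, collapse = ", "))
    }
  }
  with(cfg$filter, {
    if (!(expressed_fraction > 0 && expressed_fraction <= 1)) {
      stop("config error: expressed_fraction must be in (0, 1]")
    }
  })
  if (!(cfg$motifs$p_threshold > 0 && cfg$motifs$p_threshold < 1)) {
    stop("config error: motif p_threshold must be in (0, 1)")
  }
  invisible(cfg)
}

#' @keywords internal
stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input generation or loading, expressed-gene
#' filtering, delta-matrix construction, k-selection and clustering,
#' stability resampling, motif counting, per-cluster enrichment, TF
#' filtering, stepwise motif-count regression, and sleep scoring with the
#' genotype x housing interaction ANOVA. Writes every artifact under
#' `cfg$out_dir` (assignment TSV, stability JSON, enrichment TSV,
#' regression TSV, sleep TSVs, long-format heat-map TSV) plus a
#' `provenance.json` recording package version, configuration and seeds.
#' Deterministic outputs are byte-reproducible for a fixed config. On a
#' stage error, a `FAILED` marker naming the stage is written and the error
#' is re-thrown.
#'
#' @param cfg Config list from [default_config()] or [read_config()].
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(cfg = default_config()) {
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  current_stage <- "setup"
  result <- tryCatch(
    run_pipeline_stages(cfg, function(s) current_stage <<- s),
    error = function(e) {
      writeLines(paste("stage:", current_stage, "-", conditionMessage(e)),
                 marker)
      stop("pipeline failed at stage '", current_stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
  prov <- list(package = "dopascape",
               version = as.character(utils::packageVersion("dopascape")),
               config = cfg)
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(result)
}

#' @keywords internal
run_pipeline_stages <- function(cfg, set_stage) {
  seed <- as.integer(cfg$seed)

  set_stage("simulate")
  if (isTRUE(cfg$simulate$enabled)) {
    stage_log("simulate", "generating synthetic inputs")
    land <- gen_landscape(
      landscape_spec(n_genes = cfg$simulate$n_genes, k = cfg$simulate$k,
                     separation = cfg$simulate$separation),
      seed = seed)
    prom <- gen_promoters(motif_spec(),
                          n_genes = cfg$simulate$n_promoter_genes,
                          seed = seed + 1L)
    act <- gen_activity(
      behavior_spec(flies_per_group = cfg$simulate$flies_per_group),
      seed = seed + 2L)
    gh <- land$gh; sh <- land$sh
    sequences <- prom$sequences; motifs <- prom$motifs
    traces <- act$traces
  } else {
    stage_log("simulate", "loading inputs from config paths")
    sig_files <- list.files(cfg$inputs$signal_dir, "\\.tsv$",
                            full.names = TRUE)
    gh <- list(); sh <- list()
    for (f in sig_files) {
      parts <- strsplit(sub("\\.tsv$", "", basename(f)), "_")[[1]]
      sm <- read_signal_table(f, parts[1], parts[2])
      if (parts[2] == "GH") gh[[parts[1]]] <- sm else sh[[parts[1]]] <- sm
    }
    seqs <- Biostrings::readDNAStringSet(cfg$inputs$promoter_fasta)
    sequences <- stats::setNames(as.character(seqs), names(seqs))
    motifs <- read_meme(cfg$inputs$meme)
    traces <- read_monitor(cfg$inputs$monitor, cfg$inputs$monitor_meta)
  }

  set_stage("filter")
  expr <- expression_table(gh$mRNA, sh$mRNA)
  expressed <- select_expressed(expr, cfg$filter$expressed_fraction,
                                cfg$filter$rank_by)
  snr <- signal_to_noise_report(expr, cfg$filter$expressed_fraction,
                                cfg$filter$rank_by)
  stage_log("filter", sprintf("%d of %d genes retained", length(expressed),
                              nrow(expr)))

  set_stage("delta")
  delta <- make_delta(gh, sh, expressed)

  set_stage("cluster")
  kc <- choose_k(delta, cfg$cluster$k_min, cfg$cluster$k_max,
                 cfg$cluster$criterion, seed = seed,
                 restarts = cfg$cluster$restarts)
  fit <- kmeans_fit(delta, kc$k, seed = seed, restarts = cfg$cluster$restarts)
  prof <- profile_clusters(delta, fit)
  stage_log("cluster", sprintf("k=%d chosen by %s", kc$k, kc$criterion))
  utils::write.table(
    data.frame(gene = delta$genes, cluster = prof$labels),
    file.path(cfg$out_dir, "cluster_assignment.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  long <- data.frame(gene = rep(delta$genes, times = length(delta$signals)),
                     signal = rep(delta$signals, each = length(delta$genes)),
                     z = as.vector(delta$z),
                     cluster = rep(prof$labels, times = length(delta$signals)))
  utils::write.table(long, file.path(cfg$out_dir, "delta_long.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  set_stage("stability")
  stab <- cluster_stability(delta, kc$k, n_runs = cfg$stability$n_runs,
                            base_seed = seed,
                            restarts = cfg$stability$restarts)
  stage_log("stability", sprintf("median overlap %.1f%%", stab$median_overlap))
  jsonlite::write_json(
    list(n_runs = stab$n_runs, k = stab$k, pair_count = stab$pair_count,
         n_records = length(stab$overlap_records),
         median_overlap = stab$median_overlap,
         frac_above_99 = stab$frac_above_99, seeds = stab$seeds,
         overlap_records = stab$overlap_records),
    file.path(cfg$out_dir, "stability.json"), digits = NA)

  set_stage("motifs")
  motif_genes <- names(sequences)
  counts <- count_motifs(sequences, motifs, genes = motif_genes,
                         p_threshold = cfg$motifs$p_threshold)

  set_stage("enrich")
  # response log fold change per promoter gene: planted when simulating
  # (promoters are decoupled from the landscape genes), else measured mRNA
  if (isTRUE(cfg$simulate$enabled)) {
    y <- prom$truth$log_fc[motif_genes]
  } else {
    i <- match(motif_genes, expr$gene)
    if (anyNA(i)) stop("promoter genes missing from the expression table")
    y <- stats::setNames(
      fold_changes(expr$tpm_gh[i], expr$tpm_sh[i], motif_genes,
                   cfg$filter$pseudocount)$log2fc, motif_genes)
  }
  if (all(motif_genes %in% delta$genes)) {
    # promoters cover clustered genes: per-cluster enrichment vs control
    labs <- prof$labels[match(motif_genes, delta$genes)]
    test_sets <- split(motif_genes, labs)
    test_sets <- test_sets[lengths(test_sets) <= length(motif_genes) / 2 &
                             lengths(test_sets) > 0]
  } else {
    # synthetic promoter panel: most-repressed third vs the rest, the set a
    # planted repressor motif should be enriched in
    n_test <- floor(length(motif_genes) / 3)
    test_sets <- list(repressed = motif_genes[order(y)][seq_len(n_test)])
  }
  rows <- lapply(names(test_sets), function(nm) {
    r <- enrich_cluster_motifs(test_sets[[nm]], motif_genes, counts,
                               seed = seed + match(nm, names(test_sets)),
                               alpha = cfg$motifs$enrich_alpha)
    cbind(set = nm, r)
  })
  enrich <- do.call(rbind, rows)
  utils::write.table(enrich, file.path(cfg$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  set_stage("regress")
  reg <- stepwise_fit(y, counts, gene_group = "promoter set",
                      alpha = cfg$regression$alpha,
                      alpha_marginal = cfg$regression$alpha_marginal,
                      drop_gate = cfg$regression$drop_gate)
  reg_tab <- data.frame(group = reg$gene_group, n = reg$n, r = reg$r,
                        f = reg$f_statistic, p = reg$f_p)
  utils::write.table(reg_tab, file.path(cfg$out_dir, "regression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(reg$terms, file.path(cfg$out_dir, "regression_terms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  set_stage("sleep")
  per_fly <- data.frame(
    fly_id = vapply(traces, `[[`, character(1), "fly_id"),
    genotype = vapply(traces, `[[`, character(1), "genotype"),
    housing = vapply(traces, `[[`, character(1), "housing"),
    daytime_sleep = vapply(traces, daytime_sleep, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  utils::write.table(per_fly, file.path(cfg$out_dir, "daytime_sleep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summaries <- lapply(split(per_fly, per_fly$genotype), function(d)
    delta_sleep(d$daytime_sleep[d$housing == "GH"],
                d$daytime_sleep[d$housing == "SH"]))
  anova_tab <- NULL
  if (length(unique(per_fly$genotype)) > 1) {
    anova_tab <- interaction_anova(per_fly$daytime_sleep,
                                   per_fly[, c("genotype", "housing")])
    utils::write.table(anova_tab, file.path(cfg$out_dir, "sleep_anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ds_tab <- data.frame(genotype = names(summaries),
                       delta_sleep = vapply(summaries, `[[`, numeric(1),
                                            "delta_sleep"))
  utils::write.table(ds_tab, file.path(cfg$out_dir, "delta_sleep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  list(expressed = expressed, snr = snr, delta = delta, k_choice = kc,
       assignment = fit, profile = prof, stability = stab, counts = counts,
       enrichment = enrich, regression = reg, per_fly_sleep = per_fly,
       sleep_summaries = summaries, sleep_anova = anova_tab)
}
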