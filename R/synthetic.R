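SIGNALS7 <- c("mRNA", "H3K4me3", "H3K27ac", "H3K9K14ac", "H3K36me3",
              "H3K9me3", "H3K27me3")

# 8 x 7 cluster-mean pattern: mRNA ramps upward across clusters (so the
# profile ordering is meaningful) and the six marks follow +/-1 sign patterns
# from a Hadamard design, giving every cluster pair a Euclidean separation of
# at least sqrt(3) pattern units.
#' @keywords internal
default_cluster_patterns <- function() {
  h2 <- matrix(c(1, 1, 1, -1), 2, 2)
  h8 <- kronecker(h2, kronecker(h2, h2))
  pat <- cbind(seq(-1.5, 1.5, length.out = 8), h8[, 2:7])
  dimnames(pat) <- list(paste0("cluster", 1:8), SIGNALS7)
  pat
}

#' Specification for a synthetic epigenetic landscape
#'
#' Defines the planted structure for [gen_landscape()]: genes fall into K
#' clusters; each cluster has a mean GH-SH difference vector over the seven
#' signals (six marks + mRNA); per-gene deltas scatter around the cluster
#' mean; per-condition replicate tables add measurement noise around
#' baseline +/- delta/2.
#'
#' @param n_genes Number of genes; default 5372 (a top-40% expressed set).
#' @param k True cluster count; default 8.
#' @param separation Scale applied to the cluster pattern matrix, in units of
#'   the within-cluster sd; default 5 (well-separated).
#' @param proportions Cluster mixing proportions; default equal.
#' @param within_sd Within-cluster sd of per-gene deltas; default 1.
#' @param replicates Replicates per condition; default 3.
#' @param replicate_noise_sd Replicate measurement noise sd; default 0.5.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline signal levels;
#'   defaults 5 and 1.
#' @param patterns Optional k x 7 cluster-mean pattern matrix (overrides the
#'   built-in 8 x 7 design; required when `k != 8`).
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(n_genes = 5372L, k = 8L, separation = 5,
                           proportions = rep(1 / k, k), within_sd = 1,
                           replicates = 3L, replicate_noise_sd = 0.5,
                           baseline_meanlog = 5, baseline_sdlog = 1,
                           patterns = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (is.null(patterns)) {
    if (k > 8) stop("supply a patterns matrix for k > 8")
    patterns <- default_cluster_patterns()[seq_len(k), , drop = FALSE]
  }
  if (nrow(patterns) != k || ncol(patterns) != length(SIGNALS7)) {
    stop("patterns must be k x 7")
  }
  structure(list(n_genes = as.integer(n_genes), k = as.integer(k),
                 separation = separation, proportions = proportions,
                 within_sd = within_sd, replicates = as.integer(replicates),
                 replicate_noise_sd = replicate_noise_sd,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 means = separation * patterns),
            class = "landscape_spec")
}

#' Generate a synthetic GH/SH signal landscape with planted clusters
#'
#' Draws a cluster label per gene, then per-signal GH-SH deltas around the
#' cluster mean, then splits each delta across two conditions around a
#' log-normal baseline (`GH = baseline + delta/2`, `SH = baseline - delta/2`)
#' with replicate noise. Values are truncated at zero (signals are
#' non-negative); baselines are large relative to the deltas so truncation
#' is rare. Pure function of (spec, seed).
#'
#' @param spec A [landscape_spec()].
#' @param seed Integer seed.
#' @return List with `gh`/`sh` (named lists of `signal_matrix`, one per
#'   signal), `truth` (list: labels, means, genes), `spec`.
#' @export
gen_landscape <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "landscape_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  G <- spec$n_genes
  genes <- sprintf("gene%05d", seq_len(G))
  labels <- sample.int(spec$k, G, replace = TRUE, prob = spec$proportions)
  delta <- spec$means[labels, , drop = FALSE] +
    matrix(stats::rnorm(G * length(SIGNALS7), 0, spec$within_sd),
           G, length(SIGNALS7))
  baseline <- matrix(stats::rlnorm(G * length(SIGNALS7),
                                   spec$baseline_meanlog, spec$baseline_sdlog),
                     G, length(SIGNALS7))
  gh <- list(); sh <- list()
  for (s in seq_along(SIGNALS7)) {
    mk <- function(center) {
      reps <- matrix(stats::rnorm(G * spec$replicates, 0,
                                  spec$replicate_noise_sd),
                     G, spec$replicates) + center
      pmax(reps, 0)
    }
    gh[[SIGNALS7[s]]] <- signal_matrix(SIGNALS7[s], "GH", genes,
                                       mk(baseline[, s] + delta[, s] / 2))
    sh[[SIGNALS7[s]]] <- signal_matrix(SIGNALS7[s], "SH", genes,
                                       mk(baseline[, s] - delta[, s] / 2))
  }
  list(gh = gh, sh = sh,
       truth = list(labels = labels, means = spec$means, genes = genes,
                    delta = delta),
       spec = spec)
}

#' Specification for synthetic promoters with planted motif sites
#'
#' Defines motifs (non-palindromic consensus strings with a degeneracy level
#' for the scanning PWM), a planted regression coefficient per motif linking
#' site counts to log fold change, and the promoter geometry.
#'
#' @param consensus Named character vector: TF gene -> consensus site
#'   (length >= 8 so consensus hits clear a 1e-4 scan threshold).
#' @param beta Planted coefficients, same order as `consensus`.
#' @param promoter_length Odd window length; default 1001 (TSS-centered).
#' @param degeneracy Probability mass on the consensus base at each PWM
#'   position; default 0.97.
#' @param background Background base probabilities; default uniform.
#' @param count_size,count_prob Per-gene planted site counts are
#'   Binomial(count_size, count_prob); defaults 6 and 0.25 (range 0-6).
#' @param noise_sd Residual sd of the planted log fold change; default 0.5.
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(consensus = c(Hr38 = "AGGTCACT", cbt = "GTACCCTT",
                                     CrebA = "TGACGTCA", sr = "ACGCCCAC",
                                     pho = "GCCATTTC"),
                       beta = c(Hr38 = -0.3, cbt = -0.25, CrebA = -0.2,
                                sr = 0.2, pho = 0),
                       promoter_length = 1001L, degeneracy = 0.97,
                       background = rep(0.25, 4),
                       count_size = 6L, count_prob = 0.25,
                       noise_sd = 0.5) {
  if (promoter_length %% 2 != 1) stop("promoter_length must be odd")
  if (!identical(names(consensus), names(beta))) {
    stop("consensus and beta must share names")
  }
  if (any(!is.finite(beta))) stop("beta must be finite")
  structure(list(consensus = consensus, beta = beta,
                 promoter_length = as.integer(promoter_length),
                 degeneracy = degeneracy, background = background,
                 count_size = as.integer(count_size),
                 count_prob = count_prob, noise_sd = noise_sd),
            class = "motif_spec")
}

#' @keywords internal
consensus_to_pwm <- function(consensus, degeneracy) {
  chars <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - degeneracy) / 3, length(chars), 4,
              dimnames = list(NULL, DNA_BASES))
  m[cbind(seq_along(chars), match(chars, DNA_BASES))] <- degeneracy
  m
}

#' Generate synthetic promoter sequences with planted motif sites
#'
#' For each gene, draws a planted site count per motif, plants that many
#' exact consensus copies at non-overlapping random positions (random strand)
#' in a background sequence, and derives the gene's log fold change from the
#' planted linear model `log_fc = counts %*% beta + noise`. Background
#' sequence can add chance sites, so scanned counts are >= planted counts.
#' Pure function of (spec, n_genes, seed).
#'
#' @param spec A [motif_spec()].
#' @param n_genes Number of promoters.
#' @param seed Integer seed.
#' @return List with `sequences` (named character), `motifs` (list of
#'   `motif_model`), `truth` (list: counts matrix, beta, log_fc), `spec`.
#' @export
gen_promoters <- function(spec, n_genes = 300L, seed = 1L) {
  stopifnot(inherits(spec, "motif_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  genes <- sprintf("pgene%05d", seq_len(n_genes))
  n_motifs <- length(spec$consensus)
  counts <- matrix(stats::rbinom(n_genes * n_motifs, spec$count_size,
                                 spec$count_prob),
                   n_genes, n_motifs,
                   dimnames = list(genes, names(spec$consensus)))
  log_fc <- as.numeric(counts %*% spec$beta) +
    stats::rnorm(n_genes, 0, spec$noise_sd)
  names(log_fc) <- genes
  plen <- spec$promoter_length
  seqs <- character(n_genes)
  for (g in seq_len(n_genes)) {
    s <- sample(DNA_BASES, plen, replace = TRUE, prob = spec$background)
    placed <- matrix(numeric(0), 0, 2)  # start, end (inclusive)
    for (m in seq_len(n_motifs)) {
      site <- strsplit(spec$consensus[m], "")[[1]]
      L <- length(site)
      for (cnt in seq_len(counts[g, m])) {
        for (try in 1:200) {
          pos <- sample.int(plen - L + 1L, 1)
          if (nrow(placed) == 0 ||
              all(pos + L - 1 < placed[, 1] | pos > placed[, 2])) break
        }
        placed <- rbind(placed, c(pos, pos + L - 1))
        if (stats::runif(1) < 0.5) {
          s[pos:(pos + L - 1)] <- site
        } else {
          s[pos:(pos + L - 1)] <- revcomp_chars(site)
        }
      }
    }
    seqs[g] <- paste(s, collapse = "")
  }
  names(seqs) <- genes
  motifs <- lapply(names(spec$consensus), function(tf) {
    motif_model(paste0("M_", tf),
                consensus_to_pwm(spec$consensus[[tf]], spec$degeneracy),
                tf_gene = tf, background = spec$background)
  })
  names(motifs) <- vapply(motifs, function(m) m$motif_id, character(1))
  list(sequences = seqs, motifs = motifs,
       truth = list(counts = counts, beta = spec$beta, log_fc = log_fc),
       spec = spec)
}

#' Specification for synthetic fly activity traces
#'
#' Per-minute two-state Markov model: an awake fly falls asleep with
#' probability `p_sleep`, an asleep fly wakes with probability `p_wake`
#' (separate day and night rates), and awake minutes emit
#' Poisson(`lambda_awake`) beam-break counts (asleep minutes emit 0).
#' Group housing raises the daytime sleep propensity; an RNAi genotype
#' shrinks the GH-SH gap in `p_sleep_day` by `knockdown_effect`.
#'
#' @param flies_per_group Flies per genotype x housing cell; default 32.
#' @param days Whole days simulated (the first serves as acclimation);
#'   default 2.
#' @param lambda_awake Mean awake activity counts/min (> 0); default 2.
#' @param gh_p_sleep_day,sh_p_sleep_day Daytime fall-asleep rates; defaults
#'   0.05 and 0.022.
#' @param gh_p_wake_day,sh_p_wake_day Daytime wake rates; defaults 0.07 and
#'   0.105.
#' @param p_sleep_night,p_wake_night Night rates (shared); defaults 0.12 and
#'   0.025.
#' @param knockdown_effect Fraction of the GH-SH `p_sleep_day` gap removed in
#'   the RNAi genotype; default 0.6.
#' @return A `behavior_spec` list.
#' @export
behavior_spec <- function(flies_per_group = 32L, days = 2L, lambda_awake = 2,
                          gh_p_sleep_day = 0.05, sh_p_sleep_day = 0.022,
                          gh_p_wake_day = 0.07, sh_p_wake_day = 0.105,
                          p_sleep_night = 0.12, p_wake_night = 0.025,
                          knockdown_effect = 0.6) {
  probs <- c(gh_p_sleep_day, sh_p_sleep_day, gh_p_wake_day, sh_p_wake_day,
             p_sleep_night, p_wake_night, knockdown_effect)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (lambda_awake <= 0) stop("lambda_awake must be > 0")
  structure(list(flies_per_group = as.integer(flies_per_group),
                 days = as.integer(days), lambda_awake = lambda_awake,
                 gh_p_sleep_day = gh_p_sleep_day,
                 sh_p_sleep_day = sh_p_sleep_day,
                 gh_p_wake_day = gh_p_wake_day,
                 sh_p_wake_day = sh_p_wake_day,
                 p_sleep_night = p_sleep_night, p_wake_night = p_wake_night,
                 knockdown_effect = knockdown_effect),
            class = "behavior_spec")
}

# Day transition rates for one (genotype, housing) cell.
#' @keywords internal
cell_rates <- function(spec, genotype, housing) {
  gap_keep <- if (genotype == "control") 1 else 1 - spec$knockdown_effect
  if (housing == "GH") {
    list(p_sleep_day = spec$sh_p_sleep_day +
           gap_keep * (spec$gh_p_sleep_day - spec$sh_p_sleep_day),
         p_wake_day = spec$sh_p_wake_day +
           gap_keep * (spec$gh_p_wake_day - spec$sh_p_wake_day))
  } else {
    list(p_sleep_day = spec$sh_p_sleep_day, p_wake_day = spec$sh_p_wake_day)
  }
}

#' Expected scored daytime sleep under the trace model
#'
#' Closed-form approximation used as planted truth: at stationarity the
#' asleep fraction is `p_sleep / (p_sleep + p_wake)`; with geometric bout
#' lengths (mean `1/p_wake`), the fraction of asleep minutes lying in bouts
#' of length >= 5 is `q^4 (5 p_wake + q)` with `q = 1 - p_wake`. Boundary
#' effects at the light transitions are ignored.
#'
#' @param p_sleep,p_wake Daytime transition probabilities.
#' @return Expected scored daytime sleep in minutes (of 720).
#' @export
expected_daytime_sleep <- function(p_sleep, p_wake) {
  pi_s <- p_sleep / (p_sleep + p_wake)
  q <- 1 - p_wake
  720 * pi_s * q^4 * (5 * p_wake + q)
}

#' Planted delta-sleep for a genotype
#'
#' @param spec A [behavior_spec()].
#' @param genotype `"control"` or `"RNAi"`.
#' @return Expected GH - SH daytime sleep difference in minutes.
#' @export
planted_delta_sleep <- function(spec, genotype = "control") {
  gh <- cell_rates(spec, genotype, "GH")
  sh <- cell_rates(spec, genotype, "SH")
  expected_daytime_sleep(gh$p_sleep_day, gh$p_wake_day) -
    expected_daytime_sleep(sh$p_sleep_day, sh$p_wake_day)
}

#' Generate synthetic activity traces
#'
#' Simulates the two-state sleep/wake Markov chain per minute for every fly
#' in a genotypes x housing design, starting each fly from the stationary
#' day distribution of its cell. Days start at lights-on (ZT0); minutes with
#' ZT < 720 use day rates. Pure function of (spec, seed).
#'
#' @param spec A [behavior_spec()].
#' @param seed Integer seed.
#' @param genotypes Genotype labels to simulate; default
#'   `c("control", "RNAi")`.
#' @return List with `traces` (list of `activity_trace`), `design`
#'   (data.frame fly_id, genotype, housing) and `truth` (per-cell expected
#'   daytime sleep and per-genotype planted delta-sleep).
#' @export
gen_activity <- function(spec, seed = 1L, genotypes = c("control", "RNAi")) {
  stopifnot(inherits(spec, "behavior_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  total <- spec$days * 1440L
  zt <- (seq_len(total) - 1L) %% 1440L
  is_day <- zt < 720L
  traces <- list(); design <- list(); expected <- list()
  for (gt in genotypes) for (hs in c("GH", "SH")) {
    rates <- cell_rates(spec, gt, hs)
    n <- spec$flies_per_group
    p_s <- ifelse(is_day, rates$p_sleep_day, spec$p_sleep_night)
    p_w <- ifelse(is_day, rates$p_wake_day, spec$p_wake_night)
    pi0 <- rates$p_sleep_day / (rates$p_sleep_day + rates$p_wake_day)
    asleep <- stats::runif(n) < pi0
    states <- matrix(FALSE, n, total)
    for (m in seq_len(total)) {
      u <- stats::runif(n)
      asleep <- ifelse(asleep, u >= p_w[m], u < p_s[m])
      states[, m] <- asleep
    }
    counts <- matrix(stats::rpois(n * total, spec$lambda_awake), n, total)
    counts[states] <- 0L
    for (f in seq_len(n)) {
      id <- sprintf("%s_%s_%02d", gt, hs, f)
      # lights_on_index points at the final day: earlier days are the
      # acclimation period and also let the chain forget its start state
      traces[[id]] <- activity_trace(id, gt, hs, counts[f, ],
                                     lights_on_index = total - 1440L + 1L)
      design[[id]] <- data.frame(fly_id = id, genotype = gt, housing = hs,
                                 stringsAsFactors = FALSE)
    }
    expected[[paste(gt, hs, sep = "_")]] <-
      expected_daytime_sleep(rates$p_sleep_day, rates$p_wake_day)
  }
  list(traces = traces,
       design = do.call(rbind, c(design, list(make.row.names = FALSE))),
       truth = list(expected_daytime = unlist(expected),
                    planted_delta = stats::setNames(
                      vapply(genotypes, function(g)
                        planted_delta_sleep(spec, g), numeric(1)),
                      genotypes)))
}

#' Write activity traces as a monitor file plus metadata
#'
#' Serializes traces in the channel-per-column monitor format read by
#' [read_monitor()] (all traces must share one length).
#'
#' @param traces List of `activity_trace`.
#' @param monitor_path,metadata_path Output paths.
#' @export
write_monitor <- function(traces, monitor_path, metadata_path) {
  lens <- vapply(traces, function(t) length(t$counts), integer(1))
  if (length(unique(lens)) != 1) stop("traces must share one length")
  total <- lens[1]
  mat <- vapply(traces, function(t) t$counts, integer(total))
  minutes <- seq_len(total)
  df <- data.frame(idx = minutes,
                   date = "01 Jan 26",
                   time = sprintf("%02d:%02d:00", ((minutes - 1) %/% 60) %% 24,
                                  (minutes - 1) %% 60),
                   status = 1L, mat, check.names = FALSE)
  utils::write.table(df, monitor_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- data.frame(channel = seq_along(traces),
                     fly_id = vapply(traces, `[[`, character(1), "fly_id"),
                     genotype = vapply(traces, `[[`, character(1), "genotype"),
                     housing = vapply(traces, `[[`, character(1), "housing"))
  utils::write.csv(meta, metadata_path, row.names = FALSE, quote = FALSE)
  invisible(monitor_path)
}
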