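DNA_BASES <- c("A", "C", "G", "T")

#' Construct a motif model
#'
#' A position probability matrix with a background model, regularized by a
#' pseudocount so log-odds scores stay finite.
#'
#' @param motif_id Motif identifier.
#' @param matrix L x 4 matrix of per-position probabilities over A,C,G,T
#'   (rows sum to 1).
#' @param tf_gene Gene id of the TF the motif belongs to (`NA` if unmapped).
#' @param background Length-4 background probabilities; default uniform.
#' @param pseudocount Added (scaled by background) to each cell before
#'   renormalization; default 0.01.
#' @return A `motif_model`.
#' @export
motif_model <- function(motif_id, matrix, tf_gene = NA_character_,
                        background = rep(0.25, 4), pseudocount = 0.01) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) stop("motif matrix must have 4 columns (A,C,G,T)")
  if (nrow(matrix) < 4) stop("motif length must be >= 4")
  if (any(matrix < 0)) stop("negative motif probability")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 probabilities summing to 1")
  }
  raw <- matrix / rowSums(matrix)
  if (any(abs(rowSums(raw) - 1) > 1e-6)) stop("motif rows do not sum to 1")
  # regularized copy used for scoring (keeps log-odds finite)
  m <- sweep(raw, 2, pseudocount * background, "+")
  m <- m / rowSums(m)
  colnames(m) <- DNA_BASES
  colnames(raw) <- DNA_BASES
  structure(list(motif_id = motif_id, tf_gene = tf_gene, matrix = m,
                 matrix_raw = raw, background = background,
                 pseudocount = pseudocount, length = nrow(m)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s (TF %s), length %d\n",
              x$motif_id, x$tf_gene, x$length))
  invisible(x)
}

#' Read motifs from a MEME minimal-format file
#'
#' Parses `MEME version`, optional `ALPHABET`/`Background letter frequencies`
#' lines and `MOTIF` blocks with `letter-probability matrix` sections, the
#' interchange format used by motif databases and scanning tools.
#'
#' @param path Path to a MEME minimal text file.
#' @param tf_map Optional named character vector mapping motif id -> TF gene.
#' @param pseudocount Passed to [motif_model()].
#' @return List of `motif_model` objects, named by motif id.
#' @export
read_meme <- function(path, tf_map = NULL, pseudocount = 0.01) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME minimal file (missing 'MEME version'): ", path)
  }
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1 && bg_at < length(lines)) {
    toks <- strsplit(trimws(lines[bg_at + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[seq(2, length(toks), 2)]))
    keys <- toks[seq(1, length(toks), 2)]
    if (!anyNA(vals) && setequal(keys, DNA_BASES)) {
      background <- vals[match(DNA_BASES, keys)]
      background <- background / sum(background)
    }
  }
  motif_at <- grep("^MOTIF\\b", lines)
  motifs <- list()
  for (start in motif_at) {
    header <- strsplit(trimws(lines[start]), "\\s+")[[1]]
    id <- header[2]
    alt <- if (length(header) >= 3) header[3] else NA_character_
    lp <- grep("^letter-probability matrix", lines[start:length(lines)])[1]
    if (is.na(lp)) stop("motif ", id, " has no letter-probability matrix")
    lp <- start + lp - 1
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[lp])
    w <- suppressWarnings(as.integer(w))
    rows <- list()
    i <- lp + 1
    while (i <= length(lines)) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      num <- suppressWarnings(as.numeric(tok))
      if (length(num) != 4 || anyNA(num)) break
      rows[[length(rows) + 1]] <- num
      i <- i + 1
    }
    m <- do.call(rbind, rows)
    if (!is.na(w) && nrow(m) != w) {
      stop("motif ", id, ": matrix has ", nrow(m), " rows but w=", w)
    }
    tf <- if (!is.null(tf_map) && id %in% names(tf_map)) tf_map[[id]]
          else if (!is.na(alt)) alt else NA_character_
    motifs[[id]] <- motif_model(id, m, tf_gene = tf, background = background,
                                pseudocount = pseudocount)
  }
  if (length(motifs) == 0) stop("no MOTIF blocks found in ", path)
  motifs
}

#' Write motifs to a MEME minimal-format file
#'
#' @param motifs List of `motif_model` objects.
#' @param path Output path.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies"), con)
  bg <- motifs[[1]]$background
  writeLines(sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
             con)
  for (m in motifs) {
    writeLines(c("", sprintf("MOTIF %s %s", m$motif_id,
                             ifelse(is.na(m$tf_gene), m$motif_id, m$tf_gene)),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         m$length)), con)
    for (i in seq_len(m$length)) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", m$matrix_raw[i, 1],
                         m$matrix_raw[i, 2], m$matrix_raw[i, 3],
                         m$matrix_raw[i, 4]), con)
    }
  }
  invisible(path)
}

#' Per-position log-odds score matrix (log2 motif/background)
#' @keywords internal
logodds_matrix <- function(motif) {
  log2(sweep(motif$matrix, 2, motif$background, "/"))
}

#' Exact null distribution of the PWM log-odds score
#'
#' Distribution of the log2-odds score of a random L-mer drawn from the
#' background model, computed by dynamic programming over motif columns with
#' score discretization on a fixed grid. With granularity g, every score is
#' represented within L*g/2 of its exact value.
#'
#' @param motif A `motif_model`.
#' @param granularity Score-grid step in bits; default 1e-3.
#' @param collision_tol Maximal within-column score difference allowed to
#'   share a grid cell; scores closer than the grid but farther apart than
#'   this tolerance trigger an error suggesting finer bins. Default
#'   `granularity`.
#' @return List with `score` (ascending grid scores), `prob` (point masses
#'   summing to 1), `tail_p` (P(score >= score[i])), `granularity`.
#' @export
pwm_score_distribution <- function(motif, granularity = 1e-3,
                                   collision_tol = granularity) {
  lo <- logodds_matrix(motif)
  q <- round(lo / granularity)  # integer grid per cell
  for (i in seq_len(nrow(lo))) {
    s <- sort(lo[i, ])
    d <- diff(s)
    collide <- d > collision_tol & diff(round(s / granularity)) == 0
    if (any(collide)) {
      stop("score discretization too coarse (collisions in column ", i,
           "); use a finer granularity")
    }
  }
  offset <- sum(apply(q, 1, min))
  width <- sum(apply(q, 1, max)) - offset + 1
  prob <- numeric(width); prob[1] <- 1  # P over (sum - running_min_offset)
  run_min <- 0
  for (i in seq_len(nrow(q))) {
    row_min <- min(q[i, ])
    nxt <- numeric(width)
    for (b in 1:4) {
      shift <- q[i, b] - row_min
      if (motif$background[b] == 0) next
      idx <- seq_len(width - shift)
      nxt[idx + shift] <- nxt[idx + shift] + prob[idx] * motif$background[b]
    }
    prob <- nxt
    run_min <- run_min + row_min
  }
  score <- (seq_len(width) - 1 + offset) * granularity
  keep <- prob > 0
  score <- score[keep]; prob <- prob[keep]
  tail_p <- rev(cumsum(rev(prob)))
  list(score = score, prob = prob, tail_p = tail_p, granularity = granularity)
}

#' Score threshold for a target p-value
#'
#' The smallest grid score whose exact null tail probability is <= p, i.e.
#' the threshold realizing the largest attainable p-value not exceeding the
#' target. Returns `Inf` (no hit possible) when even the maximum score has
#' tail probability > p... which cannot happen for p >= min tail; returns the
#' threshold and its achieved p.
#'
#' @param dist Result of [pwm_score_distribution()].
#' @param p_threshold Target p-value in (0, 1).
#' @return List with `threshold` (score) and `p_achieved`.
#' @export
pwm_score_threshold <- function(dist, p_threshold) {
  if (!(p_threshold > 0 && p_threshold < 1)) stop("p_threshold must be in (0,1)")
  ok <- which(dist$tail_p <= p_threshold)
  if (length(ok) == 0) {
    # even the top score is too frequent: no position can qualify
    return(list(threshold = Inf, p_achieved = 0))
  }
  i <- ok[1]
  list(threshold = dist$score[i], p_achieved = dist$tail_p[i])
}

#' @keywords internal
revcomp_chars <- function(chars) {
  rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars])
}

# Score every window start on one strand; returns numeric vector (NA where
# the window contains N).
#' @keywords internal
scan_strand <- function(idx, lo, granularity) {
  L <- nrow(lo)
  n <- length(idx) - L + 1
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  bad <- logical(n)
  for (j in seq_len(L)) {
    b <- idx[j:(j + n - 1)]
    nb <- is.na(b)
    bad <- bad | nb
    b[nb] <- 1L
    # snap per-cell scores to the DP grid so thresholds compare exactly
    sc <- sc + round(lo[j, b] / granularity) * granularity
  }
  sc[bad] <- NA_real_
  sc
}

#' Scan a sequence with a PWM at an exact p-value threshold
#'
#' Slides the motif over both strands of `sequence`, scoring each window by
#' the summed log2-odds against the background. Windows containing N are
#' skipped. A window is a hit when its score reaches the threshold whose
#' exact null p-value (from [pwm_score_distribution()]) is the largest
#' p <= `p_threshold`.
#'
#' @param sequence Character string over A,C,G,T,N.
#' @param motif A `motif_model`.
#' @param p_threshold Per-position p-value threshold; default 1e-4 (the
#'   scanning default of common PWM match tools).
#' @param dist Optional precomputed score distribution (reused across calls).
#' @return Data.frame with `start` (1-based, on the forward strand), `strand`
#'   (`"+"`/`"-"`), `score`, `p` (exact tail p of the score).
#' @export
pwm_scan <- function(sequence, motif, p_threshold = 1e-4, dist = NULL) {
  if (is.null(dist)) dist <- pwm_score_distribution(motif)
  thr <- pwm_score_threshold(dist, p_threshold)
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  L <- motif$length
  if (length(chars) < L) {
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0), p = numeric(0)))
  }
  lo <- logodds_matrix(motif)
  idx_f <- match(chars, DNA_BASES)                 # NA for N / other
  idx_r <- match(revcomp_chars(chars), DNA_BASES)
  sc_f <- scan_strand(idx_f, lo, dist$granularity)
  sc_r <- scan_strand(idx_r, lo, dist$granularity)
  n <- length(sc_f)
  tail_at <- function(s) {
    i <- findInterval(s + dist$granularity / 2, dist$score)
    ifelse(i >= 1, dist$tail_p[pmin(i, length(dist$tail_p))], 1)
  }
  eps <- dist$granularity / 2
  hit_f <- which(!is.na(sc_f) & sc_f >= thr$threshold - eps)
  # reverse-strand window starting (in reversed coords) at position r covers
  # forward positions (n - r + 1) .. (n - r + L); report its forward start
  hit_r <- which(!is.na(sc_r) & sc_r >= thr$threshold - eps)
  out <- rbind(
    if (length(hit_f)) data.frame(start = hit_f, strand = "+",
                                  score = sc_f[hit_f], p = tail_at(sc_f[hit_f])),
    if (length(hit_r)) data.frame(start = n - hit_r + 1L, strand = "-",
                                  score = sc_r[hit_r], p = tail_at(sc_r[hit_r]))
  )
  if (is.null(out)) out <- data.frame(start = integer(0), strand = character(0),
                                      score = numeric(0), p = numeric(0))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter windows centered on the TSS
#'
#' Builds TSS +/- `flank` windows (width `2*flank + 1`) from a BED6-style
#' annotation: 0-based half-open gene intervals with strand; the TSS is
#' `start` on `+` genes and `end - 1` on `-` genes. Windows are clipped at
#' position 0 (contig starts) and flagged.
#'
#' @param bed Data.frame with columns chrom, start, end, name, score, strand
#'   (BED6) or a path to a BED file.
#' @param flank Half-window in bp; default 500 (a 1001-bp window).
#' @return Data.frame with gene, chrom, start, end (0-based half-open),
#'   strand, clipped.
#' @export
promoter_windows <- function(bed, flank = 500L) {
  if (is.character(bed)) {
    bed <- utils::read.delim(bed, header = FALSE, stringsAsFactors = FALSE)
    names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  }
  tss <- ifelse(bed$strand == "-", bed$end - 1L, bed$start)
  start <- tss - flank
  end <- tss + flank + 1L
  clipped <- start < 0
  start[clipped] <- 0L
  data.frame(gene = bed$name, chrom = bed$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = bed$strand, clipped = clipped,
             stringsAsFactors = FALSE)
}

#' Count predicted binding sites per gene per motif
#'
#' Scans the promoter window of every gene with every motif and records the
#' number of hits (both strands; overlapping hits each counted). Sequences
#' are looked up by gene id in `sequences`.
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet` of
#'   promoter sequences keyed by gene id.
#' @param motifs List of `motif_model` objects.
#' @param genes Genes to count; default all sequence names.
#' @param p_threshold Per-position scan threshold; default 1e-4.
#' @return Integer matrix genes x motifs.
#' @export
count_motifs <- function(sequences, motifs, genes = NULL, p_threshold = 1e-4) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(genes)) genes <- names(sequences)
  missing <- setdiff(genes, names(sequences))
  if (length(missing) > 0) {
    stop("no promoter sequence for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  counts <- matrix(0L, length(genes), length(motifs),
                   dimnames = list(genes, names(motifs)))
  for (m in seq_along(motifs)) {
    dist <- pwm_score_distribution(motifs[[m]])
    for (g in seq_along(genes)) {
      hits <- pwm_scan(sequences[[genes[g]]], motifs[[m]],
                       p_threshold = p_threshold, dist = dist)
      counts[g, m] <- nrow(hits)
    }
  }
  counts
}

#' Motif enrichment of a cluster versus random control genes
#'
#' For each motif, compares the number of cluster genes carrying >= 1
#' predicted site against an equal-sized control set drawn (seeded, without
#' replacement) from the non-cluster universe, with a one-sided
#' hypergeometric test, Bonferroni-adjusted over motifs. A motif is called
#' enriched when the adjusted p-value is below `alpha` (default 1e-10, an
#' intentionally extreme cutoff).
#'
#' @param cluster_genes Genes in the cluster (subset of `universe_genes`).
#' @param universe_genes All candidate genes.
#' @param counts Matrix from [count_motifs()] covering the universe.
#' @param seed Seed for the control draw.
#' @param alpha Adjusted-p enrichment threshold; default 1e-10.
#' @return Data.frame: motif, n_test, n_control, genes_with_site_test,
#'   genes_with_site_control, sites_test, sites_control, p, p_adj, enriched.
#' @export
enrich_cluster_motifs <- function(cluster_genes, universe_genes, counts,
                                  seed = 1L, alpha = 1e-10) {
  cluster_genes <- unique(cluster_genes)
  pool <- setdiff(universe_genes, cluster_genes)
  if (length(pool) == 0) stop("cluster equals the gene universe")
  if (length(pool) < length(cluster_genes)) {
    stop("not enough non-cluster genes to draw an equal-sized control set")
  }
  old_seed <- get_rng_state(); on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  control <- sample(pool, length(cluster_genes))
  ct <- counts[cluster_genes, , drop = FALSE]
  cc <- counts[control, , drop = FALSE]
  n <- length(cluster_genes)
  res <- data.frame(
    motif = colnames(counts),
    n_test = n, n_control = n,
    genes_with_site_test = colSums(ct >= 1),
    genes_with_site_control = colSums(cc >= 1),
    sites_test = colSums(ct),
    sites_control = colSums(cc),
    stringsAsFactors = FALSE, row.names = NULL)
  # one-sided hypergeometric: test-set carriers among all carriers, drawing
  # n test genes from the pooled 2n
  res$p <- mapply(function(a, b) {
    stats::phyper(a - 1, a + b, 2 * n - a - b, n, lower.tail = FALSE)
  }, res$genes_with_site_test, res$genes_with_site_control)
  res$p_adj <- pmin(1, res$p * ncol(counts))
  res$enriched <- res$p_adj < alpha
  res
}

#' Filter enriched motifs down to responsive, expressed TFs
#'
#' Keeps motifs whose TF gene (i) is in the expressed gene set and (ii) shows
#' at least `min_pct_change` percent change in transcript level between
#' housing conditions. Motifs of one TF collapse to the TF level; motifs with
#' no mapped TF gene are set aside in an `unmapped` bin.
#'
#' @param motifs List of `motif_model` objects (typically the enriched ones).
#' @param expressed Character vector of expressed gene ids.
#' @param fc [fold_changes()] table covering the TF genes.
#' @param min_pct_change Percent-change threshold; default 33.3 (the median
#'   fold change of the expressed gene set in the reference analysis).
#' @return List with `shortlist` (data.frame tf_gene, pct_change, log2fc,
#'   motif ids collapsed per TF) and `unmapped` (motif ids with no TF gene).
#' @export
filter_tfs <- function(motifs, expressed, fc, min_pct_change = 33.3) {
  tf <- vapply(motifs, function(m) m$tf_gene, character(1))
  ids <- vapply(motifs, function(m) m$motif_id, character(1))
  unmapped <- ids[is.na(tf)]
  keep <- !is.na(tf)
  tf <- tf[keep]; ids <- ids[keep]
  rows <- lapply(unique(tf), function(g) {
    if (!(g %in% expressed)) return(NULL)
    i <- match(g, fc$gene)
    if (is.na(i)) return(NULL)
    if (fc$pct_change[i] < min_pct_change) return(NULL)
    data.frame(tf_gene = g, pct_change = fc$pct_change[i],
               log2fc = fc$log2fc[i],
               motifs = paste(ids[tf == g], collapse = ","),
               stringsAsFactors = FALSE)
  })
  shortlist <- do.call(rbind, rows)
  if (is.null(shortlist)) {
    shortlist <- data.frame(tf_gene = character(0), pct_change = numeric(0),
                            log2fc = numeric(0), motifs = character(0))
  }
  list(shortlist = shortlist, unmapped = unmapped)
}
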