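test_that("MEME minimal files round-trip through the parser", {
  bg <- c(0.3, 0.2, 0.2, 0.3)  # one global background, as in the format
  motifs <- list(
    motif_model("M_alpha", consensus_pwm("ACGTTGCA"), tf_gene = "alpha",
                background = bg),
    motif_model("M_beta", consensus_pwm("TTGACCAT"), tf_gene = "beta",
                background = bg))
  names(motifs) <- c("M_alpha", "M_beta")
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(motifs, path)
  back <- read_meme(path)
  expect_identical(names(back), c("M_alpha", "M_beta"))
  expect_identical(back$M_alpha$tf_gene, "alpha")
  expect_equal(back$M_alpha$matrix_raw, motifs$M_alpha$matrix_raw,
               tolerance = 1e-4)
  expect_equal(back$M_alpha$matrix, motifs$M_alpha$matrix, tolerance = 1e-4)
  expect_equal(back$M_beta$background, motifs$M_beta$background,
               tolerance = 1e-4)
  expect_identical(back$M_alpha$length, 8L)
  junk <- withr::local_tempfile(fileext = ".txt", lines = "not a motif file")
  expect_error(read_meme(junk), "MEME")
})

test_that("exact score distribution matches brute-force enumeration for short motifs", {
  set.seed(14)
  for (L in c(4L, 6L)) {
    m <- motif_model(paste0("m", L),
                     matrix(prop.table(matrix(rgamma(L * 4, 1), L, 4), 1),
                            L, 4),
                     background = c(0.3, 0.2, 0.25, 0.25))
    g <- 1e-4
    dist <- pwm_score_distribution(m, granularity = g)
    expect_equal(sum(dist$prob), 1, tolerance = 1e-12)

    # oracle: enumerate all 4^L words on the same score grid
    words <- as.matrix(expand.grid(rep(list(1:4), L)))
    lo <- log2(sweep(m$matrix, 2, m$background, "/"))
    sc <- vapply(seq_len(nrow(words)), function(w)
      sum(round(lo[cbind(seq_len(L), words[w, ])] / g) * g), numeric(1))
    pr <- vapply(seq_len(nrow(words)), function(w)
      prod(m$background[words[w, ]]), numeric(1))
    enum <- tapply(pr, sprintf("%.6f", sc), sum)
    dp <- setNames(dist$prob, sprintf("%.6f", dist$score))
    expect_setequal(names(enum), names(dp))
    expect_lt(max(abs(enum[names(dp)] - dp)), 1e-9)
  }
})

test_that("score thresholds hit the exact tail: boundary p-values behave", {
  m <- motif_model("m", consensus_pwm("ACGGTA", 0.9))
  dist <- pwm_score_distribution(m)
  # threshold at the minimum score keeps everything: tail p = 1
  expect_equal(dist$tail_p[1], 1, tolerance = 1e-12)
  # no score exceeds the maximum: tail beyond it is empty
  thr <- pwm_score_threshold(dist, min(dist$tail_p))
  expect_equal(thr$threshold, max(dist$score))
  # p below the minimum attainable: no hit anywhere
  tiny <- pwm_score_threshold(dist, min(dist$tail_p) / 10)
  expect_identical(tiny$threshold, Inf)
  seqs <- random_dna(500)
  expect_identical(nrow(pwm_scan(seqs, m, min(dist$tail_p) / 10)), 0L)
})

test_that("pwm_scan finds planted consensus sites and respects N and length rules", {
  m <- motif_model("m", consensus_pwm("ACGGTAAC"))
  hit_seq <- paste0(strrep("T", 30), "ACGGTAAC", strrep("T", 30))
  hits <- pwm_scan(hit_seq, m, 1e-4)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 31L)
  expect_identical(hits$strand, "+")

  # same site on the reverse strand
  rc_seq <- paste0(strrep("T", 10), "GTTACCGT", strrep("C", 10))
  rhits <- pwm_scan(rc_seq, m, 1e-4)
  expect_identical(rhits$strand, "-")
  expect_identical(rhits$start, 11L)

  # windows containing N are skipped
  expect_identical(nrow(pwm_scan("ACGGNAAC", m, 1e-4)), 0L)
  # sequence shorter than the motif: empty hit list
  expect_identical(nrow(pwm_scan("ACG", m, 1e-4)), 0L)
})

test_that("scan hit rate on random sequence matches the exact null p-value", {
  # a mixed-information motif so the achieved p sits near the target
  set.seed(77)
  m <- motif_model("m", rbind(consensus_pwm("ACGGT", 0.8),
                              matrix(0.25, 3, 4)))
  dist <- pwm_score_distribution(m)
  p_hit <- pwm_score_threshold(dist, 1e-3)$p_achieved
  expect_lte(p_hit, 1e-3)
  n_seq <- 100
  L <- m$length
  positions <- 2 * (1001 - L + 1)  # both strands
  total <- sum(vapply(seq_len(n_seq), function(i)
    nrow(pwm_scan(random_dna(1001), m, 1e-3, dist = dist)), numeric(1)))
  bounds <- qbinom(c(0.005, 0.995), n_seq * positions, p_hit)
  expect_gte(total, bounds[1])
  expect_lte(total, bounds[2])
})

test_that("count_motifs counts planted and palindromic sites on both strands", {
  m <- motif_model("m", consensus_pwm("ACGGTAAC"))
  seqs <- c(gX = paste0(strrep("T", 20), "ACGGTAAC", strrep("C", 20),
                        "ACGGTAAC", strrep("T", 20)),
            gY = strrep("T", 80))
  ct <- count_motifs(seqs, list(m = m))
  expect_identical(ct["gX", "m"], 2L)
  expect_identical(ct["gY", "m"], 0L)

  # a reverse-complement palindrome is seen once per strand: count 2
  pal <- motif_model("pal", consensus_pwm("ACGCGT"))
  ct_pal <- count_motifs(c(gZ = paste0(strrep("T", 15), "ACGCGT",
                                       strrep("T", 15))),
                         list(pal = pal), p_threshold = 1e-3)
  expect_identical(ct_pal["gZ", "pal"], 2L)

  # strand symmetry: reverse-complementing every sequence leaves counts
  set.seed(31)
  seqs_f <- c(a = random_dna(300), b = random_dna(300))
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  seqs_r <- vapply(seqs_f, rc, character(1))
  ct_f <- count_motifs(seqs_f, list(m = m), p_threshold = 1e-3)
  ct_r <- count_motifs(seqs_r, list(m = m), p_threshold = 1e-3)
  expect_identical(ct_f, ct_r)

  expect_error(count_motifs(seqs, list(m = m), genes = c("gX", "missing")),
               "missing")
  empty <- count_motifs(seqs, list())
  expect_identical(ncol(empty), 0L)
})

test_that("promoter windows are TSS-centered, stranded and clip at contig edges", {
  bed <- data.frame(chrom = c("2L", "2L", "3R"),
                    start = c(5000L, 7000L, 100L),
                    end = c(6000L, 9000L, 900L),
                    name = c("gPlus", "gMinus", "gEdge"),
                    score = 0L, strand = c("+", "-", "+"))
  w <- promoter_windows(bed, flank = 500L)
  expect_equal(w$start[1], 4500L); expect_equal(w$end[1], 5501L)
  expect_equal(w$end[1] - w$start[1], 1001L)
  # minus strand: TSS at end - 1
  expect_equal(w$start[2], 8999L - 500L)
  # clipped at the contig start and flagged
  expect_equal(w$start[3], 0L)
  expect_true(w$clipped[3])
})

test_that("cluster enrichment reproduces the hypergeometric tail and flags correctly", {
  # planted carriers: 8/10 in the cluster, 2/10 in the only possible control
  counts <- matrix(0L, 20, 1, dimnames = list(sprintf("g%02d", 1:20), "m"))
  counts[c(1:8, 11:12), 1] <- 1L
  cluster <- sprintf("g%02d", 1:10)
  res <- enrich_cluster_motifs(cluster, sprintf("g%02d", 1:20), counts,
                               seed = 1)
  # oracle: exhaustive hypergeometric upper tail at >= 8 of 10 draws from a
  # pool of 20 with 10 carriers
  p_oracle <- sum(choose(10, 8:10) * choose(10, 10 - (8:10))) / choose(20, 10)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_false(res$enriched)   # nowhere near 1e-10
  expect_gte(res$p_adj, res$p)

  # identical prevalence in cluster and control: raw p >= 0.5
  flat <- matrix(rep(c(1L, 1L, 0L, 0L), 5), 20, 1,
                 dimnames = list(sprintf("g%02d", 1:20), "m"))
  res_flat <- enrich_cluster_motifs(sprintf("g%02d", seq(1, 20, 2)),
                                    sprintf("g%02d", 1:20), flat, seed = 1)
  expect_gte(res_flat$p, 0.5)
  expect_error(enrich_cluster_motifs(sprintf("g%02d", 1:20),
                                     sprintf("g%02d", 1:20), counts),
               "universe")
})

test_that("enrichment p-values are super-uniform under random cluster labels", {
  set.seed(19)
  genes <- sprintf("g%03d", 1:120)
  counts <- matrix(rbinom(120, 1, 0.4), 120, 1, dimnames = list(genes, "m"))
  ps <- vapply(1:400, function(i) {
    cl <- sample(genes, 40)
    enrich_cluster_motifs(cl, genes, counts, seed = i)$p
  }, numeric(1))
  # discrete one-sided test: P(p <= a) <= a at a grid of levels
  for (a in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 400))
  }
})

test_that("TF filter keeps expressed, strongly responding TFs and bins unmapped motifs", {
  motifs <- list(
    motif_model("M_hi", consensus_pwm("ACGTTGCA"), tf_gene = "tf_hi"),
    motif_model("M_hi2", consensus_pwm("TACGTGCA"), tf_gene = "tf_hi"),
    motif_model("M_lo", consensus_pwm("GGTACCAT"), tf_gene = "tf_lo"),
    motif_model("M_out", consensus_pwm("CATGGTAC"), tf_gene = "tf_out"),
    motif_model("M_anon", consensus_pwm("TTGGCCAA")))
  fc <- fold_changes(c(1.94, 1.2, 2.0), c(1.0, 1.0, 1.0),
                     c("tf_hi", "tf_lo", "tf_out"), pseudocount = 1e-9)
  out <- filter_tfs(motifs, expressed = c("tf_hi", "tf_lo"), fc)
  expect_identical(out$shortlist$tf_gene, "tf_hi")      # 94% change, expressed
  expect_match(out$shortlist$motifs, "M_hi,M_hi2")      # collapsed to TF level
  expect_identical(out$unmapped, "M_anon")
  # tf_lo fails the 33.3% threshold; tf_out is not expressed
  expect_false(any(c("tf_lo", "tf_out") %in% out$shortlist$tf_gene))
})
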