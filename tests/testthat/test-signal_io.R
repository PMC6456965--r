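test_that("signal tables round-trip through TSV and enforce invariants", {
  genes <- c("gA", "gB", "gC")
  vals <- matrix(c(1.25, 0, 3.5, 2.125, 7.75, 0.5), 3, 2)
  sm <- signal_matrix("H3K4me3", "GH", genes, vals)
  expect_equal(dim(sm$values), c(3L, 2L))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_signal_table(sm, path)
  back <- read_signal_table(path, "H3K4me3", "GH")
  expect_identical(back$genes, genes)
  expect_identical(unname(back$values), unname(vals))

  # duplicate gene id named in the error
  writeLines(c("gene\tr1", "gA\t1", "gA\t2"), path)
  expect_error(read_signal_table(path, "x", "GH"), "gA")
  # non-numeric cell located by row/column
  writeLines(c("gene\tr1\tr2", "gA\t1\t2", "gB\tabc\t3"), path)
  expect_error(read_signal_table(path, "x", "GH"), "row 2.*r1")
  expect_error(signal_matrix("x", "GH", "gA", matrix(-1)), "negative")
})

test_that("select_expressed keeps ceil(fraction * G) top genes with id tie-break", {
  # the reference dataset size: top 40% of 13430 genes is 5372
  G <- 13430
  expr <- data.frame(gene = sprintf("g%05d", 1:G),
                     tpm_gh = rev(seq_len(G)) / 10,
                     tpm_sh = rev(seq_len(G)) / 10,
                     cv_gh = NA_real_, cv_sh = NA_real_)
  kept <- select_expressed(expr, 0.4)
  expect_length(kept, 5372L)
  expect_identical(kept, expr$gene[1:5372])

  small <- expr[1:10, ]
  expect_length(select_expressed(small, 0.4), 4L)
  expect_setequal(select_expressed(small, 1.0), small$gene)

  # tie-break: equal TPM resolved lexicographically by gene id
  tie <- data.frame(gene = c("gB", "gA", "gC"), tpm_gh = c(1, 1, 1),
                    tpm_sh = c(1, 1, 1), cv_gh = NA, cv_sh = NA)
  expect_identical(select_expressed(tie, 2 / 3), c("gA", "gB"))
  expect_error(select_expressed(expr[0, ], 0.4), "empty")
})

test_that("signal-to-noise report flags noisy low-expressed genes", {
  set.seed(42)
  G <- 600
  # top half: strong signal; bottom half: sparse Poisson-like counts whose
  # sd exceeds the mean, so mean/sd sits below 1
  reps <- 24
  top <- matrix(rnorm(300 * reps, 1000, 10), 300, reps)
  bottom <- matrix(rpois(300 * reps, 0.3), 300, reps) + 0.01
  vals <- rbind(top, bottom)
  genes <- sprintf("g%03d", 1:G)
  gh <- signal_matrix("mRNA", "GH", genes, vals)
  sh <- signal_matrix("mRNA", "SH", genes, vals)
  expr <- expression_table(gh, sh)
  rep50 <- signal_to_noise_report(expr, 0.5)
  # direct CV oracle on the below-cutoff half
  cv <- apply(bottom, 1, sd) / rowMeans(bottom)
  expect_equal(rep50$n_below, 300L)
  expect_equal(rep50$share_snr_below_1, mean(1 / cv[!is.na(cv)] < 1),
               tolerance = 0.02)
  expect_gt(rep50$share_snr_below_1, 0.8)

  # fraction = 1: nothing below the cutoff
  rep100 <- signal_to_noise_report(expr, 1.0)
  expect_false(rep100$applicable)

  # single replicate: CV undefined, flagged
  gh1 <- signal_matrix("mRNA", "GH", genes, vals[, 1, drop = FALSE])
  sh1 <- signal_matrix("mRNA", "SH", genes, vals[, 1, drop = FALSE])
  rep1 <- signal_to_noise_report(expression_table(gh1, sh1), 0.5)
  expect_false(rep1$cv_defined)
})

test_that("make_delta z-scores GH-SH differences per signal", {
  fx <- two_condition_signal(c(1, 2, 3))
  d <- make_delta(list(mRNA = fx$gh), list(mRNA = fx$sh), c("g1", "g2", "g3"))
  # raw differences 1,2,3: sample sd is exactly 1, so z = -1, 0, 1
  expect_equal(unname(d$z[, "mRNA"]), c(-1, 0, 1))

  # degenerate: GH == SH everywhere -> zero-variance column, error names it
  same <- signal_matrix("H3K27ac", "GH", c("g1", "g2"), cbind(c(5, 5)))
  expect_error(
    make_delta(list(H3K27ac = same),
               list(H3K27ac = signal_matrix("H3K27ac", "SH", c("g1", "g2"),
                                            cbind(c(5, 5)))),
               c("g1", "g2")),
    "H3K27ac")
})

test_that("delta columns are normalized and invariant to gene permutation", {
  set.seed(11)
  land <- gen_landscape(landscape_spec(n_genes = 200, k = 3, separation = 4),
                        seed = 3)
  d <- make_delta(land$gh, land$sh, land$truth$genes)
  expect_lt(max(abs(colMeans(d$z))), 1e-9)
  expect_lt(max(abs(apply(d$z, 2, sd) - 1)), 1e-9)

  perm <- sample(land$truth$genes)
  dp <- make_delta(land$gh, land$sh, perm)
  expect_equal(dp$z[land$truth$genes, ], d$z[land$truth$genes, ])
})

test_that("fold changes match the percent-change definition and are symmetric", {
  # 94% worked example: GH mean 1.94 vs SH mean 1.0 at vanishing pseudocount
  fc <- fold_changes(1.94, 1.0, "cbt", pseudocount = 1e-9)
  expect_equal(fc$pct_change, 94, tolerance = 1e-6)
  expect_equal(fc$log2fc, log2(1.94), tolerance = 1e-6)

  # no change and the 33.33% boundary case (ratio 4/3)
  none <- fold_changes(5, 5, "gX")
  expect_equal(none$log2fc, 0)
  expect_equal(none$pct_change, 0)
  edge <- fold_changes(4, 3, "gY", pseudocount = 1e-12)
  expect_equal(edge$pct_change, 100 / 3, tolerance = 1e-6)

  # direction-free: swapping conditions flips log2fc, preserves pct_change
  a <- fold_changes(c(2, 8, 0.2), c(1, 2, 1), pseudocount = 0.5)
  b <- fold_changes(c(1, 2, 1), c(2, 8, 0.2), pseudocount = 0.5)
  expect_equal(a$pct_change, b$pct_change)
  expect_equal(a$log2fc, -b$log2fc)
  expect_error(fold_changes(-1, 1), "negative")
  expect_error(fold_changes(1, 1, pseudocount = 0), "pseudocount")
})
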