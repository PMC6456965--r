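test_that("sleep bouts require five consecutive inactive minutes", {
  pad <- function(z) c(rep(1, 10), z, rep(1, 1440 - 10 - length(z)))
  four <- activity_trace("f4", "ctl", "GH", pad(rep(0, 4)))
  five <- activity_trace("f5", "ctl", "GH", pad(rep(0, 5)))
  expect_equal(sum(score_sleep(four)$mask), 0)
  s5 <- score_sleep(five)
  expect_equal(sum(s5$mask), 5)
  expect_equal(s5$bouts$start, 11)
  expect_equal(s5$bouts$length, 5)

  # saturation: an all-zero day is 720 sleep minutes
  full <- activity_trace("f6", "ctl", "GH", rep(0L, 1440))
  expect_equal(daytime_sleep(full), 720)
  # no bout shorter than 5; total sleep equals summed bout lengths
  set.seed(121)
  tr <- activity_trace("f7", "ctl", "SH", rbinom(1440, 1, 0.6))
  s <- score_sleep(tr)
  expect_true(all(s$bouts$length >= 5))
  expect_equal(sum(s$mask), sum(s$bouts$length))
})

test_that("scoring is idempotent and unaffected by appended awake minutes", {
  set.seed(122)
  counts <- rbinom(1440, 2, 0.5)
  m1 <- score_sleep(counts)$mask
  # re-score the mask-as-counts: asleep minutes are zeros, awake nonzero
  m2 <- score_sleep(as.integer(!m1))$mask
  expect_identical(m1, m2)
  longer <- c(counts, rep(1L, 1440))
  expect_identical(score_sleep(longer)$mask[1:1440], m1)
})

test_that("daytime sleep splits bouts at the lights-off boundary", {
  # a bout from ZT11:58 through ZT12:09 contributes exactly 2 day minutes
  cnt <- rep(1L, 1440)
  cnt[719:730] <- 0L
  tr <- activity_trace("fb", "ctl", "GH", cnt)
  expect_equal(daytime_sleep(tr), 2)

  awake <- activity_trace("fa", "ctl", "GH", rep(1L, 1440))
  expect_equal(daytime_sleep(awake), 0)
  short <- activity_trace("fs", "ctl", "GH", rep(0L, 1440),
                          lights_on_index = 100L)
  expect_error(daytime_sleep(short), "24-h")
})

test_that("traces with gaps or ragged lengths are rejected", {
  expect_error(activity_trace("g1", "ctl", "GH", c(rep(0, 100), NA,
                                                   rep(0, 1339))), "gaps")
  expect_error(activity_trace("g2", "ctl", "GH", rep(0, 1000)), "whole number")
  expect_error(activity_trace("g3", "ctl", "GH", c(-1, rep(0, 1439))),
               "negative")
})

test_that("delta_sleep is the difference of group means", {
  ds <- delta_sleep(c(380, 420), c(240, 260))
  expect_equal(ds$delta_sleep, 150)
  expect_equal(ds$mean_gh, 400)
  same <- delta_sleep(c(100, 200), c(100, 200))
  expect_equal(same$delta_sleep, 0)
  expect_error(delta_sleep(numeric(0), c(1)), "non-empty")
})

test_that("monitor files round-trip through the reader with acclimation trim", {
  spec <- behavior_spec(flies_per_group = 3, days = 2)
  act <- gen_activity(spec, seed = 17, genotypes = "control")
  mon <- withr::local_tempfile(fileext = ".tsv")
  meta <- withr::local_tempfile(fileext = ".csv")
  write_monitor(act$traces, mon, meta)
  back <- read_monitor(mon, meta, lights_on_index = 1L, trim_minutes = 1440L)
  expect_length(back, 6L)
  for (i in seq_along(back)) {
    orig <- act$traces[[i]]
    expect_identical(back[[i]]$counts, orig$counts[1441:2880])
    expect_identical(back[[i]]$fly_id, orig$fly_id)
    expect_identical(back[[i]]$housing, orig$housing)
  }
})

test_that("type III interaction ANOVA matches the textbook balanced decomposition", {
  # balanced 2 x 2 with n = 3 per cell and hand-computable cell means
  a <- rep(c("a1", "a2"), each = 6)
  b <- rep(rep(c("b1", "b2"), each = 3), 2)
  y <- c(10, 12, 14, 20, 22, 24, 30, 32, 34, 20, 22, 24)
  out <- interaction_anova(y, data.frame(A = a, B = b))

  # oracle: classical two-way formulas computed independently
  cell <- tapply(y, list(a, b), mean)
  gm <- mean(y)
  ss_a <- 6 * sum((rowMeans(cell) - gm)^2)
  ss_b <- 6 * sum((colMeans(cell) - gm)^2)
  ss_ab <- 3 * sum((cell - outer(rowMeans(cell), colMeans(cell), "+") + gm)^2)
  ss_res <- sum((y - cell[cbind(a, b)])^2)
  expect_equal(out$sum_sq[out$term == "A"], ss_a, tolerance = 1e-9)
  expect_equal(out$sum_sq[out$term == "B"], ss_b, tolerance = 1e-9)
  expect_equal(out$sum_sq[out$term == "A:B"], ss_ab, tolerance = 1e-9)
  expect_equal(out$sum_sq[out$term == "Residuals"], ss_res, tolerance = 1e-9)
  expect_equal(sum(out$sum_sq), attr(out, "total_ss"), tolerance = 1e-6)

  # balanced: type III agrees with the sequential (type I) table
  seq_tab <- anova(lm(y ~ a * b))
  expect_equal(out$sum_sq[1:3], seq_tab$`Sum Sq`[1:3], tolerance = 1e-9)

  # additive zero-noise data: interaction SS exactly 0
  y_add <- 5 + 2 * (a == "a2") + 3 * (b == "b2") + 0
  out_add <- interaction_anova(y_add, data.frame(A = a, B = b))
  expect_equal(out_add$sum_sq[out_add$term == "A:B"], 0, tolerance = 1e-9)

  # missing design cell is named
  expect_error(
    interaction_anova(y[1:9],
                      data.frame(A = c(rep("a1", 6), rep("a2", 3)),
                                 B = c(rep(c("b1", "b2"), each = 3),
                                       rep("b1", 3)))),
    "cell.*a2\\.b2")
})

test_that("type III sums of squares agree with an independent implementation on unbalanced data", {
  skip_if_not_installed("car")
  set.seed(141)
  # deliberately unbalanced: type III differs from sequential here
  g <- c(rep("ctl", 14), rep("kd", 10))
  h <- c(rep(c("GH", "SH"), c(8, 6)), rep(c("GH", "SH"), c(4, 6)))
  y <- 100 + 20 * (h == "GH") + 10 * (g == "kd") + rnorm(24, 0, 5)
  ours <- interaction_anova(y, data.frame(genotype = g, housing = h))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  d <- data.frame(y = y, genotype = g, housing = h)
  theirs <- car::Anova(lm(y ~ genotype * housing, data = d), type = 3)
  for (term in c("genotype", "housing", "genotype:housing")) {
    expect_equal(ours$sum_sq[ours$term == term],
                 theirs[term, "Sum Sq"], tolerance = 1e-9)
    expect_equal(ours$p[ours$term == term],
                 theirs[term, "Pr(>F)"], tolerance = 1e-9)
  }
})

test_that("interaction p-values are uniform under a null genotype factor", {
  set.seed(131)
  ps <- vapply(1:300, function(i) {
    g <- rep(c("ctl", "kd"), each = 16)
    h <- rep(rep(c("GH", "SH"), each = 8), 2)
    y <- 100 + 50 * (h == "GH") + rnorm(32, 0, 20)  # no genotype effect
    av <- interaction_anova(y, data.frame(genotype = g, housing = h))
    av$p[av$term == "genotype:housing"]
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
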