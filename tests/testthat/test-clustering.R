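test_that("kmeans_fit separates point masses and is deterministic", {
  x <- rbind(matrix(rnorm(50 * 7, 0, 0.1), 50, 7) +
               matrix(c(10, rep(0, 6)), 50, 7, byrow = TRUE),
             matrix(rnorm(50 * 7, 0, 0.1), 50, 7) -
               matrix(c(10, rep(0, 6)), 50, 7, byrow = TRUE))
  f1 <- kmeans_fit(x, 2, seed = 9)
  f2 <- kmeans_fit(x, 2, seed = 9)
  expect_identical(f1$labels, f2$labels)
  expect_identical(sort(f1$sizes), c(50L, 50L))
  # inertia ~ within-mass variance only
  expect_lt(f1$inertia, 0.1^2 * 100 * 7 * 2)

  # 3 planted spherical gaussians at 10 sigma: near-perfect recovery
  set.seed(21)
  centers <- matrix(rnorm(3 * 5), 3, 5) * 10
  truth <- rep(1:3, each = 60)
  y <- centers[truth, ] + matrix(rnorm(180 * 5), 180, 5)
  fit <- kmeans_fit(y, 3, seed = 4)
  expect_gte(ari(fit$labels, truth), 0.99)
})

test_that("kmeans_fit inertia does not increase with more restarts", {
  set.seed(33)
  x <- matrix(rnorm(300 * 4), 300, 4)
  inertias <- vapply(c(1, 3, 6, 10), function(r)
    kmeans_fit(x, 5, seed = 2, restarts = r)$inertia, numeric(1))
  expect_true(all(diff(inertias) <= 1e-9))
})

test_that("choose_k finds planted structure and handles degenerate inputs", {
  # single tight blob: BIC picks k = 1
  set.seed(5)
  blob <- matrix(rnorm(300 * 4, 0, 0.3), 300, 4)
  expect_identical(choose_k(blob, 1, 5, "bic", seed = 1)$k, 1L)

  # 3 well-separated planted clusters, all columns informative: both
  # criteria agree with the generator truth in >= 90% of seeds
  pat <- rbind(c(-1.5, -1, -1, -1, 1, 1, 1),
               c(0, 1, -1, 1, -1, -1, 1),
               c(1.5, -1, 1, 1, 1, -1, -1))
  hits <- vapply(1:10, function(s) {
    land <- gen_landscape(landscape_spec(n_genes = 300, k = 3, separation = 8,
                                         patterns = pat), seed = s)
    d <- make_delta(land$gh, land$sh, land$truth$genes)
    c(choose_k(d, 2, 8, "bic", seed = s, restarts = 3)$k,
      choose_k(d, 2, 8, "elbow", seed = s, restarts = 3)$k)
  }, numeric(2))
  expect_gte(mean(hits[1, ] == 3), 0.9)
  expect_gte(mean(hits[2, ] == 3), 0.9)

  # featureless uniform cube: curve returned, no crash, flagged
  set.seed(6)
  cube <- matrix(runif(400 * 3), 400, 3)
  out <- choose_k(cube, 2, 8, "elbow", seed = 1, restarts = 2)
  expect_identical(nrow(out$curve), 7L)
  expect_true(is.logical(out$low_confidence))
  expect_error(choose_k(blob, 5, 4), "k_max < k_min")
})

test_that("stability combinatorics are exact and overlaps match hand enumeration", {
  # hand case: assignments {g1,g2}{g3,g4} vs {g1,g3}{g2,g4} -> every
  # cluster's best match holds exactly half of it
  ov <- dopascape:::max_overlap(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L), 2L)
  expect_equal(ov, c(50, 50))
  # label-permutation invariance of the overlap metric
  ov2 <- dopascape:::max_overlap(c(2L, 2L, 1L, 1L), c(1L, 2L, 1L, 2L), 2L)
  expect_equal(sort(ov2), sort(ov))

  set.seed(8)
  land <- gen_landscape(landscape_spec(n_genes = 300, k = 3, separation = 6),
                        seed = 2)
  d <- make_delta(land$gh, land$sh, land$truth$genes)
  st <- cluster_stability(d, 3, n_runs = 5, base_seed = 10, restarts = 2)
  expect_identical(st$pair_count, 10L)              # 5 * 4 / 2
  expect_length(st$overlap_records, 30L)            # k * pairs
  expect_true(all(st$overlap_records >= 0 & st$overlap_records <= 100))

  # well-separated planted data: all runs agree, every record is 100
  expect_equal(st$median_overlap, 100)
  expect_equal(st$frac_above_99, 1)
  expect_error(cluster_stability(d, 3, n_runs = 1), "n_runs")
})

test_that("cluster profiles are ordered by mRNA and conserve gene counts", {
  land <- gen_landscape(landscape_spec(n_genes = 400, k = 3, separation = 6),
                        seed = 12)
  d <- make_delta(land$gh, land$sh, land$truth$genes)
  fit <- kmeans_fit(d, 3, seed = 1)
  prof <- profile_clusters(d, fit)
  expect_identical(sum(prof$sizes), 400L)
  expect_true(all(diff(prof$means[, "mRNA"]) > 0))

  # recovered per-cluster means match the planted means mapped into z units:
  # each column of z is the raw delta centered on the mixture mean and
  # scaled by sqrt(within variance + replicate-mean noise + between-cluster
  # variance), so the planted cluster mean transforms the same way
  spec <- landscape_spec(n_genes = 400, k = 3, separation = 6)
  mix_mean <- colMeans(spec$means)
  between <- colMeans(sweep(spec$means, 2, mix_mean)^2)
  noise_var <- spec$within_sd^2 +
    2 * spec$replicate_noise_sd^2 / spec$replicates
  col_sd <- sqrt(noise_var + between)
  z_planted <- sweep(sweep(spec$means, 2, mix_mean), 2, col_sd, "/")
  planted_of_cluster <- vapply(1:3, function(c) {
    genes_c <- which(prof$labels == c)
    as.integer(names(which.max(table(land$truth$labels[genes_c]))))
  }, integer(1))
  for (c in 1:3) {
    n_c <- prof$sizes[c]
    sem <- sqrt(noise_var) / col_sd / sqrt(n_c)
    expect_true(all(abs(prof$means[c, ] -
                          z_planted[planted_of_cluster[c], ]) < 4 * sem))
  }
})
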