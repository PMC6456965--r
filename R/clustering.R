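#' k-means++ initial centers
#'
#' Standard k-means++ seeding: first center uniform, subsequent centers drawn
#' with probability proportional to squared distance to the nearest chosen
#' center. Operates on the active RNG stream.
#'
#' @param x Numeric matrix (observations x features).
#' @param k Number of centers.
#' @return k x ncol(x) matrix of initial centers.
#' @keywords internal
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  if (k > 1) for (j in 2:k) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Fit k-means to a delta matrix
#'
#' Lloyd's algorithm with k-means++ seeding, best of `restarts`
#' initializations by total within-cluster sum of squares. Deterministic
#' given `seed`. If Lloyd iteration produces an empty cluster, that start is
#' retried with the offending centroid re-seeded from the point farthest
#' from its assigned centroid, so the requested k is always preserved.
#'
#' @param delta A `delta_matrix` (or plain numeric matrix).
#' @param k Number of clusters, `2 <= k <= n/10` for a delta matrix.
#' @param seed Integer seed.
#' @param restarts Number of k-means++ starts; best by inertia wins.
#' @param iter_max Lloyd iteration cap per start.
#' @return A `cluster_assignment`: list with `genes`, `labels` (1..k), `k`,
#'   `seed`, `inertia`, `centers`, `sizes`.
#' @export
kmeans_fit <- function(delta, k, seed = 1L, restarts = 5L, iter_max = 100L) {
  x <- if (inherits(delta, "delta_matrix")) delta$z else as.matrix(delta)
  genes <- if (inherits(delta, "delta_matrix")) delta$genes else rownames(x)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(x)))
  n <- nrow(x)
  if (k < 1 || k > n) stop("k out of range")
  if (inherits(delta, "delta_matrix") && (k < 2 || k > n / 10)) {
    stop("k must satisfy 2 <= k <= n_genes/10 for a delta matrix")
  }
  best <- NULL
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, k)
    fit <- lloyd_with_reseed(x, centers, iter_max)
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(list(genes = genes,
                 labels = as.integer(best$cluster),
                 k = as.integer(k),
                 seed = as.integer(seed),
                 inertia = best$tot.withinss,
                 centers = best$centers,
                 sizes = as.integer(best$size)),
            class = "cluster_assignment")
}

# Lloyd via stats::kmeans; on the rare empty-cluster error, replace the
# centroid involved with the farthest point from its current center and retry.
#' @keywords internal
lloyd_with_reseed <- function(x, centers, iter_max, max_retries = 25L) {
  for (attempt in seq_len(max_retries)) {
    # "did not converge" warnings are acceptable; empty-cluster errors are not
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers,
                                     iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) e)
    if (!inherits(fit, "error")) return(fit)
    # nearest-center assignment to find an empty centroid and the farthest
    # point, then re-seed that centroid at the farthest point
    d2 <- vapply(seq_len(nrow(centers)), function(j)
      rowSums((x - matrix(centers[j, ], nrow(x), ncol(x), byrow = TRUE))^2),
      numeric(nrow(x)))
    nearest <- max.col(-d2, ties.method = "first")
    far <- which.max(d2[cbind(seq_len(nrow(x)), nearest)])
    empty <- setdiff(seq_len(nrow(centers)), unique(nearest))
    target <- if (length(empty) > 0) empty[1] else sample.int(nrow(centers), 1)
    centers[target, ] <- x[far, ]
  }
  stop("k-means failed to resolve empty clusters after re-seeding")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k=%d over %d genes, inertia=%.3f (seed %d)\n",
              x$k, length(x$genes), x$inertia, x$seed))
  cat("sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

# Save/restore .Random.seed so fits don't perturb the caller's RNG stream.
#' @keywords internal
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @keywords internal
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Log-likelihood of a hard-assignment spherical Gaussian mixture
#'
#' Shared variance across clusters and dimensions, estimated from the total
#' within-cluster sum of squares; mixture weights from cluster sizes.
#'
#' @keywords internal
spherical_loglik <- function(n, d, sizes, tot_withinss) {
  sigma2 <- tot_withinss / (n * d)
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  sum(sizes * log(sizes / n)) - (n * d / 2) * log(2 * pi * sigma2) - n * d / 2
}

#' Choose the number of clusters
#'
#' Fits k-means over a candidate range and selects k either by a
#' spherical-Gaussian BIC, `-2 * loglik + (k*d + 1) * log(n)` (minimum wins),
#' or by the elbow rule (largest second difference of inertia over k). The
#' full diagnostic curve is returned so either criterion can be inspected.
#'
#' @param delta A `delta_matrix` or numeric matrix.
#' @param k_min,k_max Candidate range (inclusive); `k_min >= 1`.
#' @param criterion `"bic"` or `"elbow"`.
#' @param seed,restarts Passed to the per-k fits (seed offset by k).
#' @return List with `k` (chosen), `criterion`, `curve` (data.frame of k,
#'   inertia, bic) and `low_confidence` (TRUE when the criterion barely
#'   discriminates, e.g. featureless data).
#' @export
choose_k <- function(delta, k_min = 1L, k_max = 12L,
                     criterion = c("bic", "elbow"), seed = 1L, restarts = 5L) {
  criterion <- match.arg(criterion)
  if (k_max < k_min) stop("k_max < k_min")
  if (k_min < 1) stop("k_min must be >= 1")
  x <- if (inherits(delta, "delta_matrix")) delta$z else as.matrix(delta)
  n <- nrow(x); d <- ncol(x)
  ks <- seq.int(k_min, k_max)
  inertia <- numeric(length(ks)); bic <- numeric(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k == 1) {
      ctr <- colMeans(x)
      w <- sum(sweep(x, 2, ctr)^2)
      inertia[i] <- w
      ll <- spherical_loglik(n, d, n, w)
    } else {
      fit <- kmeans_fit(x, k, seed = seed + k, restarts = restarts)
      inertia[i] <- fit$inertia
      ll <- spherical_loglik(n, d, fit$sizes, fit$inertia)
    }
    bic[i] <- -2 * ll + (k * d + 1) * log(n)
  }
  curve <- data.frame(k = ks, inertia = inertia, bic = bic)
  if (criterion == "bic") {
    k_hat <- ks[which.min(bic)]
    spread <- diff(range(bic))
    low_conf <- spread < 2 * log(n)
  } else {
    if (length(ks) < 3) stop("elbow criterion needs at least 3 candidate k")
    second_diff <- diff(diff(inertia))  # at interior ks[2..(m-1)]
    k_hat <- ks[which.max(second_diff) + 1L]
    low_conf <- max(second_diff) <= 0 ||
      max(second_diff) < 0.05 * abs(inertia[1] - inertia[length(ks)])
  }
  list(k = as.integer(k_hat), criterion = criterion, curve = curve,
       low_confidence = low_conf)
}

#' Maximum percent overlap between two cluster assignments
#'
#' For each cluster c of `a`, the percent overlap `100 * |c intersect c'| /
#' |c|` maximized over clusters c' of `b`. Invariant under relabeling of
#' either assignment.
#'
#' @param a,b Integer label vectors over the same genes (same order).
#' @param k Number of clusters in `a`.
#' @return Numeric vector of length k (one record per cluster of `a`).
#' @keywords internal
max_overlap <- function(a, b, k) {
  tab <- table(factor(a, levels = seq_len(k)), b)
  as.numeric(100 * apply(tab, 1, max) / rowSums(tab))
}

#' Cluster-stability report via repeated k-means runs
#'
#' Runs k-means `n_runs` times with distinct seeds (`base_seed + run index`).
#' For every unordered pair of runs (i < j) and every cluster c of the
#' lower-indexed run i, records the maximum percent overlap of c with the
#' clusters of run j: `100 * |c intersect c'| / |c|` maximized over c'. With
#' N runs and k clusters this yields exactly `N(N-1)/2` pairs and
#' `k * N(N-1)/2` overlap records, summarized by their median and the
#' fraction exceeding 99%.
#'
#' @param delta A `delta_matrix` or numeric matrix.
#' @param k Cluster count.
#' @param n_runs Number of repeated assignments N (>= 2); 46 reproduces a
#'   1035-pair design.
#' @param base_seed First seed; run r uses `base_seed + r - 1`.
#' @param restarts Restarts per run.
#' @return A `stability_report`: list with `n_runs`, `k`, `pair_count`,
#'   `overlap_records`, `median_overlap`, `frac_above_99`, `seeds`.
#' @export
cluster_stability <- function(delta, k, n_runs = 46L, base_seed = 1L,
                              restarts = 5L) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  runs <- lapply(seeds, function(s) kmeans_fit(delta, k, seed = s,
                                               restarts = restarts)$labels)
  pairs <- utils::combn(n_runs, 2)
  records <- numeric(k * ncol(pairs))
  pos <- 1L
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    records[pos:(pos + k - 1L)] <- max_overlap(runs[[i]], runs[[j]], k)
    pos <- pos + k
  }
  structure(list(n_runs = as.integer(n_runs), k = as.integer(k),
                 pair_count = as.integer(n_runs * (n_runs - 1) / 2),
                 overlap_records = records,
                 median_overlap = stats::median(records),
                 frac_above_99 = mean(records > 99),
                 seeds = seeds),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("<stability_report> N=%d runs, k=%d: %d pairs, ",
                     "%d overlap records\n  median overlap %.1f%%, ",
                     "%.0f%% of records > 99%%\n"),
              x$n_runs, x$k, x$pair_count, length(x$overlap_records),
              x$median_overlap, 100 * x$frac_above_99))
  invisible(x)
}

#' Per-cluster signal profiles ordered by mean mRNA expression
#'
#' Computes per-cluster mean z per signal and gene counts, then renumbers the
#' clusters in increasing order of mean mRNA z (heat-map convention: cluster
#' 1 most SH-shifted mRNA, cluster k most GH-shifted).
#'
#' @param delta A `delta_matrix` containing an `"mRNA"` column (or the column
#'   named by `order_by`).
#' @param assignment A `cluster_assignment` over the same genes.
#' @param order_by Signal column used to order clusters; default `"mRNA"`.
#' @return A `cluster_profile`: list with `means` (k x signals), `sizes`,
#'   `order` (old label -> new), `labels` (re-indexed per-gene labels).
#' @export
profile_clusters <- function(delta, assignment, order_by = "mRNA") {
  stopifnot(inherits(delta, "delta_matrix"),
            inherits(assignment, "cluster_assignment"))
  if (!identical(delta$genes, assignment$genes)) {
    stop("assignment genes do not match delta genes")
  }
  k <- assignment$k
  lab <- assignment$labels
  means <- t(vapply(seq_len(k), function(c)
    colMeans(delta$z[lab == c, , drop = FALSE]), numeric(length(delta$signals))))
  colnames(means) <- delta$signals
  sizes <- as.integer(table(factor(lab, levels = seq_len(k))))
  if (!order_by %in% delta$signals) {
    ord <- seq_len(k)  # no mRNA column: keep original order
  } else {
    ord <- order(means[, order_by])
  }
  new_of_old <- integer(k); new_of_old[ord] <- seq_len(k)
  structure(list(means = means[ord, , drop = FALSE],
                 sizes = sizes[ord],
                 order = new_of_old,
                 labels = new_of_old[lab],
                 signals = delta$signals),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  k <- nrow(x$means)
  cat(sprintf("<cluster_profile> %d clusters (ordered by ascending %s)\n",
              k, if ("mRNA" %in% x$signals) "mean mRNA z" else "input order"))
  cat("N (genes per cluster):",
      paste(sprintf("%d:%d", seq_len(k), x$sizes), collapse = " "), "\n")
  invisible(x)
}
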