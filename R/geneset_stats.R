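#' Exact binomial sign test
#'
#' Exact binomial test at p = 1/2 for counts of direction agreements, the
#' test behind "14 of 15 mitochondrial genes higher in SH" style statements.
#' One-sided: upper tail P(X >= successes). Two-sided: twice the smaller
#' tail, capped at 1.
#'
#' @param successes Number of successes (e.g. genes moving in the focal
#'   direction).
#' @param trials Total number of genes tested.
#' @param sidedness `"one"` or `"two"`. Reported analyses mix the two, so the
#'   choice is always explicit.
#' @return List with `successes`, `trials`, `sidedness`, `p`.
#' @export
sign_test <- function(successes, trials, sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  if (trials < 1) stop("trials must be >= 1")
  if (successes < 0 || successes > trials) {
    stop("successes must be between 0 and trials")
  }
  upper <- stats::pbinom(successes - 1, trials, 0.5, lower.tail = FALSE)
  lower <- stats::pbinom(successes, trials, 0.5)
  p <- switch(sidedness,
              one = upper,
              two = min(1, 2 * min(upper, lower)))
  list(successes = as.integer(successes), trials = as.integer(trials),
       sidedness = sidedness, p = p)
}

#' Compare a signal between two disjoint gene sets
#'
#' Two-sample test of per-gene values (z deltas or log fold changes) between
#' two gene sets, e.g. targets repressed vs activated by a TF. When `values`
#' is a matrix, one row of results per signal column, reported per signal
#' with no cross-signal adjustment.
#'
#' @param values Named numeric vector (or genes x signals matrix with
#'   rownames) of per-gene values.
#' @param setA,setB Disjoint, non-empty gene-id vectors present in `values`.
#' @param test `"welch_t"` (default) or `"wilcoxon"`.
#' @return Data.frame with signal, n_a, n_b, mean_a, mean_b, statistic, p,
#'   direction (sign of mean_a - mean_b).
#' @export
compare_sets <- function(values, setA, setB, test = c("welch_t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(intersect(setA, setB)) > 0) stop("gene sets must be disjoint")
  if (length(setA) == 0 || length(setB) == 0) stop("both sets must be non-empty")
  if (is.null(dim(values))) {
    values <- matrix(values, ncol = 1,
                     dimnames = list(names(values), "value"))
  }
  missing <- setdiff(c(setA, setB), rownames(values))
  if (length(missing) > 0) {
    stop("genes absent from values: ", paste(utils::head(missing, 5),
                                             collapse = ", "))
  }
  one_signal <- function(sig) {
    a <- values[setA, sig]; b <- values[setB, sig]
    if (test == "welch_t") {
      if (length(a) < 2 || length(b) < 2) {
        stop("welch_t needs >= 2 genes per set; try test = 'wilcoxon'")
      }
      ht <- stats::t.test(a, b, var.equal = FALSE)
    } else {
      ht <- stats::wilcox.test(a, b, exact = FALSE)
    }
    data.frame(signal = sig, n_a = length(a), n_b = length(b),
               mean_a = mean(a), mean_b = mean(b),
               statistic = unname(ht$statistic), p = ht$p.value,
               direction = sign(mean(a) - mean(b)),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(colnames(values), one_signal))
}

#' Correlate fold changes with an external dataset
#'
#' Pearson correlation of per-gene log fold changes between this dataset and
#' an external one (e.g. activity-regulated-gene responses measured under
#' direct neuronal stimulation), joined on gene id.
#'
#' @param fc_self Named numeric vector, gene -> log fold change (this data).
#' @param fc_external Named numeric vector from the external study.
#' @return List with `r`, `p`, `n` (shared genes used), `genes`.
#' @export
correlate_fc <- function(fc_self, fc_external) {
  shared <- intersect(names(fc_self), names(fc_external))
  if (length(shared) < 3) stop("need >= 3 shared genes; have ", length(shared))
  ct <- stats::cor.test(fc_self[shared], fc_external[shared],
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared),
       genes = shared)
}
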