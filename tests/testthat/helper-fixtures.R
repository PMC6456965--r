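# Small in-code fixtures shared across test files.

# A near-degenerate PWM for a consensus string: prob `p` on the consensus
# base, remainder spread evenly.
consensus_pwm <- function(consensus, p = 0.97) {
  chars <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p) / 3, length(chars), 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(chars), match(chars, c("A", "C", "G", "T")))] <- p
  m
}

# Tiny GH/SH signal-matrix pair with prescribed per-gene replicate-mean
# difference on a single signal.
two_condition_signal <- function(diffs, signal = "mRNA", genes = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_along(diffs))
  base <- 10 + seq_along(diffs)
  list(gh = signal_matrix(signal, "GH", genes, cbind(base + diffs)),
       sh = signal_matrix(signal, "SH", genes, cbind(base)))
}

# Random DNA string under a base-probability vector.
random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Adjusted Rand index (independent of the clustering code under test);
# falls back to a direct pair-counting implementation if mclust is absent.
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
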