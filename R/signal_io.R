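#' Read a per-gene signal quantification table
#'
#' Reads a tab-delimited table of one signal (a histone mark or mRNA) in one
#' housing condition: header row, first column gene id, remaining columns
#' replicate measurements on the signal's normalized scale (coverage or TPM).
#'
#' @param path Path to a TSV file.
#' @param signal_name Label for the signal, e.g. `"H3K4me3"` or `"mRNA"`.
#' @param condition Housing condition label, `"GH"` or `"SH"`.
#' @return A `signal_matrix` object: list with `signal_name`, `condition`,
#'   `genes` (character) and `values` (numeric matrix, genes x replicates).
#' @export
read_signal_table <- function(path, signal_name, condition) {
  if (!file.exists(path)) stop("signal table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("signal table needs a gene column plus >= 1 replicate: ", path)
  genes <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric cell in %s at row %d, column '%s'",
                     path, bad[1], names(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  signal_matrix(signal_name, condition, genes, m)
}

#' Construct a signal matrix
#'
#' @param signal_name,condition Labels (see [read_signal_table()]).
#' @param genes Character vector of gene ids, no duplicates.
#' @param values Numeric matrix genes x replicates, finite and non-negative.
#' @return A `signal_matrix` object.
#' @export
signal_matrix <- function(signal_name, condition, genes, values) {
  values <- as.matrix(values)
  if (length(genes) != nrow(values)) stop("gene list / value rows mismatch")
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) stop("duplicate gene id: ", dup[1])
  if (ncol(values) < 1) stop("need at least one replicate column")
  if (any(!is.finite(values))) stop("non-finite value in signal matrix")
  if (any(values < 0)) stop("negative value in signal matrix")
  rownames(values) <- genes
  structure(list(signal_name = signal_name, condition = condition,
                 genes = genes, values = values),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %s / %s: %d genes x %d replicates\n",
              x$signal_name, x$condition, length(x$genes), ncol(x$values)))
  invisible(x)
}

#' Write a signal matrix back to TSV
#'
#' Inverse of [read_signal_table()]; round trips values exactly (full
#' precision via `format(..., digits = 17)`).
#'
#' @param x A `signal_matrix`.
#' @param path Output path.
#' @export
write_signal_table <- function(x, path) {
  stopifnot(inherits(x, "signal_matrix"))
  df <- data.frame(gene = x$genes, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build an expression table from mRNA signal matrices
#'
#' Summarizes per-condition mean expression and within-treatment coefficient
#' of variation, the inputs to the expressed-gene filter and its
#' signal-to-noise diagnostic.
#'
#' @param gh,sh `signal_matrix` objects for mRNA in the two conditions, with
#'   identical gene universes.
#' @return A data.frame with columns `gene`, `tpm_gh`, `tpm_sh`, `cv_gh`,
#'   `cv_sh`. CV is sd/mean per gene within a condition; `NA` when fewer than
#'   2 replicates or mean 0.
#' @export
expression_table <- function(gh, sh) {
  stopifnot(inherits(gh, "signal_matrix"), inherits(sh, "signal_matrix"))
  if (!identical(gh$genes, sh$genes)) {
    if (!setequal(gh$genes, sh$genes)) stop("GH/SH gene universes differ")
    sh_values <- sh$values[match(gh$genes, sh$genes), , drop = FALSE]
  } else sh_values <- sh$values
  cv_of <- function(m) {
    if (ncol(m) < 2) return(rep(NA_real_, nrow(m)))
    mu <- rowMeans(m)
    s <- apply(m, 1, stats::sd)
    ifelse(mu > 0, s / mu, NA_real_)
  }
  data.frame(gene = gh$genes,
             tpm_gh = rowMeans(gh$values),
             tpm_sh = rowMeans(sh_values),
             cv_gh = cv_of(gh$values),
             cv_sh = cv_of(sh_values),
             stringsAsFactors = FALSE)
}

#' Select the expressed gene set (top fraction by mean expression)
#'
#' Keeps the `ceiling(fraction * G)` genes with the highest mean expression.
#' The default ranking statistic is the pooled mean over the two conditions;
#' ties break lexicographically by gene id so the selection is deterministic.
#'
#' @param expr Expression table from [expression_table()].
#' @param fraction Fraction of genes to keep, in (0, 1].
#' @param rank_by `"pooled"` (default), `"gh"` or `"sh"`: which mean ranks.
#' @return Character vector of retained gene ids, in rank order.
#' @export
select_expressed <- function(expr, fraction = 0.4, rank_by = c("pooled", "gh", "sh")) {
  rank_by <- match.arg(rank_by)
  if (nrow(expr) == 0) stop("empty expression table")
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  score <- switch(rank_by,
                  pooled = (expr$tpm_gh + expr$tpm_sh) / 2,
                  gh = expr$tpm_gh,
                  sh = expr$tpm_sh)
  n_keep <- ceiling(fraction * nrow(expr))
  ord <- order(-score, expr$gene)
  expr$gene[ord][seq_len(n_keep)]
}

#' Signal-to-noise report for genes below the expression cutoff
#'
#' Advisory diagnostic backing the expressed-gene filter: among genes below
#' the top-`fraction` cutoff, what share has a within-treatment
#' signal-to-noise ratio (mean/sd, the reciprocal CV) below 1? Low-expressed
#' genes dominated by replicate noise justify excluding them from the
#' landscape clustering. Never alters the filtering itself.
#'
#' @inheritParams select_expressed
#' @return List with `n_below` (genes below cutoff), `n_with_cv` (of those,
#'   genes with a defined CV), `share_snr_below_1` (share of defined-CV genes
#'   with mean/sd < 1 in both conditions' average), `applicable` (FALSE when
#'   the below-cutoff set is empty) and `cv_defined` (FALSE when replicate
#'   counts make CV undefined).
#' @export
signal_to_noise_report <- function(expr, fraction = 0.4, rank_by = "pooled") {
  keep <- select_expressed(expr, fraction, rank_by)
  below <- expr[!(expr$gene %in% keep), , drop = FALSE]
  if (nrow(below) == 0) {
    return(list(n_below = 0L, n_with_cv = 0L, share_snr_below_1 = NA_real_,
                applicable = FALSE, cv_defined = NA))
  }
  cv <- rowMeans(cbind(below$cv_gh, below$cv_sh), na.rm = TRUE)
  cv[is.nan(cv)] <- NA_real_
  if (all(is.na(cv))) {
    return(list(n_below = nrow(below), n_with_cv = 0L,
                share_snr_below_1 = NA_real_, applicable = TRUE,
                cv_defined = FALSE))
  }
  # snr = mean/sd = 1/cv; zero-variance replicates give cv = 0, snr = Inf,
  # counted as >= 1
  snr <- 1 / cv
  ok <- !is.na(snr)
  list(n_below = nrow(below), n_with_cv = sum(ok),
       share_snr_below_1 = mean(snr[ok] < 1),
       applicable = TRUE, cv_defined = TRUE)
}

#' Median-scaling normalizer (optional fallback)
#'
#' Rescales each replicate column so its median over genes matches the global
#' median of column medians. A deliberately simple between-replicate
#' normalizer for inputs that arrive unnormalized; quantification pipelines
#' normally supply already-normalized signals, which should be used as-is.
#'
#' @param x A `signal_matrix`.
#' @return A `signal_matrix` with rescaled columns.
#' @export
normalize_median <- function(x) {
  stopifnot(inherits(x, "signal_matrix"))
  med <- apply(x$values, 2, stats::median)
  if (any(med <= 0)) stop("median scaling undefined: a replicate has median <= 0")
  target <- stats::median(med)
  v <- sweep(x$values, 2, med / target, "/")
  signal_matrix(x$signal_name, x$condition, x$genes, v)
}

#' Build the delta matrix of z-scored GH - SH differences
#'
#' For each signal, the per-gene difference of replicate means (GH - SH) is
#' computed over the expressed gene set, then each signal column is z-scored
#' (mean 0, sample sd 1, ddof = 1). The result is the clustering substrate:
#' rows are expressed genes, columns are the seven signals.
#'
#' @param gh,sh Named lists of `signal_matrix` objects, one per signal, with
#'   identical names and per-signal matching gene universes.
#' @param expressed Character vector of gene ids to keep (subset of every
#'   signal's genes).
#' @return A `delta_matrix` object: list with `genes`, `signals`, and `z`
#'   (genes x signals numeric matrix).
#' @export
make_delta <- function(gh, sh, expressed) {
  if (!identical(sort(names(gh)), sort(names(sh)))) {
    stop("GH and SH signal lists must carry the same signal names")
  }
  signals <- names(gh)
  z <- matrix(NA_real_, nrow = length(expressed), ncol = length(signals),
              dimnames = list(expressed, signals))
  for (s in signals) {
    g <- gh[[s]]; h <- sh[[s]]
    stopifnot(inherits(g, "signal_matrix"), inherits(h, "signal_matrix"))
    if (!all(expressed %in% g$genes) || !all(expressed %in% h$genes)) {
      stop("expressed genes missing from signal ", s)
    }
    dg <- rowMeans(g$values[match(expressed, g$genes), , drop = FALSE])
    dh <- rowMeans(h$values[match(expressed, h$genes), , drop = FALSE])
    d <- dg - dh
    sd_d <- stats::sd(d)
    if (!is.finite(sd_d) || sd_d == 0) {
      stop("signal '", s, "' has zero variance across genes; cannot z-score")
    }
    z[, s] <- (d - mean(d)) / sd_d
  }
  structure(list(genes = expressed, signals = signals, z = z),
            class = "delta_matrix")
}

#' @export
print.delta_matrix <- function(x, ...) {
  cat(sprintf("<delta_matrix> %d genes x %d signals (z-scored GH-SH)\n",
              length(x$genes), length(x$signals)))
  invisible(x)
}

#' Per-gene fold changes between housing conditions
#'
#' @param gh_mean,sh_mean Numeric vectors of per-gene mean expression in the
#'   two conditions (same gene order), non-negative.
#' @param genes Gene ids.
#' @param pseudocount Added to both means before the ratio; default 0.5.
#' @return Data.frame with `gene`, `log2fc` (log2((GH+pc)/(SH+pc))) and
#'   `pct_change` (100 * (max(ratio, 1/ratio) - 1)), the direction-free
#'   percent change used for the TF filter.
#' @export
fold_changes <- function(gh_mean, sh_mean, genes = names(gh_mean),
                         pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(gh_mean < 0) || any(sh_mean < 0)) stop("negative expression value")
  if (length(gh_mean) != length(sh_mean)) stop("length mismatch")
  if (is.null(genes)) genes <- paste0("g", seq_along(gh_mean))
  ratio <- (gh_mean + pseudocount) / (sh_mean + pseudocount)
  data.frame(gene = genes,
             log2fc = log2(ratio),
             pct_change = 100 * (pmax(ratio, 1 / ratio) - 1),
             stringsAsFactors = FALSE)
}
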