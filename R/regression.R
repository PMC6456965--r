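#' Stepwise multilinear regression of fold change on motif counts
#'
#' Ordinary least squares of per-gene log fold change on per-gene motif
#' counts (intercept included), followed by backward elimination: the least
#' significant predictor (largest coefficient p-value) is dropped while any
#' predictor's p reaches the drop gate, and the model is refit. The final
#' model is summarized the way TF-group regression tables are reported: the
#' multiple correlation r (square root of the explained variance fraction),
#' the overall F-test p-value, and a sign per retained predictor — `"+"`/
#' `"-"` for significant coefficients (p < `alpha`), `"(+)"`/`"(-)"` for
#' marginal ones (`alpha <= p < alpha_marginal`).
#'
#' With the default `drop_gate = "alpha"` elimination continues until every
#' retained predictor is significant, so marginal annotations only arise
#' under `drop_gate = "marginal"`, which stops eliminating once all p-values
#' are below `alpha_marginal` and can therefore retain a marginal predictor.
#'
#' @param log_fc Numeric response, one value per gene.
#' @param counts Genes x motifs numeric matrix of predictors (rows aligned
#'   with `log_fc`).
#' @param gene_group Label for the gene set being fit.
#' @param alpha Significance level; default 0.05.
#' @param alpha_marginal Upper edge of the marginal band; default 0.10.
#' @param drop_gate `"alpha"` (default) or `"marginal"`: the p threshold at
#'   which elimination stops.
#' @return A `regression_result`: list with `gene_group`, `n`, `terms`
#'   (data.frame motif, coefficient, t, p, sign), `r`, `r_squared`,
#'   `f_statistic`, `f_p`, `dropped` (motifs removed, in removal order).
#' @export
stepwise_fit <- function(log_fc, counts, gene_group = "genes",
                         alpha = 0.05, alpha_marginal = 0.10,
                         drop_gate = c("alpha", "marginal")) {
  drop_gate <- match.arg(drop_gate)
  gate <- if (drop_gate == "alpha") alpha else alpha_marginal
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("m", seq_len(ncol(counts)))
  }
  n <- length(log_fc)
  if (nrow(counts) != n) stop("response/predictor row mismatch")
  if (n <= ncol(counts) + 2) {
    stop("gene group too small: need > #predictors + 2 observations")
  }
  dropped <- character(0)
  # constant predictors carry no information; perfectly collinear pairs are
  # unresolvable — drop the later-listed one
  keep <- colnames(counts)
  is_const <- apply(counts, 2, function(v) stats::sd(v) == 0)
  if (any(is_const)) {
    warning("dropping constant predictor(s): ",
            paste(keep[is_const], collapse = ", "))
    dropped <- c(dropped, keep[is_const])
    keep <- keep[!is_const]
  }
  if (length(keep) >= 2) {
    cm <- stats::cor(counts[, keep, drop = FALSE])
    for (j in seq_along(keep)) {
      if (is.na(keep[j])) next
      dup <- which(abs(cm[j, ]) > 1 - 1e-12 & seq_along(keep) > j &
                     !is.na(keep))
      if (length(dup) > 0) {
        warning("dropping predictor(s) perfectly collinear with ", keep[j],
                ": ", paste(keep[dup], collapse = ", "))
        dropped <- c(dropped, keep[dup])
        keep[dup] <- NA
      }
    }
    keep <- keep[!is.na(keep)]
  }
  fit_terms <- function(vars) {
    df <- data.frame(.y = log_fc, counts[, vars, drop = FALSE],
                     check.names = FALSE)
    stats::lm(.y ~ ., data = df)
  }
  vars <- keep
  fit <- NULL
  while (length(vars) > 0) {
    fit <- fit_terms(vars)
    coefs <- summary(fit)$coefficients
    pv <- coefs[-1, 4]  # drop intercept
    if (all(pv < gate)) break
    worst <- which.max(pv)
    dropped <- c(dropped, vars[worst])
    vars <- vars[-worst]
    fit <- NULL
  }
  if (length(vars) == 0) {
    return(structure(list(gene_group = gene_group, n = n,
                          terms = data.frame(motif = character(0),
                                             coefficient = numeric(0),
                                             t = numeric(0), p = numeric(0),
                                             sign = character(0)),
                          r = 0, r_squared = 0,
                          f_statistic = NA_real_, f_p = NA_real_,
                          dropped = dropped),
                     class = "regression_result"))
  }
  sm <- summary(fit)
  coefs <- sm$coefficients[-1, , drop = FALSE]
  sign_of <- function(beta, p) {
    if (p < alpha) ifelse(beta > 0, "+", "-")
    else if (p < alpha_marginal) ifelse(beta > 0, "(+)", "(-)")
    else ""
  }
  terms <- data.frame(motif = vars,
                      coefficient = coefs[, 1],
                      t = coefs[, 3],
                      p = coefs[, 4],
                      sign = mapply(sign_of, coefs[, 1], coefs[, 4]),
                      stringsAsFactors = FALSE, row.names = NULL)
  fstat <- sm$fstatistic
  f_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(gene_group = gene_group, n = n, terms = terms,
                 r = sqrt(sm$r.squared), r_squared = sm$r.squared,
                 f_statistic = unname(fstat[1]), f_p = unname(f_p),
                 dropped = dropped),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s (n=%d): r=%.3f, F=%s, p=%s\n",
              x$gene_group, x$n, x$r,
              ifelse(is.na(x$f_statistic), "NA", sprintf("%.2f", x$f_statistic)),
              ifelse(is.na(x$f_p), "NA", format(x$f_p, digits = 3))))
  if (nrow(x$terms) > 0) {
    for (i in seq_len(nrow(x$terms))) {
      cat(sprintf("  %s %s (beta=%.3f, p=%s)\n", x$terms$motif[i],
                  x$terms$sign[i], x$terms$coefficient[i],
                  format(x$terms$p[i], digits = 3)))
    }
  } else cat("  (no predictors retained)\n")
  invisible(x)
}
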