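#' Construct an activity trace
#'
#' One fly's 1-minute activity counts from a beam-break monitor, after any
#' acclimation trimming. Gaps (NA counts) are rejected outright: monitors
#' emit dense data, and imputation would bias bout detection.
#'
#' @param fly_id Identifier.
#' @param genotype Genotype label.
#' @param housing `"GH"` or `"SH"`.
#' @param counts Integer vector of per-minute activity counts; length must be
#'   a multiple of 1440 (whole days).
#' @param lights_on_index 1-based index of the first minute of ZT0 (lights
#'   on) within `counts`.
#' @return An `activity_trace`.
#' @export
activity_trace <- function(fly_id, genotype, housing, counts,
                           lights_on_index = 1L) {
  if (anyNA(counts)) stop("trace ", fly_id, " has gaps (NA counts); rejected")
  if (any(counts < 0)) stop("negative activity count in trace ", fly_id)
  if (length(counts) %% 1440 != 0) {
    stop("trace ", fly_id, " length ", length(counts),
         " is not a whole number of days")
  }
  if (lights_on_index < 1 || lights_on_index > length(counts)) {
    stop("lights_on_index out of range")
  }
  structure(list(fly_id = fly_id, genotype = genotype, housing = housing,
                 counts = as.integer(counts),
                 lights_on_index = as.integer(lights_on_index)),
            class = "activity_trace")
}

#' Score sleep bouts from an activity trace
#'
#' A sleep bout is a maximal run of consecutive zero-count minutes of length
#' >= `min_bout` (default 5, the standard fly sleep criterion). Every minute
#' inside a bout is marked asleep; shorter quiescent runs are awake.
#'
#' @param trace An `activity_trace` (or plain integer count vector).
#' @param min_bout Minimal bout length in minutes; default 5.
#' @return List with `mask` (logical per minute, TRUE = asleep) and `bouts`
#'   (data.frame start, length; 1-based starts).
#' @export
score_sleep <- function(trace, min_bout = 5L) {
  counts <- if (inherits(trace, "activity_trace")) trace$counts else trace
  r <- rle(counts == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_bout <- r$values & r$lengths >= min_bout
  mask <- logical(length(counts))
  for (i in which(is_bout)) mask[starts[i]:ends[i]] <- TRUE
  list(mask = mask,
       bouts = data.frame(start = starts[is_bout],
                          length = r$lengths[is_bout]))
}

#' Daytime sleep minutes
#'
#' Sums asleep minutes over the day window [ZT0, ZT12) of the first scored
#' 24-h window. Bouts spanning the lights-off boundary contribute only their
#' daytime minutes.
#'
#' @param trace An `activity_trace`.
#' @param mask Optional precomputed sleep mask from [score_sleep()].
#' @return Minutes of daytime sleep, in [0, 720].
#' @export
daytime_sleep <- function(trace, mask = NULL) {
  stopifnot(inherits(trace, "activity_trace"))
  if (is.null(mask)) mask <- score_sleep(trace)$mask
  z0 <- trace$lights_on_index
  if (z0 + 1439L > length(trace$counts)) {
    stop("trace does not cover a full 24-h window from lights-on")
  }
  sum(mask[z0:(z0 + 719L)])
}

#' Group sleep summary and delta-sleep
#'
#' Delta-sleep is the social-experience readout: minutes of daytime sleep in
#' group-housed flies minus the same measure in single-housed flies.
#'
#' @param gh,sh Numeric vectors of per-fly daytime sleep minutes.
#' @return A `sleep_summary`: list with per-group `n`, `mean`, `sem`, and
#'   `delta_sleep = mean_gh - mean_sh`.
#' @export
delta_sleep <- function(gh, sh) {
  if (length(gh) == 0 || length(sh) == 0) stop("both groups must be non-empty")
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  structure(list(n_gh = length(gh), n_sh = length(sh),
                 mean_gh = mean(gh), mean_sh = mean(sh),
                 sem_gh = sem(gh), sem_sh = sem(sh),
                 delta_sleep = mean(gh) - mean(sh)),
            class = "sleep_summary")
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat(sprintf(paste0("<sleep_summary> GH %.1f +/- %.1f (n=%d), ",
                     "SH %.1f +/- %.1f (n=%d); delta-sleep %.1f min\n"),
              x$mean_gh, x$sem_gh, x$n_gh, x$mean_sh, x$sem_sh, x$n_sh,
              x$delta_sleep))
  invisible(x)
}

#' Type III interaction ANOVA on per-fly daytime sleep
#'
#' Fits a fixed-effects linear model of per-fly daytime sleep on crossed
#' factors (typically genotype and housing, optionally more) with all
#' interactions, using sum-to-zero contrasts, and computes Type III sums of
#' squares by full-versus-reduced model comparisons: each term's SS is the
#' increase in residual SS when that term's model-matrix columns are removed
#' from the otherwise full model. On balanced designs this coincides with
#' the classical sequential two-way decomposition. The genotype x housing
#' interaction operationalizes "does the knockdown change delta-sleep":
#' delta-sleep itself is a group-level difference with no per-fly
#' replicates, so it cannot be the response directly.
#'
#' A saturated zero-noise fit (residual SS 0) reports F = 0 for zero-SS
#' terms and F = Inf (p = 0) for non-zero ones.
#'
#' @param sleep Numeric per-fly response (daytime sleep minutes).
#' @param factors Data.frame of factor columns, rows aligned with `sleep`.
#' @return A `interaction_anova` data.frame: term, sum_sq, df, f, p, plus a
#'   Residuals row; attribute `total_ss`.
#' @export
interaction_anova <- function(sleep, factors) {
  factors <- as.data.frame(factors)
  if (nrow(factors) != length(sleep)) stop("response/factor row mismatch")
  for (j in seq_along(factors)) factors[[j]] <- factor(factors[[j]])
  cells <- interaction(factors, drop = FALSE)
  tab <- table(cells)
  if (any(tab == 0)) {
    stop("empty design cell: ", names(tab)[which(tab == 0)[1]])
  }
  if (any(tab < 2)) {
    stop("need >= 2 replicates per cell; cell ",
         names(tab)[which(tab < 2)[1]], " has ", min(tab))
  }
  df <- data.frame(.y = sleep, factors)
  form <- stats::as.formula(paste(".y ~", paste(names(factors), collapse = " * ")))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- stats::lm(form, data = df)
  X <- stats::model.matrix(fit)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  rss_full <- sum(stats::residuals(fit)^2)
  df_res <- stats::df.residual(fit)
  ms_res <- rss_full / df_res
  rows <- lapply(seq_along(labels), function(i) {
    cols <- which(asgn == i)
    red <- stats::lm.fit(X[, -cols, drop = FALSE], sleep)
    ss <- sum(red$residuals^2) - rss_full
    ss <- max(ss, 0)
    f <- if (ms_res > 0) (ss / length(cols)) / ms_res
         else if (ss < 1e-10) 0 else Inf
    p <- if (is.finite(f) && ms_res > 0) {
      stats::pf(f, length(cols), df_res, lower.tail = FALSE)
    } else if (f == 0) NA_real_ else 0
    data.frame(term = labels[i], sum_sq = ss, df = length(cols), f = f, p = p,
               stringsAsFactors = FALSE)
  })
  out <- rbind(do.call(rbind, rows),
               data.frame(term = "Residuals", sum_sq = rss_full, df = df_res,
                          f = NA_real_, p = NA_real_))
  rownames(out) <- NULL
  attr(out, "total_ss") <- sum((sleep - mean(sleep))^2)
  class(out) <- c("interaction_anova", class(out))
  out
}

#' Read a beam-break activity monitor file
#'
#' Parses a Trikinetics-style tab-delimited file: no header; columns are
#' reading index, date, time, status, then one activity-count column per
#' channel. Channel metadata (fly id, genotype, housing) comes from a
#' separate CSV with columns `channel, fly_id, genotype, housing`.
#'
#' @param monitor_path Monitor TSV path.
#' @param metadata_path Metadata CSV path.
#' @param lights_on_index 1-based minute index of ZT0 in the retained trace.
#' @param trim_minutes Leading minutes to discard (acclimation); default 0.
#' @return List of `activity_trace`, one per metadata row.
#' @export
read_monitor <- function(monitor_path, metadata_path, lights_on_index = 1L,
                         trim_minutes = 0L) {
  mon <- utils::read.delim(monitor_path, header = FALSE,
                           stringsAsFactors = FALSE)
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("channel", "fly_id", "genotype", "housing")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  n_channels <- ncol(mon) - 4L
  if (any(meta$channel < 1 | meta$channel > n_channels)) {
    stop("metadata channel outside 1..", n_channels)
  }
  lapply(seq_len(nrow(meta)), function(i) {
    counts <- mon[[4L + meta$channel[i]]]
    if (trim_minutes > 0) counts <- counts[-seq_len(trim_minutes)]
    activity_trace(meta$fly_id[i], meta$genotype[i], meta$housing[i],
                   counts, lights_on_index)
  })
}

#' Sleep per 30-minute bin over 24 h
#'
#' Actogram-style export: asleep minutes per half-hour bin across the scored
#' day, averaged over a group of traces.
#'
#' @param traces List of `activity_trace`.
#' @return Data.frame with `bin_start_zt` (hours) and `mean_sleep_min`.
#' @export
sleep_per_30min <- function(traces) {
  per_fly <- vapply(traces, function(tr) {
    mask <- score_sleep(tr)$mask
    z0 <- tr$lights_on_index
    day <- mask[z0:(z0 + 1439L)]
    vapply(seq_len(48), function(b) sum(day[((b - 1) * 30 + 1):(b * 30)]),
           numeric(1))
  }, numeric(48))
  data.frame(bin_start_zt = (seq_len(48) - 1) / 2,
             mean_sleep_min = rowMeans(per_fly))
}
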