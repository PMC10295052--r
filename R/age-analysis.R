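# Downstream statistics: aggregate fitted parameters beats ->
# segments -> recordings, filter age levels by participant count, and
# test each parameter's association with age (Kendall tau, Bonferroni
# x 24).

#' Aggregate fitted parameters to recording level
#'
#' Two-stage unweighted mean of the seconds-basis parameters: beats
#' are averaged within segments, then segment means within recordings
#' (so a recording's value is the mean of its segment means, not the
#' pooled-beat mean). Only non-excluded beats (fitting SNR >= the
#' exclusion threshold) enter; recordings with no surviving beat are
#' dropped with a message.
#'
#' @param fits Data.frame of per-beat fits with columns `beat_id`,
#'   `excluded`, the 24 seconds-basis parameter columns (either
#'   suffixed `_sec` as produced by [batch_extract()], or bare
#'   `param_names()`), and — directly or via `metadata` — `segment_id`,
#'   `recording_id`, `subject`, `age_months`.
#' @param metadata Optional data.frame keyed by `beat_id` supplying the
#'   id columns missing from `fits`.
#' @return Data.frame with one row per recording: `recording_id`,
#'   `subject`, `age_months` and the 24 mean parameter columns (bare
#'   names, seconds basis).
#' @export
aggregate_fits <- function(fits, metadata = NULL) {
  dt <- data.table::as.data.table(fits)
  if (!is.null(metadata)) {
    meta_cols <- setdiff(intersect(
      c("beat_id", "segment_id", "recording_id", "subject", "age_months"),
      names(metadata)), names(dt))
    dt <- merge(dt, data.table::as.data.table(
      metadata)[, c("beat_id", meta_cols), with = FALSE], by = "beat_id")
  }
  need <- c("recording_id", "segment_id", "subject", "age_months",
            "excluded")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("fits are missing columns: ", paste(miss, collapse = ", "))
  pcols <- if (all(paste0(param_names(), "_sec") %in% names(dt)))
    paste0(param_names(), "_sec") else param_names()
  if (!all(pcols %in% names(dt)))
    stop("fits are missing the 24 seconds-basis parameter columns")
  dropped <- dt[, .(all_excluded = all(excluded)), by = "recording_id"]
  if (any(dropped$all_excluded))
    message("dropping ", sum(dropped$all_excluded),
            " recording(s) with no surviving beats")
  dt <- dt[excluded == FALSE]
  seg <- dt[, c(lapply(.SD, mean),
                .(subject = subject[1], age_months = age_months[1])),
            by = c("recording_id", "segment_id"), .SDcols = pcols]
  rec <- seg[, c(lapply(.SD, mean),
                 .(subject = subject[1], age_months = age_months[1])),
             by = "recording_id", .SDcols = pcols]
  out <- as.data.frame(rec)
  names(out)[match(pcols, names(out))] <- param_names()
  out[, c("recording_id", "subject", "age_months", param_names())]
}

#' Filter age levels by participant count
#'
#' Keeps only age levels represented by at least `min_n` distinct
#' participants (default 8), for reliable statistical estimation.
#'
#' @param table Recording-level data.frame with `subject` and
#'   `age_months` columns (see [aggregate_fits()]).
#' @param min_n Minimum distinct participants per age level.
#' @return The filtered data.frame.
#' @export
filter_age_levels <- function(table, min_n = 8) {
  if (nrow(table) == 0) return(table)
  counts <- tapply(table$subject, table$age_months,
                   function(s) length(unique(s)))
  keep_ages <- as.numeric(names(counts)[counts >= min_n])
  table[table$age_months %in% keep_ages, , drop = FALSE]
}

#' Parameter-age correlations with Bonferroni correction
#'
#' Kendall rank correlation (tau-b, which handles the heavy ties from
#' discrete age levels) of each of the 24 parameters against age.
#' p-values are multiplied by `n_tests` (default 24) and capped at 1;
#' a parameter is flagged significant when the corrected p falls below
#' `alpha` (default 0.01). Constant columns yield `NA`.
#'
#' All recordings enter the correlation, including repeated subjects;
#' the repeated-measures independence caveat is the user's to weigh.
#'
#' @param table Recording-level data.frame from [aggregate_fits()]
#'   (optionally after [filter_age_levels()]).
#' @param alpha Significance level on the corrected p-value.
#' @param n_tests Bonferroni multiplicity (24 parameters).
#' @return Data.frame: `parameter`, `tau`, `p_raw`, `p_corrected`,
#'   `significant`.
#' @export
age_correlations <- function(table, alpha = 0.01, n_tests = 24) {
  if (length(unique(table$age_months)) < 2)
    stop("need at least two age levels")
  res <- lapply(param_names(), function(pn) {
    x <- table[[pn]]
    if (is.null(x)) stop("missing parameter column: ", pn)
    if (length(unique(x)) < 2)
      return(data.frame(parameter = pn, tau = NA_real_, p_raw = NA_real_,
                        p_corrected = NA_real_, significant = NA))
    ct <- suppressWarnings(
      stats::cor.test(x, table$age_months, method = "kendall",
                      exact = FALSE))
    p_corr <- min(1, ct$p.value * n_tests)
    data.frame(parameter = pn, tau = unname(ct$estimate),
               p_raw = ct$p.value, p_corrected = p_corr,
               significant = p_corr < alpha)
  })
  do.call(rbind, res)
}
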