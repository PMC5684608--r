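#' Normal intervals of a record set
#'
#' A normal interval runs from the end of one seizure's posthorizon to the
#' beginning of the next seizure's prediction horizon, clipped to recorded
#' coverage. The coverage start acts as a posthorizon end and the coverage
#' end as a horizon start for boundary seizures, so the interval before the
#' first seizure starts at the beginning of coverage.
#'
#' @param seizures policy-applied annotation table on the global clock.
#' @param horizon_s prediction horizon in seconds.
#' @param posthorizon_s posthorizon length in seconds (default 600, equal to
#'   the postictal interval).
#' @param coverage interval matrix of recorded coverage.
#' @return Interval matrix of disjoint normal intervals.
#' @export
normal_intervals <- function(seizures, horizon_s, posthorizon_s = 600, coverage) {
  sz <- seizures[!is.na(seizures$onset_s), , drop = FALSE]
  blocked <- if (nrow(sz)) {
    iv(sz$onset_s - horizon_s, sz$offset_s + posthorizon_s)
  } else {
    iv_empty()
  }
  iv_complement(blocked, coverage)
}

#' False waiting time
#'
#' Each unmerged false alarm opens a waiting window from the alarm to the
#' end of its horizon, clipped to the end of the normal interval containing
#' the alarm. The false waiting time is the length of the union of these
#' windows (overlapping windows are not double-counted, consistent with
#' same-type alarms within one horizon counting as one).
#'
#' @param false_alarms numeric vector of false-alarm times (global seconds).
#' @param horizon_s prediction horizon in seconds.
#' @param normal_iv interval matrix of normal intervals.
#' @return Waiting time in seconds.
#' @export
false_waiting_time <- function(false_alarms, horizon_s, normal_iv) {
  if (!length(false_alarms)) return(0)
  loc <- iv_locate(normal_iv, false_alarms)
  s <- numeric(0); e <- numeric(0)
  for (i in seq_along(false_alarms)) {
    if (is.na(loc[i])) next  # alarm outside any normal interval waits no normal time
    s <- c(s, false_alarms[i])
    e <- c(e, min(false_alarms[i] + horizon_s, normal_iv[loc[i], 2L]))
  }
  iv_length(iv_normalize(iv(s, e)))
}

#' Specificity from false waiting time
#'
#' `spec = 1 - fwt / np`: the fraction of normal time not spent waiting out
#' horizons opened by false alarms.
#'
#' @param fwt false waiting time in seconds.
#' @param np total normal-interval length in seconds.
#' @return Value in `[0, 1]`, or `NA` when `np` is 0 (not applicable).
#' @export
specificity <- function(fwt, np) {
  if (np <= 0) return(NA_real_)
  min(1, max(0, 1 - fwt / np))
}

#' Sensitivity over evaluable seizures
#'
#' A seizure counts as predicted if at least one alarm falls within its
#' prediction horizon `[onset - horizon_s, onset)`. Excluded seizures do not
#' enter the denominator.
#'
#' @param alarms an `alarm_series` from [classify_alarms()], or a numeric
#'   vector of alarm times (then all are treated as candidate positives).
#' @param seizures policy-applied annotation table.
#' @param horizon_s prediction horizon in seconds.
#' @return Fraction of predicted seizures, or `NA` with zero evaluable
#'   seizures.
#' @export
sensitivity <- function(alarms, seizures, horizon_s) {
  tt <- if (inherits(alarms, "alarm_series")) {
    alarms$time[alarms$type == "positive"]
  } else {
    as.numeric(alarms)
  }
  live <- seizures[!seizures$excluded & !is.na(seizures$onset_s), , drop = FALSE]
  if (!nrow(live)) return(NA_real_)
  hit <- vapply(seq_len(nrow(live)), function(k) {
    any(tt >= live$onset_s[k] - horizon_s & tt < live$onset_s[k])
  }, logical(1))
  mean(hit)
}

#' False prediction rate
#'
#' Merged false alarms per evaluated hour.
#'
#' @param n_false number of false alarms after horizon merging.
#' @param hours evaluated duration in hours.
#' @return Alarms per hour, or `NA` when `hours` is 0.
#' @export
fpr <- function(n_false, hours) {
  if (hours <= 0) return(NA_real_)
  n_false / hours
}

#' Prediction times of predicted seizures
#'
#' For each predicted seizure, the time from the earliest positive alarm in
#' its horizon to seizure onset, in minutes.
#'
#' @param alarms an `alarm_series` or numeric vector of positive alarm
#'   times.
#' @param seizures policy-applied annotation table.
#' @param horizon_s prediction horizon in seconds.
#' @return List with `per_seizure` (minutes, one per predicted seizure) and
#'   `mean` (`NA` when nothing was predicted).
#' @export
prediction_time <- function(alarms, seizures, horizon_s) {
  tt <- if (inherits(alarms, "alarm_series")) {
    alarms$time[alarms$type == "positive"]
  } else {
    as.numeric(alarms)
  }
  live <- seizures[!seizures$excluded & !is.na(seizures$onset_s), , drop = FALSE]
  per <- numeric(0)
  for (k in seq_len(nrow(live))) {
    inh <- tt[tt >= live$onset_s[k] - horizon_s & tt < live$onset_s[k]]
    if (length(inh)) per <- c(per, (live$onset_s[k] - min(inh)) / 60)
  }
  list(per_seizure = per, mean = if (length(per)) mean(per) else NA_real_)
}

#' Periodic and Poisson chance predictors
#'
#' The periodic predictor raises an alarm every `period_h` hours from the
#' start of coverage; the Poisson predictor raises alarms at exponentially
#' distributed intervals with mean `period_h` hours (seeded). Alarms landing
#' outside recorded coverage are skipped. The period/mean defaults to the
#' patient's average interictal interval in practice.
#'
#' @param kind `"periodic"` or `"poisson"`.
#' @param period_h fixed period `T` (periodic) or mean `M` (Poisson), in
#'   hours.
#' @param coverage interval matrix of recorded coverage (global seconds).
#' @param seed integer seed (Poisson only).
#' @return Numeric vector of alarm times (global seconds).
#' @export
baseline_alarms <- function(kind = c("periodic", "poisson"), period_h, coverage,
                            seed = 1L) {
  kind <- match.arg(kind)
  if (period_h <= 0) stop("period must be positive", call. = FALSE)
  t0 <- min(coverage[, 1L])
  t1 <- max(coverage[, 2L])
  per_s <- period_h * 3600
  tt <- if (kind == "periodic") {
    seq(t0 + per_s, t1 + 1e-9, by = per_s)
  } else {
    withr::with_seed(seed, {
      draws <- numeric(0)
      cur <- t0
      repeat {
        cur <- cur + stats::rexp(1L, rate = 1 / per_s)
        if (cur > t1) break
        draws <- c(draws, cur)
      }
      draws
    })
  }
  # keep alarms inside coverage (closed at the far end of coverage)
  tt[iv_contains(coverage, tt) | abs(tt - t1) < 1e-9]
}

#' Evaluate an alarm stream against a record set's seizures
#'
#' Computes the full metric set for one predictor on one span of coverage:
#' classifies the alarms, derives normal intervals, false waiting time and
#' specificity, sensitivity over evaluable seizures, merged-false-alarm rate
#' per evaluated hour, and prediction times.
#'
#' @param alarms numeric vector of raw alarm times (global seconds).
#' @param seizures policy-applied annotation table.
#' @param coverage interval matrix of recorded coverage.
#' @param config an [alarm_config()] supplying horizon, postictal,
#'   posthorizon and gap-margin lengths.
#' @param gaps interval matrix of coverage gaps, or `NULL`.
#' @return An object of class `evaluation_result`: list with `sensitivity`,
#'   `specificity`, `fpr`, `mean_prediction_time_min`,
#'   `prediction_times_min`, `fwt_s`, `np_s`, `n_false`, `n_positive`,
#'   `n_discarded`, `evaluated_h`, `alarms` (the classified series).
#' @export
evaluate_alarms <- function(alarms, seizures, coverage, config = alarm_config(),
                            gaps = NULL) {
  cls <- classify_alarms(alarms, seizures, config$horizon_s, gaps = gaps,
                         postictal_s = config$postictal_s,
                         gap_margin_s = config$gap_margin_s)
  niv <- normal_intervals(seizures, config$horizon_s,
                          posthorizon_s = config$posthorizon_s,
                          coverage = coverage)
  falses <- cls$time[cls$type == "false" & !cls$merged]
  fwt <- false_waiting_time(falses, config$horizon_s, niv)
  np <- iv_length(niv)
  hrs <- iv_length(.evaluated_time(seizures, coverage, gaps,
                                   config$postictal_s, config$gap_margin_s)) / 3600
  pt <- prediction_time(cls, seizures, config$horizon_s)
  structure(
    list(sensitivity = sensitivity(cls, seizures, config$horizon_s),
         specificity = specificity(fwt, np),
         fpr = fpr(length(falses), hrs),
         mean_prediction_time_min = pt$mean,
         prediction_times_min = pt$per_seizure,
         fwt_s = fwt, np_s = np,
         n_false = length(falses),
         n_positive = sum(cls$type == "positive" & !cls$merged),
         n_discarded = sum(cls$type == "discarded"),
         evaluated_h = hrs,
         alarms = cls),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_result> sens %.3f | spec %.3f | FPR %.3f/h | ",
                     "pred time %.1f min | fwt %.2f h / np %.2f h\n"),
              x$sensitivity, x$specificity, x$fpr, x$mean_prediction_time_min,
              x$fwt_s / 3600, x$np_s / 3600))
  invisible(x)
}
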