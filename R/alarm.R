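#' Alarm configuration
#'
#' @param alpha fixed run-length threshold (seconds of consecutive preictal
#'   decisions) or `NULL` to select it from training data.
#' @param alpha_grid candidate thresholds for [select_alpha()].
#' @param horizon_s prediction horizon in seconds (3600, 5400 or 7200).
#' @param gap_margin_s margin around coverage gaps whose alarms are
#'   discarded (seconds).
#' @param postictal_s postictal interval length in seconds.
#' @param posthorizon_s post-seizure interval ending a seizure's influence
#'   on normal time (seconds; equal to the postictal interval).
#' @return An object of class `alarm_config`.
#' @export
alarm_config <- function(alpha = NULL,
                         alpha_grid = c(3, 5, 10, 20, 40, 60, 90, 120),
                         horizon_s = 3600, gap_margin_s = 600,
                         postictal_s = 600, posthorizon_s = 600) {
  if (!is.null(alpha) && alpha < 1) stop("alpha must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, alpha_grid = alpha_grid, horizon_s = horizon_s,
                 gap_margin_s = gap_margin_s, postictal_s = postictal_s,
                 posthorizon_s = posthorizon_s),
            class = "alarm_config")
}

#' Raise alarms from a smoothed decision series
#'
#' An alarm fires at the first instant each maximal run of consecutive
#' preictal decisions (1s at 1-second steps) reaches length `alpha`; the run
#' must break (a 0, or a discontinuity in the time axis such as a record
#' boundary) before another alarm can fire. At most one alarm per maximal
#' run.
#'
#' @param series a `binary_series` with 1-second steps.
#' @param alpha positive integer run-length threshold.
#' @return Numeric vector of alarm times (global seconds).
#' @export
raise_alarms <- function(series, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 1 ||
      abs(alpha - round(alpha)) > 1e-9) {
    stop("alpha must be a positive integer", call. = FALSE)
  }
  alpha <- as.integer(round(alpha))
  v <- series$values
  tt <- series$times
  step <- series$step_s
  run <- 0L
  out <- numeric(0)
  for (i in seq_along(v)) {
    contiguous <- i > 1L && abs(tt[i] - tt[i - 1L] - step) < 1e-9
    run <- if (v[i] == 1L) { if (contiguous) run + 1L else 1L } else 0L
    if (run == alpha) out <- c(out, tt[i])
  }
  out
}

#' Classify alarms against seizures, gaps and horizons
#'
#' Assigns each alarm exactly one type:
#' \itemize{
#' \item `discarded` when the alarm falls within `gap_margin_s` of a
#'   coverage-gap boundary (alarms in the 10 minutes before or after a
#'   missing hour are not considered) or inside a seizure's ictal/postictal
#'   interval;
#' \item `positive` when it falls in `[onset - horizon_s, onset)` of a
#'   non-excluded seizure;
#' \item `false` otherwise.
#' }
#' Consecutive alarms of the same type where a later alarm falls inside the
#' horizon window opened by an earlier unmerged one are marked `merged`
#' (counted once).
#'
#' @param alarms sorted numeric vector of alarm times (global seconds).
#' @param seizures policy-applied annotation table on the global clock.
#' @param horizon_s prediction horizon in seconds.
#' @param gaps interval matrix of coverage gaps, or `NULL`.
#' @param postictal_s postictal interval in seconds.
#' @param gap_margin_s discard margin around gaps in seconds.
#' @return An object of class `alarm_series`: data frame with `time`,
#'   `type` (factor positive/false/discarded) and `merged`; attribute
#'   `horizon_s`.
#' @export
classify_alarms <- function(alarms, seizures, horizon_s, gaps = NULL,
                            postictal_s = 600, gap_margin_s = 600) {
  if (is.null(gaps)) gaps <- iv_empty()
  alarms <- sort(as.numeric(alarms))
  sz <- seizures[!is.na(seizures$onset_s), , drop = FALSE]
  live <- sz[!sz$excluded, , drop = FALSE]
  blocked <- if (nrow(sz)) iv(sz$onset_s, sz$offset_s + postictal_s) else iv_empty()
  wide_gaps <- if (nrow(gaps)) iv(gaps[, 1L] - gap_margin_s, gaps[, 2L] + gap_margin_s)
               else iv_empty()
  horizons <- if (nrow(live)) iv(live$onset_s - horizon_s, live$onset_s) else iv_empty()

  type <- rep("false", length(alarms))
  type[iv_contains(horizons, alarms)] <- "positive"
  type[iv_contains(blocked, alarms) | iv_contains(wide_gaps, alarms)] <- "discarded"

  merged <- rep(FALSE, length(alarms))
  for (tp in c("positive", "false")) {
    idx <- which(type == tp)
    open_until <- -Inf
    for (i in idx) {
      if (alarms[i] < open_until) {
        merged[i] <- TRUE
      } else {
        open_until <- alarms[i] + horizon_s
      }
    }
  }
  out <- data.frame(time = alarms,
                    type = factor(type, levels = c("positive", "false", "discarded")),
                    merged = merged)
  attr(out, "horizon_s") <- horizon_s
  class(out) <- c("alarm_series", class(out))
  out
}

#' Select the run-length threshold from training runs
#'
#' Evaluates each candidate `alpha` over a set of training runs (smoothed
#' decision series with their seizures and coverage), and returns the value
#' maximizing training sensitivity, tie-broken by lowest training false
#' prediction rate, then by largest `alpha` (the most conservative
#' threshold). Deterministic.
#'
#' @param runs list of runs; each a list with `series` (a smoothed
#'   `binary_series`), `seizures` (policy-applied, global clock) and
#'   `coverage` (interval matrix).
#' @param horizon_s prediction horizon in seconds.
#' @param alpha_grid non-empty numeric vector of candidate thresholds.
#' @param gaps interval matrix of coverage gaps, or `NULL`.
#' @param postictal_s,gap_margin_s see [classify_alarms()].
#' @return The selected `alpha`.
#' @export
select_alpha <- function(runs, horizon_s,
                         alpha_grid = c(3, 5, 10, 20, 40, 60, 90, 120),
                         gaps = NULL, postictal_s = 600, gap_margin_s = 600) {
  if (!length(alpha_grid)) stop("empty alpha grid", call. = FALSE)
  n_sz <- sum(vapply(runs, function(r)
    sum(!r$seizures$excluded & !is.na(r$seizures$onset_s)), numeric(1)))
  if (n_sz == 0) stop("no training seizure available for alpha selection", call. = FALSE)

  score <- t(vapply(sort(alpha_grid), function(a) {
    pred <- 0; evy <- 0; nf <- 0; hrs <- 0
    for (r in runs) {
      al <- raise_alarms(r$series, a)
      cls <- classify_alarms(al, r$seizures, horizon_s, gaps = gaps,
                             postictal_s = postictal_s, gap_margin_s = gap_margin_s)
      live <- r$seizures[!r$seizures$excluded & !is.na(r$seizures$onset_s), , drop = FALSE]
      for (k in seq_len(nrow(live))) {
        evy <- evy + 1
        hit <- any(cls$type == "positive" &
                     cls$time >= live$onset_s[k] - horizon_s &
                     cls$time < live$onset_s[k])
        if (hit) pred <- pred + 1
      }
      nf <- nf + sum(cls$type == "false" & !cls$merged)
      hrs <- hrs + iv_length(.evaluated_time(r$seizures, r$coverage, gaps,
                                             postictal_s, gap_margin_s)) / 3600
    }
    c(sens = pred / evy, fpr = if (hrs > 0) nf / hrs else 0)
  }, numeric(2)))
  grid <- sort(alpha_grid)
  best <- order(-score[, "sens"], score[, "fpr"], -grid)[1L]
  if (score[best, "sens"] == 0) {
    warning("no alpha predicts any training seizure; keeping the most conservative",
            call. = FALSE)
  }
  grid[best]
}

# time base actually evaluated: coverage minus ictal+postictal minus gap margins
.evaluated_time <- function(seizures, coverage, gaps, postictal_s, gap_margin_s) {
  sz <- seizures[!is.na(seizures$onset_s), , drop = FALSE]
  drop_iv <- if (nrow(sz)) iv(sz$onset_s, sz$offset_s + postictal_s) else iv_empty()
  if (!is.null(gaps) && nrow(gaps)) {
    drop_iv <- rbind(drop_iv, iv(gaps[, 1L] - gap_margin_s, gaps[, 2L] + gap_margin_s))
  }
  iv_complement(iv_normalize(drop_iv), coverage)
}
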