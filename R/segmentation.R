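#' Segmentation configuration
#'
#' Windowing and labeling parameters: a 3-second analysis window slid in
#' 1-second steps (i.e. an overlap of window - 1 seconds), a preictal
#' training interval of 3, 5 or 10 minutes ending `preictal_offset_s`
#' seconds before seizure onset (0, 60 or 120 minutes), a 10-minute
#' postictal interval, and a 10-minute exclusion margin around coverage
#' gaps.
#'
#' @param window_s epoch length in seconds (default 3).
#' @param step_s hop between successive epochs in seconds (default 1).
#' @param preictal_len_s preictal training interval length in seconds.
#' @param preictal_offset_s distance from the end of the preictal interval
#'   to seizure onset, in seconds (0 = interval ends right at onset).
#' @param postictal_s postictal exclusion length in seconds.
#' @param gap_margin_s exclusion margin around coverage gaps in seconds.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(window_s = 3, step_s = 1, preictal_len_s = 180,
                                preictal_offset_s = 0, postictal_s = 600,
                                gap_margin_s = 600) {
  if (step_s <= 0 || step_s > window_s) {
    stop("need 0 < step_s <= window_s", call. = FALSE)
  }
  if (preictal_len_s <= 0) stop("preictal_len_s must be positive", call. = FALSE)
  structure(list(window_s = window_s, step_s = step_s,
                 preictal_len_s = preictal_len_s,
                 preictal_offset_s = preictal_offset_s,
                 postictal_s = postictal_s, gap_margin_s = gap_margin_s),
            class = "segmentation_config")
}

#' Cut a recording into overlapping epochs
#'
#' Frames the recording with a sliding window: epochs start at 0, `step_s`,
#' `2 * step_s`, ... seconds from the recording start; the count is
#' `floor((duration - window_s) / step_s) + 1` and no partial trailing epoch
#' is produced. The return value stores epoch geometry (0-based start
#' samples and global start times) plus a reference to the recording;
#' [epoch_matrix()] materializes individual epochs.
#'
#' @param rec an `eeg_recording`.
#' @param config a [segmentation_config()].
#' @return An object of class `epoch_set` with fields `recording`,
#'   `start_sample` (0-based), `window_n`, `times` (global epoch start
#'   seconds), `record_id`, `config`. Zero epochs (with a warning) if the
#'   recording is shorter than the window.
#' @export
sliding_epochs <- function(rec, config = segmentation_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  win_n <- round(config$window_s * rec$fs)
  step_n <- round(config$step_s * rec$fs)
  n <- ncol(rec$signal)
  if (n < win_n) {
    warning(sprintf("recording '%s' shorter than one window; no epochs",
                    rec$record_id), call. = FALSE)
    starts <- integer(0)
  } else {
    count <- (n - win_n) %/% step_n + 1L
    starts <- (seq_len(count) - 1L) * step_n
  }
  structure(
    list(recording = rec, start_sample = starts, window_n = win_n,
         times = rec$start_time + starts / rec$fs,
         record_id = rec$record_id, config = config),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set '%s'> %d epochs of %d samples (window %gs, step %gs)\n",
              x$record_id, length(x$start_sample), x$window_n,
              x$config$window_s, x$config$step_s))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param es an `epoch_set`.
#' @return Integer count.
#' @export
n_epochs <- function(es) length(es$start_sample)

#' Extract one epoch's data matrix
#'
#' @param es an `epoch_set`.
#' @param i epoch index (1-based).
#' @return Channels-by-samples matrix for epoch `i`.
#' @export
epoch_matrix <- function(es, i) {
  s <- es$start_sample[i]
  es$recording$signal[, (s + 1L):(s + es$window_n), drop = FALSE]
}

#' Label epochs as preictal / interictal / excluded
#'
#' Implements the interval rules used for training and evaluation. An epoch
#' (a half-open window `[t, t + window_s)` on the global clock) is:
#' \itemize{
#' \item excluded with reason `ictal` if it overlaps any seizure
#'   `[onset, offset)`;
#' \item excluded with reason `postictal` if it overlaps any
#'   `[offset, offset + postictal_s)`;
#' \item excluded with reason `gap_margin` if it overlaps a coverage gap
#'   widened by `gap_margin_s` on both sides;
#' \item preictal if it lies entirely within
#'   `[onset - preictal_offset_s - preictal_len_s, onset - preictal_offset_s)`
#'   of a non-excluded seizure;
#' \item interictal otherwise.
#' }
#' Interictal epochs additionally carry `interictal_train = TRUE` only when
#' their source record contains no seizure, because interictal training data
#' is drawn from nonseizure records only; interictal epochs from seizure
#' records still count for testing.
#'
#' @param es an `epoch_set` (or a list of them).
#' @param annotations policy-applied annotation table on the global clock.
#' @param config a [segmentation_config()].
#' @param gaps interval matrix of coverage gaps (global seconds), or `NULL`.
#' @return A data frame with one row per epoch: `record_id`, `time`,
#'   `epoch` (index into its epoch set), `class` (factor preictal /
#'   interictal / excluded), `reason`, `interictal_train`.
#' @export
label_epochs <- function(es, annotations, config = es$config, gaps = NULL) {
  if (inherits(es, "epoch_set")) es <- list(es)
  if (is.null(gaps)) gaps <- iv_empty()
  ann <- annotations
  live <- ann[!ann$excluded & !is.na(ann$onset_s), , drop = FALSE]
  all_sz <- ann[!is.na(ann$onset_s), , drop = FALSE]
  ictal_iv <- if (nrow(all_sz)) iv(all_sz$onset_s, all_sz$offset_s) else iv_empty()
  post_iv <- if (nrow(all_sz)) iv(all_sz$offset_s, all_sz$offset_s + config$postictal_s)
             else iv_empty()
  pre_end <- live$onset_s - config$preictal_offset_s
  pre_iv <- if (nrow(live)) iv(pre_end - config$preictal_len_s, pre_end) else iv_empty()
  wide_gaps <- if (nrow(gaps)) iv(gaps[, 1L] - config$gap_margin_s,
                                  gaps[, 2L] + config$gap_margin_s) else iv_empty()
  sz_records <- unique(ann$record_id)

  out <- lapply(es, function(e) {
    t0 <- e$times
    t1 <- t0 + config$window_s
    cls <- rep("interictal", length(t0))
    reason <- rep("none", length(t0))
    hit_pre <- iv_within_any(t0, t1, pre_iv)
    cls[hit_pre] <- "preictal"
    hit_gap <- iv_overlaps_any(t0, t1, wide_gaps)
    cls[hit_gap] <- "excluded"; reason[hit_gap] <- "gap_margin"
    hit_post <- iv_overlaps_any(t0, t1, post_iv)
    cls[hit_post] <- "excluded"; reason[hit_post] <- "postictal"
    hit_ict <- iv_overlaps_any(t0, t1, ictal_iv)
    cls[hit_ict] <- "excluded"; reason[hit_ict] <- "ictal"
    data.frame(record_id = e$record_id, time = t0, epoch = seq_along(t0),
               class = cls, reason = reason,
               interictal_train = cls == "interictal" &
                 !(e$record_id %in% sz_records),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$class <- factor(out$class, levels = c("preictal", "interictal", "excluded"))
  out$reason[out$class != "excluded"] <- "none"
  rownames(out) <- NULL
  out
}
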