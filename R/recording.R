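#' Multichannel EEG recording
#'
#' Container for one continuous multichannel recording: a channels-by-samples
#' signal matrix (microvolts), its sampling rate, ordered channel labels, the
#' recording's start time on the patient's global clock, and an identifier.
#' Epochs, covariances and spatial filters all inherit the channel order of
#' this object.
#'
#' @param signal numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector of channel names, one per row.
#'   Duplicate labels are made unique with a warning.
#' @param start_time start of the recording in seconds on the patient's
#'   global clock.
#' @param record_id identifier string.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(signal, fs, channel_labels = rownames(signal),
                      start_time = 0, record_id = "rec") {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  if (nrow(signal) < 2L) {
    stop("a recording needs at least 2 channels", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("CH", seq_len(nrow(signal)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(signal)) {
    stop("`channel_labels` must match the number of signal rows", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    warning("duplicate channel labels made unique", call. = FALSE)
    channel_labels <- make.unique(channel_labels, sep = "_")
  }
  rownames(signal) <- channel_labels
  structure(
    list(signal = signal, fs = fs, channel_labels = channel_labels,
         start_time = as.numeric(start_time), record_id = as.character(record_id)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording '%s'> %d ch x %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              rec_duration(x), x$start_time))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param x an `eeg_recording`.
#' @return Duration in seconds.
#' @export
rec_duration <- function(x) ncol(x$signal) / x$fs

rec_interval <- function(x) iv(x$start_time, x$start_time + rec_duration(x))

#' Seizure annotation table
#'
#' Builds the annotation table used throughout the package: one row per
#' seizure with onset/offset in seconds, plus bookkeeping flags set by
#' [apply_seizure_policy()] (`merged` when a seizure has absorbed a
#' follower that began in its postictal interval, `excluded` with a
#' `reason` when a seizure cannot be used for training/evaluation).
#'
#' @param record_id character vector of record identifiers.
#' @param onset_s,offset_s seizure onset/offset in seconds (same clock as the
#'   record they annotate; [record_set()] converts record-local times to the
#'   global clock).
#' @return A data frame with columns `record_id`, `onset_s`, `offset_s`,
#'   `merged`, `excluded`, `reason`.
#' @export
seizure_annotations <- function(record_id = character(0), onset_s = numeric(0),
                                offset_s = numeric(0)) {
  record_id <- as.character(record_id)
  onset_s <- as.numeric(onset_s)
  offset_s <- as.numeric(offset_s)
  if (length(onset_s) != length(offset_s) || length(onset_s) != length(record_id)) {
    stop("record_id, onset_s, offset_s must have equal length", call. = FALSE)
  }
  if (any(onset_s < 0) || any(offset_s <= onset_s)) {
    stop("need 0 <= onset_s < offset_s for every seizure", call. = FALSE)
  }
  data.frame(record_id = record_id, onset_s = onset_s, offset_s = offset_s,
             merged = logical(length(onset_s)),
             excluded = logical(length(onset_s)),
             reason = rep(NA_character_, length(onset_s)),
             stringsAsFactors = FALSE)
}

#' Assemble recordings and annotations on a shared global clock
#'
#' Places a patient's recordings on one global timeline (using each
#' recording's `start_time`), derives coverage gaps as the complement of the
#' recorded time, harmonizes channels across recordings, and converts
#' record-local seizure annotations to global seconds. Gaps matter because
#' alarms close to a gap ("missing hour") boundary are discarded during
#' evaluation.
#'
#' @param recordings list of [recording()] objects with non-overlapping
#'   global time spans.
#' @param annotations annotation table from [seizure_annotations()] with
#'   record-local `onset_s`/`offset_s`; converted to global time here.
#'   Annotations naming an unknown record are kept with a warning (their
#'   global times are `NA`).
#' @param patient_id identifier for the patient.
#' @return An object of class `record_set` with elements `recordings`
#'   (named by record id), `annotations` (global-clock table), `coverage`
#'   and `gaps` (interval matrices), `patient_id`.
#' @export
record_set <- function(recordings, annotations = seizure_annotations(),
                       patient_id = "patient") {
  if (!length(recordings)) stop("empty recording list", call. = FALSE)
  if (!all(vapply(recordings, inherits, logical(1), "eeg_recording"))) {
    stop("all elements must be eeg_recording objects", call. = FALSE)
  }
  ids <- vapply(recordings, `[[`, character(1), "record_id")
  if (anyDuplicated(ids)) stop("duplicate record ids", call. = FALSE)
  names(recordings) <- ids

  # channel harmonization: every recording must carry the first recording's
  # channel set; extras are dropped (warning), missing channels are an error
  ref <- recordings[[1L]]$channel_labels
  recordings <- lapply(recordings, function(r) {
    miss <- setdiff(ref, r$channel_labels)
    if (length(miss)) {
      stop(sprintf("record '%s' is missing channels: %s", r$record_id,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    extra <- setdiff(r$channel_labels, ref)
    if (length(extra)) {
      warning(sprintf("record '%s': dropping extra channels %s", r$record_id,
                      paste(extra, collapse = ", ")), call. = FALSE)
      r$signal <- r$signal[ref, , drop = FALSE]
      r$channel_labels <- ref
    }
    r
  })

  spans <- do.call(rbind, lapply(recordings, rec_interval))
  ord <- order(spans[, 1L])
  spans <- spans[ord, , drop = FALSE]
  recordings <- recordings[ord]
  if (nrow(spans) > 1L && any(spans[-1L, 1L] < spans[-nrow(spans), 2L] - 1e-9)) {
    stop("recordings overlap in global time", call. = FALSE)
  }
  coverage <- iv_normalize(spans)
  gaps <- iv_complement(coverage, iv(min(coverage[, 1L]), max(coverage[, 2L])))

  ann <- annotations
  if (nrow(ann)) {
    starts <- vapply(recordings, `[[`, numeric(1), "start_time")
    known <- ann$record_id %in% names(recordings)
    if (any(!known)) {
      warning(sprintf("annotations reference unknown records: %s",
                      paste(unique(ann$record_id[!known]), collapse = ", ")),
              call. = FALSE)
    }
    ann$onset_rec <- ann$onset_s
    ann$offset_rec <- ann$offset_s
    ann$onset_s <- ifelse(known, starts[ann$record_id] + ann$onset_rec, NA_real_)
    ann$offset_s <- ifelse(known, starts[ann$record_id] + ann$offset_rec, NA_real_)
    durs <- vapply(recordings, rec_duration, numeric(1))
    bad <- known & ann$offset_rec > durs[ann$record_id] + 1e-9
    if (any(bad)) stop("seizure offset beyond record duration", call. = FALSE)
    ann <- ann[order(ann$onset_s), , drop = FALSE]
  }

  structure(
    list(patient_id = patient_id, recordings = recordings, annotations = ann,
         coverage = coverage, gaps = gaps),
    class = "record_set"
  )
}

#' @export
print.record_set <- function(x, ...) {
  cat(sprintf("<record_set '%s'> %d recordings, %.2f h covered, %d gaps, %d seizures\n",
              x$patient_id, length(x$recordings), iv_length(x$coverage) / 3600,
              nrow(x$gaps), nrow(x$annotations)))
  invisible(x)
}

#' Coverage gaps of a record set
#' @param x a `record_set`.
#' @return Two-column matrix of `[start, end)` gap intervals (global seconds).
#' @export
coverage_gaps <- function(x) x$gaps

#' Merge and exclude seizures according to the evaluation policy
#'
#' Applies two rules used when preparing annotations: (i) a seizure whose
#' onset falls within `postictal_len` seconds after the previous seizure's
#' offset is merged into the previous one (combined onset = first onset,
#' offset = later offset, `merged` flag set); chains are absorbed
#' iteratively. (ii) a seizure with less than `min_preictal` seconds of
#' recorded data before its onset is flagged `excluded` — it cannot supply a
#' full preictal training interval.
#'
#' The operation is idempotent: applying it twice gives the same table.
#'
#' @param annotations annotation table sorted by onset, times on one common
#'   clock (global seconds for a `record_set`).
#' @param postictal_len postictal interval length in seconds (default 600).
#' @param min_preictal required recorded preictal time in seconds.
#' @param coverage optional interval matrix of recorded coverage on the same
#'   clock; when `NULL`, continuous coverage from time 0 is assumed.
#' @return Annotation table with merges applied and exclusion flags set.
#' @export
apply_seizure_policy <- function(annotations, postictal_len = 600,
                                 min_preictal = 180, coverage = NULL) {
  ann <- annotations
  if (!nrow(ann)) return(ann)
  if (is.unsorted(ann$onset_s)) ann <- ann[order(ann$onset_s), , drop = FALSE]
  keep <- rep(TRUE, nrow(ann))
  i <- 1L
  for (j in seq_len(nrow(ann))[-1L]) {
    if (ann$onset_s[j] <= ann$offset_s[i] + postictal_len) {
      ann$offset_s[i] <- max(ann$offset_s[i], ann$offset_s[j])
      if ("offset_rec" %in% names(ann)) ann$offset_rec[i] <- NA_real_
      ann$merged[i] <- TRUE
      keep[j] <- FALSE
    } else {
      i <- j
    }
  }
  ann <- ann[keep, , drop = FALSE]

  if (is.null(coverage)) coverage <- iv(0, Inf)
  pre_start <- ann$onset_s - min_preictal
  for (k in seq_len(nrow(ann))) {
    covered <- iv_length(iv_intersect(coverage, iv(pre_start[k], ann$onset_s[k])))
    if (covered < min_preictal - 1e-9) {
      ann$excluded[k] <- TRUE
      ann$reason[k] <- "insufficient_preictal"
      message(sprintf("seizure at %gs excluded: only %gs of the required %gs preictal coverage",
                      ann$onset_s[k], covered, min_preictal))
    }
  }
  rownames(ann) <- NULL
  ann
}
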