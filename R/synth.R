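#' Random interictal/preictal covariance pair
#'
#' Constructs a pair of symmetric positive-definite spatial covariance
#' matrices sharing one random orthogonal eigenbasis, with log-spaced
#' baseline eigenvalues. The preictal eigenvalues are the interictal ones
#' multiplied by `exp(separation * d_k)` with `d_k` spread evenly over
#' `[-1, 1]`, so the generalized eigenvalues of
#' `(preictal, preictal + interictal)` are `plogis(separation * d_k)`:
#' their spread around 1/2 grows monotonically with `separation`, and
#' `separation = 0` gives two identical matrices. This mimics the
#' second-order contrast between brain states that CSP exploits, without
#' pretending to model EEG rhythms.
#'
#' @param n_channels number of channels (>= 2).
#' @param separation nonnegative scalar controlling the spectral divergence
#'   of the pair; 0 means indistinguishable states.
#' @param seed integer seed; the construction is deterministic given it.
#' @return An object of class `state_cov_spec` with fields `n_channels`,
#'   `interictal_cov`, `preictal_cov`, `separation`, `basis`,
#'   `interictal_eig`, `preictal_eig`.
#' @export
make_state_covariances <- function(n_channels, separation, seed = 1L) {
  if (!is.numeric(n_channels) || n_channels < 2) {
    stop("`n_channels` must be >= 2", call. = FALSE)
  }
  if (separation < 0) stop("`separation` must be >= 0", call. = FALSE)
  n_channels <- as.integer(n_channels)
  Q <- withr::with_seed(seed, {
    A <- matrix(stats::rnorm(n_channels^2), n_channels)
    qr.Q(qr(A))
  })
  lam <- 10^seq(log10(0.5), log10(5), length.out = n_channels)
  d <- seq(-1, 1, length.out = n_channels)
  lam_pre <- lam * exp(separation * d)
  sym <- function(M) (M + t(M)) / 2
  structure(
    list(n_channels = n_channels,
         interictal_cov = sym(Q %*% diag(lam, n_channels) %*% t(Q)),
         preictal_cov = if (separation == 0) sym(Q %*% diag(lam, n_channels) %*% t(Q))
                        else sym(Q %*% diag(lam_pre, n_channels) %*% t(Q)),
         separation = separation, basis = Q,
         interictal_eig = lam, preictal_eig = lam_pre),
    class = "state_cov_spec"
  )
}

#' Timeline specification for synthetic recordings
#'
#' Describes the seizure structure of a synthetic record: total duration,
#' seizure onsets and durations, the preictal window length placed
#' immediately before each onset, optional coverage gaps ("missing hours"),
#' sampling rate and seed.
#'
#' @param duration_s total timeline duration in seconds.
#' @param seizure_onsets global onset times in seconds (sorted, within the
#'   timeline, non-overlapping).
#' @param seizure_durations seizure lengths in seconds (recycled).
#' @param preictal_len_s length of the covariance-shifted preictal window
#'   before each onset (seconds).
#' @param gaps optional two-column matrix of `[start, end)` gap intervals.
#' @param fs sampling rate in Hz.
#' @param seed integer seed driving all signal randomness.
#' @return An object of class `timeline_spec`.
#' @export
timeline_spec <- function(duration_s, seizure_onsets = numeric(0),
                          seizure_durations = 40, preictal_len_s = 180,
                          gaps = NULL, fs = 256, seed = 1L) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  ons <- sort(as.numeric(seizure_onsets))
  durs <- rep_len(as.numeric(seizure_durations), length(ons))
  offs <- ons + durs
  if (length(ons)) {
    if (any(ons < 0) || any(offs > duration_s)) {
      stop("seizures must lie within the timeline", call. = FALSE)
    }
    if (length(ons) > 1L && any(ons[-1L] < offs[-length(offs)])) {
      stop("seizures overlap", call. = FALSE)
    }
  }
  if (!is.null(gaps)) {
    gaps <- iv_normalize(gaps)
    if (nrow(gaps) && (min(gaps[, 1L]) < 0 || max(gaps[, 2L]) > duration_s)) {
      stop("gaps must lie within the timeline", call. = FALSE)
    }
  } else {
    gaps <- iv_empty()
  }
  structure(
    list(duration_s = duration_s, seizure_onsets = ons, seizure_durations = durs,
         preictal_len_s = preictal_len_s, gaps = gaps, fs = fs,
         seed = as.integer(seed)),
    class = "timeline_spec"
  )
}

# state intervals of a timeline on the global clock
.timeline_states <- function(timeline) {
  ict <- iv(timeline$seizure_onsets,
            timeline$seizure_onsets + timeline$seizure_durations)
  pre <- iv(pmax(0, timeline$seizure_onsets - timeline$preictal_len_s),
            timeline$seizure_onsets)
  list(ictal = ict, preictal = pre)
}

# draw a zero-mean segment with covariance C (n x len)
.draw_segment <- function(Lchol, len) {
  t(Lchol) %*% matrix(stats::rnorm(nrow(Lchol) * len), nrow(Lchol), len)
}

#' Simulate one contiguous multichannel recording
#'
#' Samples a stationary zero-mean multichannel Gaussian signal whose spatial
#' covariance is `spec$interictal_cov` outside preictal windows,
#' `spec$preictal_cov` within `[onset - preictal_len, onset)`, and the
#' preictal covariance scaled by a 5x burst factor during seizures (ictal
#' content is excluded from training and evaluation; it only has to exist).
#' Generation is fully determined by `timeline$seed`.
#'
#' @param timeline a [timeline_spec()] without gaps (use
#'   [simulate_record_set()] for gapped timelines).
#' @param spec a [make_state_covariances()] object with matching channel
#'   count.
#' @return A list with `recording` (an `eeg_recording` starting at global
#'   time 0) and `annotations` (a [seizure_annotations()] table).
#' @export
simulate_recording <- function(timeline, spec) {
  if (nrow(timeline$gaps)) {
    stop("timeline has gaps; use simulate_record_set()", call. = FALSE)
  }
  rec <- .simulate_span(timeline, spec, span = c(0, timeline$duration_s),
                        seed = timeline$seed, record_id = "synthetic")
  ann <- seizure_annotations(rep("synthetic", length(timeline$seizure_onsets)),
                             timeline$seizure_onsets,
                             timeline$seizure_onsets + timeline$seizure_durations)
  list(recording = rec, annotations = ann)
}

# simulate the covered span [a, b) of a timeline as one recording
.simulate_span <- function(timeline, spec, span, seed, record_id) {
  if (spec$n_channels < 2) stop("need >= 2 channels", call. = FALSE)
  st <- .timeline_states(timeline)
  ons <- timeline$seizure_onsets
  if (length(ons) > 1L) {
    prev_off <- (ons + timeline$seizure_durations)[-length(ons)]
    if (any(ons[-1L] - timeline$preictal_len_s < prev_off)) {
      stop("preictal window overlaps the previous seizure; respace the timeline",
           call. = FALSE)
    }
  }
  fs <- timeline$fs
  n_samp <- round((span[2L] - span[1L]) * fs)
  # per-sample state id: 0 interictal, 1 preictal, 2 ictal
  t0 <- span[1L] + (seq_len(n_samp) - 1L) / fs
  state <- integer(n_samp)
  state[iv_contains(st$preictal, t0)] <- 1L
  state[iv_contains(st$ictal, t0)] <- 2L

  Li <- chol(spec$interictal_cov)
  Lp <- chol(spec$preictal_cov)
  Lb <- sqrt(5) * Lp
  sig <- matrix(0, spec$n_channels, n_samp)
  withr::with_seed(seed, {
    r <- rle(state)
    pos <- 1L
    for (k in seq_along(r$lengths)) {
      len <- r$lengths[k]
      Lc <- switch(r$values[k] + 1L, Li, Lp, Lb)
      sig[, pos:(pos + len - 1L)] <- .draw_segment(Lc, len)
      pos <- pos + len
    }
  })
  recording(sig, fs = fs, start_time = span[1L], record_id = record_id)
}

#' Simulate a full record set on a gapped timeline
#'
#' Splits the covered portion of the timeline (its complement of `gaps`)
#' into consecutive recordings of at most `record_len_s` seconds, simulates
#' each with a seed derived deterministically from `timeline$seed` and the
#' record index, and assembles a [record_set()] with global-clock seizure
#' annotations. Seizures must not straddle a record or gap boundary.
#'
#' @param timeline a [timeline_spec()].
#' @param spec a [make_state_covariances()] object.
#' @param record_len_s maximum recording length in seconds (default 600).
#' @param patient_id identifier for the synthetic patient.
#' @return A `record_set`.
#' @export
simulate_record_set <- function(timeline, spec, record_len_s = 600,
                                patient_id = "synthetic") {
  covered <- iv_complement(timeline$gaps, iv(0, timeline$duration_s))
  spans <- iv_empty()
  for (i in seq_len(nrow(covered))) {
    cuts <- seq(covered[i, 1L], covered[i, 2L], by = record_len_s)
    if (cuts[length(cuts)] < covered[i, 2L]) cuts <- c(cuts, covered[i, 2L])
    spans <- rbind(spans, iv(cuts[-length(cuts)], cuts[-1L]))
  }
  ict <- iv(timeline$seizure_onsets,
            timeline$seizure_onsets + timeline$seizure_durations)
  for (k in seq_len(nrow(ict))) {
    row <- iv_locate(spans, ict[k, 1L])
    if (is.na(row) || ict[k, 2L] > spans[row, 2L] + 1e-9) {
      stop("a seizure straddles a record or gap boundary; adjust the timeline",
           call. = FALSE)
    }
  }
  recs <- lapply(seq_len(nrow(spans)), function(i) {
    .simulate_span(timeline, spec, spans[i, ],
                   seed = timeline$seed + i * 10007L,
                   record_id = sprintf("%s_%02d", patient_id, i))
  })
  rid <- character(0); on_rec <- numeric(0); off_rec <- numeric(0)
  for (k in seq_len(nrow(ict))) {
    row <- iv_locate(spans, ict[k, 1L])
    rid <- c(rid, recs[[row]]$record_id)
    on_rec <- c(on_rec, ict[k, 1L] - spans[row, 1L])
    off_rec <- c(off_rec, ict[k, 2L] - spans[row, 1L])
  }
  record_set(recs, seizure_annotations(rid, on_rec, off_rec),
             patient_id = patient_id)
}
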