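# Minimal EDF (European Data Format) I/O.
#
# EDF stores a 256-byte ASCII header, one 256-byte ASCII sub-header per
# signal, then fixed-duration data records of little-endian 16-bit integers,
# signal by signal. Reading maps digital values back to physical units with
# the per-signal calibration in the header. The writer exists to produce
# synthetic fixtures; it is not intended for clinical data export.

.edf_field <- function(raw_hdr, at, len) {
  trimws(rawToChar(raw_hdr[(at + 1L):(at + len)]))
}

.edf_num <- function(raw_hdr, at, len, what) {
  txt <- .edf_field(raw_hdr, at, len)
  val <- suppressWarnings(as.numeric(txt))
  if (is.na(val)) {
    stop(sprintf("malformed EDF header: field '%s' is not numeric ('%s')", what, txt),
         call. = FALSE)
  }
  val
}

#' Read an EDF recording
#'
#' Parses an EDF file into an [recording()] object in physical units
#' (microvolts for EEG channels), preserving the stored channel order.
#' All signals must share one sampling rate; files with inconsistent
#' per-channel sample counts are rejected, as are truncated files and
#' headers with non-numeric control fields. Duplicate channel labels are
#' made unique with a warning.
#'
#' @param path path to an EDF file.
#' @param start_time global start time (seconds) to assign to the recording.
#' @param record_id identifier; defaults to the file name without extension.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, start_time = 0,
                     record_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  sz <- file.info(path)$size
  if (sz < 256) stop("malformed EDF header: file shorter than 256 bytes", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)

  n_rec <- .edf_num(hdr, 236L, 8L, "number of data records")
  rec_dur <- .edf_num(hdr, 244L, 8L, "duration of a data record")
  ns <- .edf_num(hdr, 252L, 4L, "number of signals")
  if (ns < 1 || ns != round(ns)) {
    stop("malformed EDF header: invalid number of signals", call. = FALSE)
  }
  ns <- as.integer(ns)
  if (sz < 256 + 256 * ns) {
    stop("truncated EDF file: signal headers incomplete", call. = FALSE)
  }
  shdr <- readBin(con, "raw", 256L * ns)
  fld <- function(off, len, i) {
    .edf_field(shdr, off * ns + (i - 1L) * len, len)
  }
  labels <- vapply(seq_len(ns), function(i) fld(0L, 16L, i), character(1))
  phys_min <- vapply(seq_len(ns), function(i)
    .edf_num(shdr, 104L * ns + (i - 1L) * 8L, 8L, "physical minimum"), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i)
    .edf_num(shdr, 112L * ns + (i - 1L) * 8L, 8L, "physical maximum"), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i)
    .edf_num(shdr, 120L * ns + (i - 1L) * 8L, 8L, "digital minimum"), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i)
    .edf_num(shdr, 128L * ns + (i - 1L) * 8L, 8L, "digital maximum"), numeric(1))
  spr <- vapply(seq_len(ns), function(i)
    .edf_num(shdr, 216L * ns + (i - 1L) * 8L, 8L, "samples per record"), numeric(1))
  if (length(unique(spr)) != 1L) {
    stop("inconsistent per-channel sample counts across signals", call. = FALSE)
  }
  spr <- as.integer(spr[1L])
  if (rec_dur <= 0 || spr <= 0) {
    stop("malformed EDF header: non-positive record duration or samples per record",
         call. = FALSE)
  }
  fs <- spr / rec_dur

  expected <- 256 + 256 * ns + n_rec * ns * spr * 2
  if (sz < expected) {
    stop(sprintf("truncated EDF file: expected %d bytes, found %d", expected, sz),
         call. = FALSE)
  }

  sig <- matrix(0, nrow = ns, ncol = n_rec * spr)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr, size = 2L, signed = TRUE,
                     endian = "little")
    sig[, ((r - 1L) * spr + 1L):(r * spr)] <-
      matrix(block, nrow = spr, ncol = ns)[, , drop = FALSE] |> t()
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- sig * scale + (phys_min - dig_min * scale)
  recording(sig, fs = fs, channel_labels = labels, start_time = start_time,
            record_id = record_id)
}

#' Write a recording as an EDF file
#'
#' Writes a 16-bit EDF file with one-second data records; intended for
#' building synthetic fixtures. The signal duration must be a whole number
#' of seconds (an EDF file holds complete records only). Quantization to 16
#' bits limits the round trip to about `(max - min)/65535` per channel.
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- nrow(rec$signal)
  L <- ncol(rec$signal)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  if (L %% fs != 0L) {
    stop("signal length must be a whole number of seconds for EDF records", call. = FALSE)
  }
  n_rec <- L %/% fs

  phys_min <- apply(rec$signal, 1L, min)
  phys_max <- apply(rec$signal, 1L, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768
  dig_max <- 32767
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round(sweep(sweep(rec$signal, 1L, phys_min), 1L, scale, "/") + dig_min)
  storage.mode(dig) <- "integer"

  pad <- function(x, w) formatC(substr(as.character(x), 1L, w), width = -w)
  num <- function(x, w) pad(formatC(x, digits = 7, format = "g"), w)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8L), pad("X X X X", 80L), pad(paste("Startdate 01-JAN-2000", rec$record_id), 80L),
    pad("01.01.00", 8L), pad("00.00.00", 8L), pad(256 * (1 + n), 8L),
    pad("", 44L), pad(n_rec, 8L), pad("1", 8L), pad(n, 4L)
  ), con, eos = NULL)
  wall <- function(vals, w) writeChar(paste0(vapply(vals, pad, character(1), w = w),
                                             collapse = ""), con, eos = NULL)
  wall(rec$channel_labels, 16L)
  wall(rep("", n), 80L)                       # transducer
  wall(rep("uV", n), 8L)                      # physical dimension
  wall(num(phys_min, 8L), 8L)
  wall(num(phys_max, 8L), 8L)
  wall(rep(dig_min, n), 8L)
  wall(rep(dig_max, n), 8L)
  wall(rep("", n), 80L)                       # prefiltering
  wall(rep(fs, n), 8L)                        # samples per record
  wall(rep("", n), 32L)
  for (r in seq_len(n_rec)) {
    block <- t(dig[, ((r - 1L) * fs + 1L):(r * fs), drop = FALSE])
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read CHB-MIT-style seizure annotation summaries
#'
#' Parses the plain-text per-patient summary dialect used by the CHB-MIT
#' corpus: blocks introduced by `File Name:` lines, each declaring
#' `Number of Seizures in File:` and pairs of `Seizure [k ]Start Time:` /
#' `Seizure [k ]End Time:` lines with values in seconds from the start of
#' that record.
#'
#' @param path path to the summary text file.
#' @return A [seizure_annotations()] table with record-local times;
#'   `record_id` is the declared file name without its extension.
#' @export
read_chb_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  file_idx <- grep("^\\s*File Name\\s*:", lines)
  rid <- character(0); on <- numeric(0); off <- numeric(0)
  bounds <- c(file_idx, length(lines) + 1L)
  for (b in seq_along(file_idx)) {
    block <- lines[bounds[b]:(bounds[b + 1L] - 1L)]
    fname <- trimws(sub("^\\s*File Name\\s*:", "", block[1L]))
    stem <- sub("\\.[^.]*$", "", fname)
    starts <- grep("^\\s*Seizure( \\d+)? Start Time\\s*:", block, value = TRUE)
    ends <- grep("^\\s*Seizure( \\d+)? End Time\\s*:", block, value = TRUE)
    if (length(starts) != length(ends)) {
      stop(sprintf("record '%s': %d start times but %d end times", stem,
                   length(starts), length(ends)), call. = FALSE)
    }
    secs <- function(x) as.numeric(gsub("[^0-9.]", "", sub(".*:", "", x)))
    s <- secs(starts); e <- secs(ends)
    if (any(is.na(s)) || any(is.na(e))) {
      stop(sprintf("record '%s': unparseable seizure time", stem), call. = FALSE)
    }
    if (any(s >= e)) {
      stop(sprintf("record '%s': seizure onset at or after offset", stem), call. = FALSE)
    }
    rid <- c(rid, rep(stem, length(s))); on <- c(on, s); off <- c(off, e)
  }
  seizure_annotations(rid, on, off)
}
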