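# Portable fixture container: a single-file, versioned bundle holding either
# one recording plus its annotation table, or a whole record set. Round trips
# are lossless to float precision (unlike 16-bit EDF), which makes this the
# interchange format for synthetic data, cached models and CLI artifacts.

.fixture_version <- c(1L, 0L)  # major, minor

#' Write a fixture file
#'
#' @param x an `eeg_recording`, a `record_set`, or any serializable object
#'   (e.g. a fitted model) to bundle.
#' @param path output path.
#' @param annotations annotation table to bundle with a single recording;
#'   ignored for record sets (they carry their own).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(x, path, annotations = seizure_annotations()) {
  kind <- if (inherits(x, "eeg_recording")) "recording"
          else if (inherits(x, "record_set")) "record_set"
          else "object"
  obj <- list(format = "cspseizure-fixture", version = .fixture_version,
              kind = kind, payload = x,
              annotations = if (kind == "recording") annotations else NULL)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a fixture file
#'
#' Rejects files that are not fixture containers or that were written by a
#' newer major version of the format.
#'
#' @param path path to a fixture written by [write_fixture()].
#' @return For `kind = "recording"`: a list with `recording` and
#'   `annotations`. For other kinds: the stored object.
#' @export
read_fixture <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("not a readable fixture file: %s", path), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "cspseizure-fixture")) {
    stop("format error: not a cspseizure fixture container", call. = FALSE)
  }
  if (obj$version[1L] > .fixture_version[1L]) {
    stop(sprintf("fixture written by newer major version %d (supported: %d)",
                 obj$version[1L], .fixture_version[1L]), call. = FALSE)
  }
  if (identical(obj$kind, "recording")) {
    list(recording = obj$payload, annotations = obj$annotations)
  } else {
    obj$payload
  }
}
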