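test_that("EDF round trip preserves dimensions, labels and signal to 16-bit precision", {
  set.seed(42)
  rec <- recording(matrix(rnorm(23 * 60 * 256, sd = 30), 23, 60 * 256), fs = 256,
                   channel_labels = sprintf("EEG%02d", 1:23), record_id = "syn")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(nrow(back$signal), 23L)
  expect_equal(ncol(back$signal), 15360L)
  expect_equal(back$fs, 256)
  expect_equal(back$channel_labels, rec$channel_labels)
  q <- max(apply(rec$signal, 1, function(r) diff(range(r)))) / 65535
  expect_lt(max(abs(back$signal - rec$signal)), 2 * q)
})

test_that("EDF decoding agrees with an independent reader (mne)", {
  set.seed(7)
  rec <- recording(matrix(rnorm(4 * 512, sd = 20), 4, 512), fs = 256,
                   channel_labels = c("FP1", "FP2", "C3", "C4"))
  dir <- withr::local_tempdir()
  edf <- file.path(dir, "x.edf")
  csv <- file.path(dir, "mne.csv")
  write_edf(rec, edf)
  status <- system2("python", c("-c", shQuote(sprintf(
    "import mne, numpy as np; raw = mne.io.read_raw_edf('%s', verbose='error'); np.savetxt('%s', raw.get_data() * 1e6, delimiter=',')",
    edf, csv))))
  expect_equal(status, 0L)
  m <- as.matrix(read.csv(csv, header = FALSE))
  ours <- read_edf(edf)$signal
  expect_lt(max(abs(unname(ours) - unname(m))), 1e-9)
})

test_that("duplicate channel labels are made unique with a warning", {
  sig <- matrix(rnorm(3 * 256), 3, 256)
  expect_warning(rec <- recording(sig, 256, c("C3", "C3", "C4")), "duplicate")
  expect_false(anyDuplicated(rec$channel_labels) > 0)
})

test_that("truncated and malformed EDF files are rejected with format errors", {
  set.seed(1)
  rec <- recording(matrix(rnorm(2 * 512), 2, 512), fs = 256)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  full <- readBin(path, "raw", file.info(path)$size)
  trunc_path <- withr::local_tempfile(fileext = ".edf")
  writeBin(full[1:(length(full) - 100L)], trunc_path)
  expect_error(read_edf(trunc_path), "truncated")
  bad_path <- withr::local_tempfile(fileext = ".edf")
  bad <- full
  bad[253:256] <- charToRaw("abcd")  # number-of-signals field
  writeBin(bad, bad_path)
  expect_error(read_edf(bad_path), "not numeric|invalid")
  expect_error(read_edf(withr::local_tempfile()), "no such file")
})

test_that("CHB-MIT summary dialect parses per-record seizure blocks", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "Data Sampling Rate: 256 Hz",
    "",
    "File Name: chb01_03.edf",
    "Number of Seizures in File: 1",
    "Seizure Start Time: 2996 seconds",
    "Seizure End Time: 3036 seconds",
    "",
    "File Name: chb01_04.edf",
    "Number of Seizures in File: 0",
    "",
    "File Name: chb01_05.edf",
    "Number of Seizures in File: 2",
    "Seizure 1 Start Time: 1000 seconds",
    "Seizure 1 End Time: 1040 seconds",
    "Seizure 2 Start Time: 1300 seconds",
    "Seizure 2 End Time: 1360 seconds"
  ), path)
  ann <- read_chb_annotations(path)
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$record_id[1], "chb01_03")
  expect_equal(ann$onset_s[1], 2996)
  expect_equal(ann$offset_s[1], 3036)
  expect_false("chb01_04" %in% ann$record_id)
  # close pair is parsed unmerged; merging is the policy's job
  expect_equal(sum(ann$record_id == "chb01_05"), 2L)
  expect_false(any(ann$merged))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("File Name: a.edf", "Number of Seizures in File: 1",
               "Seizure Start Time: 50 seconds",
               "Seizure End Time: 40 seconds"), bad)
  expect_error(read_chb_annotations(bad), "onset at or after offset")
})

test_that("seizure policy merges postictal-chained seizures and flags short preictal", {
  ann <- seizure_annotations(c("a", "a"), c(1000, 1300), c(1040, 1360))
  out <- apply_seizure_policy(ann, postictal_len = 600, min_preictal = 180)
  expect_equal(nrow(out), 1L)
  expect_equal(out$onset_s, 1000)
  expect_equal(out$offset_s, 1360)
  expect_true(out$merged)
  expect_false(out$excluded)

  # chain of three is absorbed into one
  ann3 <- seizure_annotations(rep("a", 3), c(1000, 1300, 1900), c(1040, 1360, 1950))
  out3 <- apply_seizure_policy(ann3, postictal_len = 600, min_preictal = 180)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$offset_s, 1950)

  # not enough recorded preictal time before onset
  early <- seizure_annotations("a", 100, 140)
  expect_message(oute <- apply_seizure_policy(early, min_preictal = 180),
                 "excluded")
  expect_true(oute$excluded)
  expect_equal(oute$reason, "insufficient_preictal")

  # well-separated seizures pass through unchanged
  far <- seizure_annotations(c("a", "a"), c(1000, 5000), c(1040, 5040))
  outf <- suppressMessages(apply_seizure_policy(far, min_preictal = 180))
  expect_equal(outf$onset_s, c(1000, 5000))
  expect_false(any(outf$merged))
})

test_that("seizure policy is idempotent and merges exactly the postictal onsets", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    on <- sort(runif(n, 1000, 20000))
    off <- on + runif(n, 10, 200)
    off <- pmin(off, c(on[-1], Inf) - 1)  # keep seizures non-overlapping
    ann <- seizure_annotations(rep("a", n), on, off)
    once <- suppressMessages(apply_seizure_policy(ann, 600, 180))
    twice <- suppressMessages(apply_seizure_policy(once, 600, 180))
    expect_equal(twice, once)
    # count drop equals the number of onsets within postictal of the previous offset,
    # tracked against the running merged offset
    expected <- n
    cur_off <- off[1]
    for (k in 2:n) {
      if (on[k] <= cur_off + 600) {
        expected <- expected - 1L
        cur_off <- max(cur_off, off[k])
      } else {
        cur_off <- off[k]
      }
    }
    expect_equal(nrow(once), expected)
  }
})

test_that("fixture container round-trips recordings losslessly and enforces its version", {
  set.seed(5)
  rec <- recording(matrix(rnorm(3 * 100), 3, 100), fs = 50, record_id = "fx")
  ann <- seizure_annotations("fx", 0.5, 1.0)
  path <- withr::local_tempfile(fileext = ".fix")
  write_fixture(rec, path, ann)
  back <- read_fixture(path)
  expect_identical(back$recording$signal, rec$signal)
  expect_identical(back$recording$channel_labels, rec$channel_labels)
  expect_equal(back$recording$fs, rec$fs)
  expect_equal(back$annotations, ann)

  # empty annotation table round trip
  p2 <- withr::local_tempfile()
  write_fixture(rec, p2)
  expect_equal(nrow(read_fixture(p2)$annotations), 0L)

  # future major version refused
  p3 <- withr::local_tempfile()
  saveRDS(list(format = "cspseizure-fixture", version = c(2L, 0L),
               kind = "object", payload = 1), p3)
  expect_error(read_fixture(p3), "newer major version")
  p4 <- withr::local_tempfile()
  saveRDS(list(not = "a fixture"), p4)
  expect_error(read_fixture(p4), "format error")
})

test_that("record sets build a global clock with derived gaps and harmonized channels", {
  set.seed(2)
  mk <- function(id, t0, extra = NULL) {
    labs <- c("C3", "C4", extra)
    recording(matrix(rnorm(length(labs) * 100), length(labs), 100), fs = 10,
              channel_labels = labs, start_time = t0, record_id = id)
  }
  expect_warning(
    rs <- record_set(list(mk("r1", 0), mk("r2", 20, extra = "EXTRA")),
                     seizure_annotations("r2", 2, 4)),
    "extra channels")
  expect_equal(nrow(rs$gaps), 1L)
  expect_equal(unname(rs$gaps[1, ]), c(10, 20))
  expect_equal(rs$annotations$onset_s, 22)  # global clock
  expect_equal(ncol(rs$recordings$r2$signal), 100L)
  expect_equal(rs$recordings$r2$channel_labels, c("C3", "C4"))

  expect_error(record_set(list(mk("r1", 0), mk("r2", 5))), "overlap")
  expect_warning(record_set(list(mk("r1", 0)),
                            seizure_annotations("nope", 1, 2)),
                 "unknown records")
})
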