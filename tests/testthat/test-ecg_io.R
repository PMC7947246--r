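test_that("CSV round trip is an identity on voltages and annotations", {
  rec <- make_record(n = 4000, annotations = list(beat_annotation("SR", 1200),
                                                  beat_annotation("PVC", 2600)))
  path <- file.path(tempdir(), "rt.csv")
  write_record_csv(rec, path)
  back <- read_record(path, format = "csv", fs = 2000)
  expect_equal(record_length <- length(back$signals$I), 4000)
  for (l in lead_names()) {
    expect_lt(max(abs(back$signals[[l]] - rec$signals[[l]])), 1e-9)
  }
  expect_equal(vapply(back$annotations, `[[`, 0L, "approx_r_index"),
               c(1200L, 2600L))
  expect_equal(vapply(back$annotations, `[[`, "", "beat_class"),
               c("SR", "PVC"))
  # second round trip reproduces the first exactly
  path2 <- file.path(tempdir(), "rt2.csv")
  write_record_csv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed records are rejected with the documented errors", {
  sig <- stats::setNames(rep(list(numeric(100)), 11L), lead_names()[1:11])
  expect_error(twelve_lead_ecg(sig, fs = 2000), "incomplete-leads")
  sig12 <- stats::setNames(rep(list(numeric(100)), 12L), lead_names())
  sig12$V3 <- numeric(99)
  expect_error(twelve_lead_ecg(sig12, fs = 2000), "ragged-record")
  sig12$V3 <- numeric(100)
  expect_error(twelve_lead_ecg(sig12, fs = 0), "bad-rate")
  # case-insensitive lead matching, canonical reordering
  shuffled <- rev(stats::setNames(rep(list(numeric(10)), 12L),
                                  tolower(lead_names())))
  rec <- twelve_lead_ecg(shuffled, fs = 2000)
  expect_identical(names(rec$signals), lead_names())
})

test_that("uV CSVs are converted to mV on read", {
  rec <- make_record(n = 100)
  path <- file.path(tempdir(), "uv.csv")
  dt <- data.table::as.data.table(lapply(rec$signals, function(v) v * 1000))
  data.table::fwrite(dt, path)
  back <- read_record(path, format = "csv", unit = "uV")
  expect_equal(back$signals$V1, rec$signals$V1, tolerance = 1e-12)
})

test_that("WFDB format-16 round trip preserves voltages to ADC resolution", {
  rec <- make_record(n = 2000, annotations = list(beat_annotation("SR", 500)))
  base <- file.path(tempdir(), "wfdbrec")
  write_wfdb(rec, base)
  back <- read_wfdb(base)
  expect_equal(back$fs, 2000)
  for (l in lead_names()) {
    expect_lt(max(abs(back$signals[[l]] - rec$signals[[l]])), 5.1e-4)
  }
  expect_equal(back$annotations[[1L]]$approx_r_index, 500L)
})

test_that("resample_to_2khz handles identity, doubling, and band-limited error", {
  rec <- make_record(n = 2000, fs = 2000)
  expect_identical(resample_to_2khz(rec), rec)

  rec1k <- make_record(n = 2000, fs = 1000,
                       annotations = list(beat_annotation("SR", 500)))
  up <- resample_to_2khz(rec1k)
  expect_equal(length(up$signals$I), 4000)
  expect_equal(up$fs, 2000)
  expect_equal(up$annotations[[1L]]$approx_r_index, 1000L)

  # 10 Hz sine at 500 Hz, integer cycles: per-sample error < 1e-3 mV
  t500 <- (0:499) / 500
  sig <- stats::setNames(rep(list(sin(2 * pi * 10 * t500)), 12L), lead_names())
  s <- twelve_lead_ecg(sig, fs = 500)
  s2k <- resample_to_2khz(s)
  t2k <- (0:1999) / 2000
  expect_lt(max(abs(s2k$signals$V1 - sin(2 * pi * 10 * t2k))), 1e-3)
  # idempotent once at 2 kHz
  expect_identical(resample_to_2khz(s2k), s2k)
})
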