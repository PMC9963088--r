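test_that("WFDB write/read round-trips signals and annotations", {
  gen <- tiny_synth(duration = 5)
  dir <- withr::local_tempdir()
  write_wfdb(gen$record, dir, gen$annotations)
  back <- read_wfdb(file.path(dir, gen$record$record_id))
  expect_identical(back$lead_names, gen$record$lead_names)
  expect_equal(back$sampling_rate, gen$record$sampling_rate)
  # format-16 with gain 2000 quantises at 0.0005 mV
  expect_lt(max(abs(back$signal - gen$record$signal)), 0.5 / 2000 + 1e-12)
  ann <- read_wfdb_annotations(
    file.path(dir, paste0(gen$record$record_id, ".atr")), back$n_samples
  )
  expect_identical(ann$sample_indices, gen$annotations$sample_indices)
})

test_that("lead selection reorders columns and errors on unknown leads", {
  gen <- tiny_synth(duration = 3)
  rec <- gen$record
  # store leads shuffled, request canonical order back
  shuffled <- select_leads(rec, rev(rec$lead_names))
  dir <- withr::local_tempdir()
  write_wfdb(shuffled, dir)
  back <- read_wfdb(file.path(dir, rec$record_id),
                    leads = c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6"))
  expect_identical(back$lead_names, rec$lead_names)
  # each re-read column correlates best with its own source lead
  for (ld in rec$lead_names) {
    cors <- apply(rec$signal, 2, stats::cor, y = back$signal[, ld])
    expect_identical(names(which.max(cors)), ld)
    expect_lt(max(abs(back$signal[, ld] - rec$signal[, ld])),
              0.5 / 2000 + 1e-12)
  }
  expect_error(select_leads(rec, c("I", "nope")), class = "vcg_lead_not_found")
  expect_error(read_wfdb(file.path(tempdir(), "no-such-record")),
               class = "vcg_io_error")
})

test_that("annotation reader keeps beat marks only, de-duplicated and sorted", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "marks.atr")
  # beats at 100 (twice -> deduplicated), 600, 3000; non-beat marks between
  idx <- c(100L, 100L, 250L, 600L, 1500L, 3000L)
  codes <- c(1L, 1L, 28L, 5L, 14L, 1L) # 28 rhythm and 14 noise are not beats
  write_wfdb_annotations(idx, path, codes)
  ann <- read_wfdb_annotations(path, n_samples = 5000L)
  expect_identical(ann$sample_indices, c(100L, 600L, 3000L))
  # clipping to the record length
  ann2 <- read_wfdb_annotations(path, n_samples = 700L)
  expect_identical(ann2$sample_indices, c(100L, 600L))
})

test_that("long inter-annotation gaps survive the SKIP encoding", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "far.atr")
  idx <- c(10L, 400000L, 400500L, 900000L)
  write_wfdb_annotations(idx, path)
  expect_identical(read_wfdb_annotations(path)$sample_indices, idx)
})

test_that("resampling preserves length formula, beat count and tones", {
  gen <- tiny_synth(duration = 5)
  same <- resample_record(gen$record, gen$annotations, 500)
  expect_equal(same$record$signal, gen$record$signal)
  expect_identical(same$annotations$sample_indices,
                   gen$annotations$sample_indices)

  # 30-minute record at 257 Hz maps to exactly 900,000 samples at 500 Hz
  n257 <- 30 * 60 * 257
  expect_equal(round(n257 * 500 / 257), 900000)
  rec <- ecg_record(matrix(rnorm(2570), ncol = 1), 257, "II")
  ann <- beat_annotations(c(100L, 900L, 2000L), n_samples = 2570L)
  out <- resample_record(rec, ann, 500)
  expect_equal(out$record$n_samples, round(2570 * 500 / 257))
  expect_length(out$annotations$sample_indices, 3L)
  expect_equal(out$annotations$sample_indices,
               round(c(100, 900, 2000) * 500 / 257))

  # a pure 10 Hz tone stays a 10 Hz tone (dominant FFT bin preserved)
  dur <- 4
  t257 <- seq(0, dur - 1 / 257, by = 1 / 257)
  tone <- ecg_record(matrix(sin(2 * pi * 10 * t257), ncol = 1), 257, "II")
  up <- resample_record(tone, target_rate = 500)
  spec <- Mod(stats::fft(up$signal[, 1]))[seq_len(up$n_samples %/% 2)]
  peak_hz <- (which.max(spec[-1])) / (up$n_samples / 500)
  expect_equal(peak_hz, 10, tolerance = 1 / dur)
})

test_that("interval annotations collapse to per-complex R-peak locations", {
  expect_identical(collapse_interval_annotations(10:14, 1L), 12L)
  expect_identical(collapse_interval_annotations(c(10:12, 50:52), 2L),
                   c(11L, 51L))
  # centroid 40.5 rounds half away from zero -> 41
  x <- c(5:7, 40:41, 90:92)
  expect_identical(collapse_interval_annotations(x, 3L), c(6L, 41L, 91L))
  expect_error(collapse_interval_annotations(1:3, 5L), class = "vcg_bad_k")
})

test_that("collapse agrees with the exhaustive partition oracle and is
           invariant to ordering and duplicates", {
  # QRS-interval mark runs: similar widths (real QRS complexes are), centres
  # a beat apart — the regime where Lloyd from quantile init is exact
  withr::local_seed(11)
  for (trial in 1:20) {
    k <- sample(1:4, 1)
    centres <- sort(sample(seq(10, 2000, by = 200), k))
    width <- sample(3:6, 1)
    x <- unlist(lapply(centres, function(c0) c0 + 0:width))
    got <- collapse_interval_annotations(x, k)
    oracle <- vcgrpeak:::round_half_away(best_partition_centroids(x, k))
    expect_identical(got, as.integer(sort(oracle)))
    shuffled <- sample(c(x, sample(x, 3, replace = TRUE)))
    expect_identical(collapse_interval_annotations(shuffled, k), got)
  }
})
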