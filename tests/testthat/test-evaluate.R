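test_that("detections outside the annotated span are discarded", {
  ann <- beat_annotations(c(1000L, 2000L, 3000L))
  det <- vcgrpeak:::new_detected_peaks(c(850L, 963L, 1000L, 3037L, 3100L),
                                       rep(0.9, 5), rep(5L, 5))
  kept <- restrict_to_annotated_span(det, ann, fs = 500)
  # 75 ms at 500 Hz = 37.5 samples: 963 and 3037 survive, 850/3100 do not
  expect_identical(kept$sample_index, c(963L, 1000L, 3037L))
  inside <- restrict_to_annotated_span(det[3, ], ann, 500)
  expect_identical(inside$sample_index, 1000L)
  expect_error(restrict_to_annotated_span(det, beat_annotations(integer(0)),
                                          500),
               class = "vcg_empty_annotations")
})

test_that("matching respects the inclusive +/-75 ms tolerance", {
  # 37 samples at 500 Hz = 74 ms: inside
  m <- match_peaks(1037L, 1000L, fs = 500)
  expect_identical(nrow(m$pairs), 1L)
  # 38 samples = 76 ms: outside -> one FN and one FP
  m <- match_peaks(1038L, 1000L, fs = 500)
  expect_identical(nrow(m$pairs), 0L)
  expect_identical(m$fn, 1000L)
  expect_identical(m$fp, 1038L)
  # a detection between two annotations pairs with the closer one in time
  # (70 ms from the first, 130 ms from the second)
  m <- match_peaks(1035L, c(1000L, 1100L), fs = 500)
  expect_identical(m$pairs$annotation, 1000L)
  expect_identical(m$fn, 1100L)
})

test_that("greedy matching attains the optimal pair count on small instances", {
  withr::local_seed(17)
  fs <- 500
  for (trial in 1:200) {
    # annotations at physiological spacing (>= 200 ms apart, i.e. more than
    # twice the tolerance, as real beats are); detections jitter around them
    # with occasional spurious or missed events
    n_ann <- sample(0:10, 1)
    ann <- sort(sample(seq(0, 2000, by = 100), n_ann))
    det <- ann + sample(-45:45, n_ann, replace = TRUE)
    keep <- stats::runif(n_ann) > 0.2
    det <- sort(unique(c(det[keep], sample(0:2000, sample(0:3, 1)))))
    m <- match_peaks(det, ann, fs)
    expect_identical(nrow(m$pairs),
                     oracle_max_matching(ann, det, fs))
    # conservation of counts
    expect_identical(nrow(m$pairs) + length(m$fn), length(ann))
    expect_identical(nrow(m$pairs) + length(m$fp), length(det))
    expect_true(all(abs(m$pairs$dt_ms) <= 75))
  }
})

test_that("metric formulas reproduce printed benchmark arithmetic", {
  r <- compute_metrics(tp = 175631, fn = 276, fp = 16)
  expect_equal(round(r$recall, 2), 99.84)
  expect_equal(round(r$precision, 2), 99.99)
  r <- compute_metrics(tp = 3946, fn = 27, fp = 0)
  expect_equal(round(r$precision, 2), 100.00)
  r <- compute_metrics(tp = 10, fn = 0, fp = 0)
  expect_equal(c(r$recall, r$precision, r$f1), c(100, 100, 100))
  # undefined metrics are flagged, not forced to 0 or 100
  r <- compute_metrics(tp = 0, fn = 5, fp = 0)
  expect_true(is.na(r$precision))
  expect_equal(r$recall, 0)
})

test_that("metrics are bounded and F1 sits between recall and precision", {
  withr::local_seed(18)
  for (trial in 1:50) {
    r <- compute_metrics(tp = sample(0:100, 1), fn = sample(0:50, 1),
                         fp = sample(1:50, 1))
    if (is.na(r$f1)) next
    expect_gte(r$f1, min(r$recall, r$precision) - 1e-9)
    expect_lte(r$f1, max(r$recall, r$precision) + 1e-9)
    expect_true(all(c(r$recall, r$precision, r$f1) >= 0))
    expect_true(all(c(r$recall, r$precision, r$f1) <= 100))
  }
})

test_that("shifting detections past the tolerance destroys every match", {
  ann <- seq(500L, 9500L, by = 450L)
  det <- ann + 10L
  fs <- 500
  base <- compute_metrics(match_peaks(det, ann, fs))
  expect_equal(base$recall, 100)
  shifted <- det + as.integer(75 / 1000 * fs) + 11L # tolerance + epsilon
  r <- compute_metrics(match_peaks(shifted, ann, fs))
  expect_equal(r$recall, 0)
  expect_identical(r$fn, length(ann))
})

test_that("pooled and macro aggregation follow their definitions", {
  a <- compute_metrics(tp = 10, fn = 0, fp = 0) # recall 100, 10 beats
  b <- compute_metrics(tp = 45, fn = 45, fp = 0) # recall 50, 90 beats
  both <- dplyr::bind_rows(a, b)
  expect_equal(aggregate_metrics(both, "macro")$recall, 75)
  expect_equal(aggregate_metrics(both, "pooled")$recall, 55)
  same <- dplyr::bind_rows(a, a)
  expect_equal(aggregate_metrics(same, "macro")$recall, a$recall)
  expect_equal(aggregate_metrics(same, "pooled")$f1, a$f1)
  single <- aggregate_metrics(a, "pooled")
  expect_equal(single$recall, a$recall)
  expect_error(aggregate_metrics(a[0, ], "pooled"),
               class = "vcg_empty_reports")
})

test_that("heart-rate and RMSSD summaries follow their closed forms", {
  # strict 60 bpm
  h <- hrv_summary(seq(0L, 4500L, by = 500L), fs = 500)
  expect_equal(h$avg_hr, 60)
  expect_equal(h$sd_hr, 0)
  expect_equal(h$rmssd, 0)

  # alternating RR of 0.8 s and 1.0 s: every successive difference is 0.2 s
  rr <- rep(c(0.8, 1), 10)
  beats <- as.integer(round(cumsum(c(0.5, rr)) * 500))
  h <- hrv_summary(beats, fs = 500)
  expect_equal(h$rmssd, 200)
  expect_equal(h$avg_hr, mean(60 / rr))

  # boundary: two beats give a rate but no RMSSD
  h <- hrv_summary(c(0L, 500L), fs = 500)
  expect_equal(h$avg_hr, 60)
  expect_true(is.na(h$rmssd))

  # pooling never forms intervals across record boundaries
  recs <- list(seq(0L, 2000L, by = 500L), seq(100L, 2100L, by = 400L))
  pooled <- hrv_summary(recs, fs = 500)
  rr_all <- c(diff(recs[[1]]), diff(recs[[2]])) / 500
  expect_equal(pooled$avg_hr, mean(60 / rr_all))
  expect_equal(pooled$rmssd,
               1000 * sqrt(mean(c(diff(diff(recs[[1]]) / 500),
                                  diff(diff(recs[[2]]) / 500))^2)))
})

test_that("tidy and glance views expose matches and aggregates", {
  m <- match_peaks(c(1000L, 1500L, 2200L), c(1000L, 1510L), fs = 500)
  td <- generics::tidy(m)
  expect_setequal(td$type, c("TP", "FP"))
  expect_identical(sum(td$type == "TP"), 2L)
  g <- generics::glance(m)
  expect_s3_class(g, "metrics_report")
  expect_identical(g$tp, 2L)
})
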