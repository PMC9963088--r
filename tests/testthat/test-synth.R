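test_that("a jitter-free rhythm puts beats exactly on the programmed grid", {
  gen <- tiny_synth(duration = 10, mean_hr = 60, rr_sd = 0)
  expect_identical(gen$annotations$sample_indices,
                   as.integer(round((0.5 + 0:9) * 500)))
  expect_identical(nrow(gen$beats), 10L)
})

test_that("the same seed reproduces a record bit for bit", {
  cfg <- synth_config(duration = 8, seed = 123,
                      noise = list(broadband_sd = 0.02))
  a <- generate_ecg(cfg)
  b <- generate_ecg(cfg)
  expect_identical(a$record$signal, b$record$signal)
  expect_identical(a$annotations$sample_indices, b$annotations$sample_indices)
  c <- generate_ecg(synth_config(duration = 8, seed = 124,
                                 noise = list(broadband_sd = 0.02)))
  expect_false(identical(a$record$signal, c$record$signal))
})

test_that("RR jitter has the i.i.d. Gaussian successive-difference RMSSD", {
  # for independent jitter of sd sigma, RMSSD -> sigma * sqrt(2) * 1000 ms
  sigma <- 0.04
  gen <- generate_ecg(synth_config(duration = 1800, mean_hr = 80,
                                   rr_sd = sigma, seed = 42))
  expect_gt(nrow(gen$beats), 2000)
  rr <- diff(gen$beats$time_s)
  rmssd <- 1000 * sqrt(mean(diff(rr)^2))
  expect_equal(rmssd, sigma * sqrt(2) * 1000, tolerance = 0.05)
})

test_that("annotations are conserved, in range and sit on VCG extrema", {
  gen <- tiny_synth(duration = 20, mean_hr = 75, rr_sd = 0.05, seed = 9)
  ann <- gen$annotations$sample_indices
  expect_identical(length(ann), nrow(gen$beats))
  expect_true(all(ann >= 0 & ann < gen$record$n_samples))
  vcg <- kors_transform(gen$record)
  # Kors consistency: X axis of the transform tracks the dipole X axis
  expect_gt(stats::cor(vcg$vectors[, "X"], gen$dipole[, "X"]), 0.95)
  # every annotation is a local extremum of some channel within +/-1 sample
  for (p in ann) {
    win <- vcg$vectors[(p - 1):(p + 3), , drop = FALSE] # 0-based p +/- 2
    hit <- any(vapply(1:3, function(ch) {
      i <- which.max(abs(win[, ch]))
      i >= 2 && i <= 4
    }, logical(1)))
    expect_true(hit)
  }
})

test_that("ectopic beats are premature with wider QRS and pacing adds spikes", {
  gen <- generate_ecg(synth_config(duration = 120, ectopic_rate = 0.15,
                                   seed = 5))
  expect_gt(sum(gen$beats$ectopic), 3)
  rr <- diff(gen$beats$time_s)
  pre <- rr[which(gen$beats$ectopic[-1])] # interval ending in an ectopic
  expect_lt(mean(pre), mean(rr))

  paced <- generate_ecg(synth_preset("paced", duration = 10, seed = 6))
  unpaced <- generate_ecg(synth_config(duration = 10, seed = 6))
  diffsig <- paced$record$signal - unpaced$record$signal
  expect_identical(paced$annotations$sample_indices,
                   unpaced$annotations$sample_indices)
  # spikes are 1-sample events: difference is zero almost everywhere
  expect_lt(mean(rowSums(abs(diffsig)) > 0), 0.01)
  expect_gt(max(abs(diffsig)), 1)
})

test_that("noise injection is additive with the stated spectral signatures", {
  gen <- tiny_synth(duration = 10)
  clean <- gen$record
  expect_equal(inject_noise(clean, list())$signal, clean$signal)

  # powerline: the added component concentrates at 50 Hz with amplitude a
  a <- 0.08
  noisy <- inject_noise(clean, list(powerline_amp = a, powerline_freq = 50),
                        seed = 2)
  added <- noisy$signal[, "II"] - clean$signal[, "II"]
  n <- length(added)
  spec <- Mod(stats::fft(added)) / n * 2
  bin50 <- 50 * (n / 500) + 1
  expect_equal(spec[bin50], a, tolerance = 0.02 * a)
  expect_lt(max(spec[-c(1, bin50, n - 50 * (n / 500) + 1)]), 0.02 * a)

  # baseline wander: mean absolute value of a sinusoid of amplitude a is
  # 2a/pi
  aw <- 0.2
  wander <- inject_noise(clean, list(baseline_amp = aw, baseline_freq = 0.25),
                         seed = 3)
  added <- wander$signal - clean$signal
  expect_equal(mean(abs(added)), 2 * aw / pi, tolerance = 0.1 * 2 * aw / pi)
})

test_that("preset scenarios configure the advertised features", {
  expect_equal(synth_preset("clean")$ectopic_rate, 0)
  expect_gt(synth_preset("ectopic")$ectopic_rate, 0)
  expect_true(synth_preset("paced")$pacemaker_spikes)
  expect_gt(synth_preset("noisy")$noise$baseline_amp, 0)
  expect_error(synth_config(duration = 0.1, mean_hr = 60),
               class = "vcg_bad_config")
})
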