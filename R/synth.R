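#' Synthetic multi-lead ECG configuration
#'
#' The generator renders a 3-axis cardiac dipole as a train of Gaussian
#' P-QRS-T waves (in the spirit of the classic dynamical ECG model), projects
#' it onto the eight independent leads, and optionally adds ectopic beats,
#' pacemaker spikes and noise. The default lead projection is the
#' Moore-Penrose pseudo-inverse of the Kors matrix, so the Kors transform of
#' the clean synthetic leads recovers the dipole exactly.
#'
#' Beat-to-beat RR intervals are Gaussian around `60 / mean_hr` with standard
#' deviation `rr_sd`, truncated at three standard deviations and floored at
#' 0.3 s. Ectopic beats are premature (RR scaled by 0.6) with doubled QRS
#' width, inverted S wave and no P wave, mimicking extrasystoles. Pacemaker
#' spikes are one-sample high-amplitude pulses 150 ms before each QRS.
#'
#' @param sampling_rate Hz (default 500).
#' @param duration record duration, seconds.
#' @param mean_hr mean heart rate, beats/min.
#' @param rr_sd RR jitter standard deviation, seconds.
#' @param ectopic_rate per-beat probability of an ectopic morphology.
#' @param pacemaker_spikes add pacing pulses before each QRS.
#' @param noise list with optional entries `baseline_amp` (mV),
#'   `baseline_freq` (Hz, < 0.5), `powerline_amp` (mV), `powerline_freq`
#'   (Hz), `broadband_sd` (mV), `burst_rate` (bursts/min), `burst_amp` (mV).
#' @param seed integer; fully determines the output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(sampling_rate = 500, duration = 60, mean_hr = 70,
                         rr_sd = 0.05, ectopic_rate = 0,
                         pacemaker_spikes = FALSE, noise = list(),
                         seed = 1L) {
  if (duration * mean_hr / 60 < 1) {
    vcg_abort("configuration yields fewer than one beat", "vcg_bad_config")
  }
  stopifnot(sampling_rate > 0, rr_sd >= 0,
            ectopic_rate >= 0, ectopic_rate <= 1)
  structure(
    list(
      sampling_rate = sampling_rate, duration = duration, mean_hr = mean_hr,
      rr_sd = rr_sd, ectopic_rate = ectopic_rate,
      pacemaker_spikes = isTRUE(pacemaker_spikes),
      noise = noise, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generator presets
#'
#' Named scenario shortcuts: `"clean"` (no noise, no ectopy), `"noisy"`
#' (baseline wander + powerline + broadband), `"ectopic"` (8% extrasystoles)
#' and `"paced"` (pacemaker spikes).
#'
#' @param name preset name.
#' @param ... overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_preset <- function(name = c("clean", "noisy", "ectopic", "paced"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    clean = list(),
    noisy = list(noise = list(baseline_amp = 0.15, baseline_freq = 0.3,
                              powerline_amp = 0.05, powerline_freq = 50,
                              broadband_sd = 0.02)),
    ectopic = list(ectopic_rate = 0.08),
    paced = list(pacemaker_spikes = TRUE)
  )
  do.call(synth_config, modifyList(base, list(...)))
}

# dipole wave table: per wave, centre offset (s), width (s), amplitude on
# the X, Y, Z axes (mV)
dipole_waves <- function(ectopic = FALSE) {
  w <- list(
    P = list(off = -0.20, sd = 0.025, amp = c(0.06, 0.05, 0.01)),
    Q = list(off = -0.035, sd = 0.010, amp = c(-0.10, -0.06, 0.05)),
    R = list(off = 0.000, sd = 0.012, amp = c(1.00, 0.60, -0.50)),
    S = list(off = 0.035, sd = 0.012, amp = c(-0.25, -0.15, 0.20)),
    T = list(off = 0.30, sd = 0.070, amp = c(0.25, 0.15, -0.10))
  )
  if (ectopic) {
    w$P$amp <- c(0, 0, 0)
    for (nm in c("Q", "R", "S")) w[[nm]]$sd <- 2 * w[[nm]]$sd
    w$S$amp <- -w$S$amp
    w$R$amp <- c(0.9, -0.5, 0.7) # different electrical axis
  }
  w
}

# default projection: right pseudo-inverse of the Kors matrix, so
# kors_transform(leads) reproduces the dipole exactly on clean records
default_lead_projection <- function() {
  M <- kors_matrix()
  t(solve(crossprod(M), t(M))) # 8 x 3
}

#' Generate a synthetic multi-lead ECG with exact ground truth
#'
#' @param config a [synth_config()].
#' @param record_id identifier for the generated record.
#' @return A list with `record` (an 8-lead [ecg_record()]), `annotations`
#'   (a [beat_annotations()] at the dipole-magnitude maximum of each beat),
#'   `dipole` (the clean `n x 3` dipole matrix) and `beats` (a tibble with
#'   beat times and ectopic flags).
#' @export
#' @examples
#' rec <- generate_ecg(synth_config(duration = 10, mean_hr = 60, rr_sd = 0))
#' length(rec$annotations$sample_indices)
generate_ecg <- function(config = synth_config(), record_id = "synth") {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  n <- as.integer(round(config$duration * fs))
  tt <- (seq_len(n) - 1L) / fs

  # rhythm (own sub-seed so noise settings never shift beat times)
  set.seed(config$seed)
  mean_rr <- 60 / config$mean_hr
  beat_t <- numeric(0)
  ect <- logical(0)
  t_cur <- 0.5
  while (t_cur < config$duration - 0.1) {
    is_ect <- config$ectopic_rate > 0 &&
      runif(1) < config$ectopic_rate && length(beat_t) > 0
    if (is_ect) t_cur <- beat_t[length(beat_t)] + 0.6 *
        (t_cur - beat_t[length(beat_t)])
    if (t_cur >= config$duration - 0.1) break
    beat_t <- c(beat_t, t_cur)
    ect <- c(ect, is_ect)
    jit <- 0
    if (config$rr_sd > 0) {
      jit <- max(min(rnorm(1, 0, config$rr_sd), 3 * config$rr_sd),
                 -3 * config$rr_sd)
    }
    t_cur <- t_cur + max(mean_rr + jit, 0.3)
  }

  dipole <- matrix(0, n, 3, dimnames = list(NULL, c("X", "Y", "Z")))
  for (b in seq_along(beat_t)) {
    waves <- dipole_waves(ect[b])
    for (wv in waves) {
      if (all(wv$amp == 0)) next
      c0 <- beat_t[b] + wv$off
      lo <- max(1L, as.integer(floor((c0 - 4 * wv$sd) * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((c0 + 4 * wv$sd) * fs)) + 1L)
      if (lo > hi) next
      g <- exp(-((tt[lo:hi] - c0)^2) / (2 * wv$sd^2))
      dipole[lo:hi, ] <- dipole[lo:hi, ] + outer(g, wv$amp)
    }
  }

  # ground-truth annotation: dipole-magnitude maximum near each beat centre
  mag <- sqrt(rowSums(dipole^2))
  ann <- vapply(beat_t, function(tb) {
    lo <- max(1L, as.integer(round((tb - 0.06) * fs)) + 1L)
    hi <- min(n, as.integer(round((tb + 0.06) * fs)) + 1L)
    lo + which.max(mag[lo:hi]) - 2L # 0-based
  }, integer(1))

  if (config$pacemaker_spikes) {
    spikes <- as.integer(round((beat_t - 0.15) * fs)) + 1L
    spikes <- spikes[spikes >= 1L & spikes <= n]
    dipole[spikes, ] <- dipole[spikes, ] +
      matrix(rep(c(2, 2, 2), each = length(spikes)), ncol = 3)
  }

  leads <- dipole %*% t(default_lead_projection())
  colnames(leads) <- KORS_LEADS
  record <- ecg_record(leads, fs, KORS_LEADS, record_id)
  if (length(config$noise)) {
    record <- inject_noise(record, noise = config$noise,
                           seed = config$seed + 1L)
  }
  list(
    record = record,
    annotations = beat_annotations(ann, record_id, "II", n),
    dipole = dipole,
    beats = tibble::tibble(time_s = beat_t, ectopic = ect)
  )
}

#' Add noise components to an ECG record
#'
#' Purely additive: baseline wander (slow sinusoid with a random phase per
#' lead), powerline interference, broadband Gaussian noise and enveloped
#' muscle-artifact bursts. Ground-truth annotations are unaffected.
#'
#' @param record an [ecg_record()].
#' @param noise named list, see [synth_config()].
#' @param seed integer seed; the same seed reproduces the same noise.
#' @return The noisy `ecg_record`.
#' @export
inject_noise <- function(record, noise = list(), seed = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  set.seed(seed)
  n <- record$n_samples
  fs <- record$sampling_rate
  tt <- (seq_len(n) - 1L) / fs
  sig <- record$signal
  n_leads <- ncol(sig)
  if (!is.null(noise$baseline_amp) && noise$baseline_amp > 0) {
    f <- noise$baseline_freq %||% 0.3
    ph <- runif(n_leads, 0, 2 * pi)
    for (l in seq_len(n_leads)) {
      sig[, l] <- sig[, l] + noise$baseline_amp * sin(2 * pi * f * tt + ph[l])
    }
  }
  if (!is.null(noise$powerline_amp) && noise$powerline_amp > 0) {
    f <- noise$powerline_freq %||% 50
    ph <- runif(n_leads, 0, 2 * pi)
    for (l in seq_len(n_leads)) {
      sig[, l] <- sig[, l] + noise$powerline_amp * sin(2 * pi * f * tt + ph[l])
    }
  }
  if (!is.null(noise$broadband_sd) && noise$broadband_sd > 0) {
    sig <- sig + matrix(rnorm(n * n_leads, 0, noise$broadband_sd), n)
  }
  if (!is.null(noise$burst_rate) && noise$burst_rate > 0) {
    n_bursts <- stats::rpois(1, noise$burst_rate * n / fs / 60)
    amp <- noise$burst_amp %||% 0.3
    if (n_bursts > 0) {
      for (b in seq_len(n_bursts)) {
        c0 <- runif(1, 0, n / fs)
        sdb <- runif(1, 0.05, 0.2)
        lo <- max(1L, as.integer((c0 - 3 * sdb) * fs))
        hi <- min(n, as.integer((c0 + 3 * sdb) * fs))
        if (lo >= hi) next
        env <- exp(-((tt[lo:hi] - c0)^2) / (2 * sdb^2))
        burst <- env * rnorm(hi - lo + 1L, 0, amp)
        sig[lo:hi, ] <- sig[lo:hi, ] + burst # common-mode artifact
      }
    }
  }
  ecg_record(sig, fs, record$lead_names, record$record_id)
}
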