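#' Pan-Tompkins baseline configuration
#'
#' Constants of the classic 1985 recipe: 5-15 Hz band-pass, five-point
#' derivative, squaring, 150 ms moving-window integration, adaptive
#' signal/noise thresholds (0.125 running-estimate blend, decision threshold
#' at noise + 0.25 (signal - noise)), 200 ms refractory period, 360 ms T-wave
#' discrimination window and search-back at 1.66 times the running RR
#' average. This is a faithful re-implementation of the published recipe, not
#' a clone of any particular open-source variant.
#'
#' @param band_low,band_high band-pass corner frequencies, Hz.
#' @param integration_ms moving-window integration width, ms.
#' @param refractory_ms refractory period, ms.
#' @param twave_ms T-wave discrimination window, ms.
#' @param searchback_factor search-back trigger as a multiple of the running
#'   RR average.
#' @return An object of class `pt_config`.
#' @export
pt_config <- function(band_low = 5, band_high = 15, integration_ms = 150,
                      refractory_ms = 200, twave_ms = 360,
                      searchback_factor = 1.66) {
  structure(
    list(
      band_low = band_low, band_high = band_high,
      integration_ms = integration_ms, refractory_ms = refractory_ms,
      twave_ms = twave_ms, searchback_factor = searchback_factor
    ),
    class = "pt_config"
  )
}

#' Detect R-peaks with the Pan-Tompkins algorithm on a single lead
#'
#' Classical cascade: zero-phase Butterworth band-pass, five-point derivative,
#' squaring, moving-window integration, then adaptive dual-threshold decision
#' with refractory period, T-wave slope discrimination and search-back.
#' Detected peaks are snapped to the largest absolute excursion of the
#' band-passed signal within half an integration window.
#'
#' @param lead_signal numeric vector, one ECG lead in millivolts.
#' @param fs sampling rate in Hz (>= 100).
#' @param config a [pt_config()].
#' @return A `detected_peaks` tibble (columns `sample_index` 0-based,
#'   `probability` = NA, `support` = NA, `time_s`).
#' @export
pt_detect <- function(lead_signal, fs, config = pt_config()) {
  x <- as.numeric(lead_signal)
  if (fs < 100) vcg_abort("`fs` must be at least 100 Hz", "vcg_bad_rate")
  if (length(x) < 2 * fs) {
    vcg_abort("signal shorter than 2 s", "vcg_record_too_short")
  }
  n <- length(x)
  ny <- fs / 2
  bf <- signal::butter(3, c(config$band_low, config$band_high) / ny,
                       type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, x))
  # centred five-point derivative
  der <- as.numeric(stats::filter(bp, c(1, 2, 0, -2, -1) / 8, sides = 2))
  der[is.na(der)] <- 0
  sq <- der * der
  w <- max(1L, as.integer(round(config$integration_ms / 1000 * fs)))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  # strict local maxima of the integrated signal
  pk <- which(diff(sign(diff(mwi))) < 0) + 1L
  pk <- pk[mwi[pk] > 0]
  refr <- config$refractory_ms / 1000 * fs
  twin <- config$twave_ms / 1000 * fs
  half_w <- w %/% 2L

  slope_at <- function(i) {
    lo <- max(1L, i - half_w)
    hi <- min(n, i + half_w)
    max(abs(der[lo:hi]))
  }

  init_span <- seq_len(min(n, as.integer(2 * fs)))
  spki <- 0.25 * max(mwi[init_span])
  npki <- 0.5 * mean(mwi[init_span])
  qrs <- integer(0)
  qrs_slope <- numeric(0)
  rr_hist <- numeric(0)
  noise_pk <- integer(0)

  for (i in pk) {
    thr1 <- npki + 0.25 * (spki - npki)
    last <- if (length(qrs)) qrs[length(qrs)] else -Inf
    rr_avg <- if (length(rr_hist)) mean(tail(rr_hist, 8)) else Inf
    # search-back: overdue beat, revisit best rejected peak above thr1/2
    if (is.finite(rr_avg) && (i - last) > config$searchback_factor * rr_avg &&
        length(noise_pk)) {
      cand <- noise_pk[noise_pk > last + refr & mwi[noise_pk] > thr1 / 2]
      if (length(cand)) {
        sb <- cand[which.max(mwi[cand])]
        spki <- 0.25 * mwi[sb] + 0.75 * spki
        if (length(qrs)) rr_hist <- c(rr_hist, sb - last)
        qrs <- sort(c(qrs, sb))
        qrs_slope <- c(qrs_slope, slope_at(sb))
        last <- qrs[length(qrs)]
        noise_pk <- integer(0)
      }
    }
    if (i - last <= refr) next
    if (mwi[i] > thr1) {
      # T-wave check: within the discrimination window and half the slope
      if (i - last <= twin && length(qrs_slope) &&
          slope_at(i) < 0.5 * qrs_slope[length(qrs_slope)]) {
        npki <- 0.125 * mwi[i] + 0.875 * npki
        noise_pk <- c(noise_pk, i)
        next
      }
      spki <- 0.125 * mwi[i] + 0.875 * spki
      if (length(qrs)) rr_hist <- c(rr_hist, i - qrs[length(qrs)])
      qrs <- c(qrs, i)
      qrs_slope <- c(qrs_slope, slope_at(i))
      noise_pk <- integer(0)
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
      noise_pk <- c(noise_pk, i)
    }
  }

  # snap to the band-passed extremum within half an integration window
  if (length(qrs)) {
    snapped <- vapply(qrs, function(i) {
      lo <- max(1L, i - half_w)
      hi <- min(n, i + half_w)
      lo + which.max(abs(bp[lo:hi])) - 1L
    }, integer(1))
    snapped <- sort(unique(snapped))
    # enforce the refractory spacing after snapping (keep larger response)
    keep <- rep(TRUE, length(snapped))
    j <- 1L
    for (i in seq_along(snapped)[-1L]) {
      if (snapped[i] - snapped[j] < refr) {
        if (abs(bp[snapped[i]]) > abs(bp[snapped[j]])) {
          keep[j] <- FALSE
          j <- i
        } else {
          keep[i] <- FALSE
        }
      } else {
        j <- i
      }
    }
    qrs <- snapped[keep]
  }
  out <- new_detected_peaks(qrs - 1L, rep(NA_real_, length(qrs)),
                            rep(NA_integer_, length(qrs)))
  out$time_s <- out$sample_index / fs
  out
}
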