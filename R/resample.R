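#' Resample a record (and its annotations) to a new rate
#'
#' Band-limited polyphase resampling per lead (an anti-aliased FIR
#' interpolator, which preserves the 10-25 Hz QRS slope content far better
#' than linear interpolation). The pipeline operates at 500 Hz, so lower-rate
#' recordings are upsampled before windowing. The output has exactly
#' `round(n_samples * target_rate / sampling_rate)` samples; each annotation
#' index maps to `round(i * target_rate / sampling_rate)`, clipped to the new
#' range.
#'
#' @param record an [ecg_record()].
#' @param annotations optional [beat_annotations()].
#' @param target_rate desired sampling rate, Hz.
#' @return When `annotations` is `NULL`, the resampled `ecg_record`;
#'   otherwise `list(record = , annotations = )`.
#' @export
#' @examples
#' rec <- ecg_record(matrix(sin(2 * pi * 5 * (0:999) / 250), 1000, 1),
#'                   250, "II")
#' resample_record(rec, target_rate = 500)$n_samples
resample_record <- function(record, annotations = NULL, target_rate) {
  stopifnot(inherits(record, "ecg_record"), target_rate > 0)
  fs <- record$sampling_rate
  ratio <- target_rate / fs
  new_n <- as.integer(round(record$n_samples * ratio))
  if (isTRUE(all.equal(target_rate, fs))) {
    out <- record
  } else {
    # rational approximation of the rate ratio for the polyphase filter
    scale <- 1000
    p <- as.integer(round(target_rate * scale))
    q <- as.integer(round(fs * scale))
    g <- gcd_int(p, q)
    p <- p %/% g
    q <- q %/% g
    sig <- apply(record$signal, 2, function(col) {
      y <- as.numeric(signal::resample(col, p, q))
      if (length(y) >= new_n) y[seq_len(new_n)]
      else c(y, rep(y[length(y)], new_n - length(y)))
    })
    out <- ecg_record(sig, target_rate, record$lead_names, record$record_id)
  }
  if (is.null(annotations)) return(out)
  idx <- pmin(pmax(round(annotations$sample_indices * ratio), 0), new_n - 1L)
  list(
    record = out,
    annotations = beat_annotations(idx, annotations$record_id,
                                   annotations$reference_lead, new_n)
  )
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    tmp <- b
    b <- a %% b
    a <- tmp
  }
  a
}

#' Collapse interval-style QRS annotations to one R-peak per complex
#'
#' Some databases mark every sample inside each QRS interval instead of a
#' single R-peak. Given the marked indices and the known number of R-peaks
#' `k`, a one-dimensional k-means (initialised at evenly spaced order
#' statistics, run with Lloyd iterations to convergence) extracts one
#' location per complex; the cluster centroids are rounded half away from
#' zero and returned sorted.
#'
#' @param marked_indices integer vector of marked sample indices.
#' @param k number of R-peaks (clusters), `1 <= k <= length(unique(indices))`.
#' @return Sorted integer vector of length `k`.
#' @export
#' @examples
#' collapse_interval_annotations(c(10, 11, 12, 50, 51, 52), 2) # 11 51
collapse_interval_annotations <- function(marked_indices, k) {
  x <- sort(unique(as.numeric(marked_indices)))
  if (!is_count(k) || k < 1) {
    vcg_abort("`k` must be a positive integer", "vcg_bad_k")
  }
  if (k > length(x)) {
    vcg_abort("`k` exceeds the number of distinct marked indices",
              "vcg_bad_k")
  }
  if (k == length(x)) return(as.integer(round_half_away(x)))
  if (k == 1L) return(as.integer(round_half_away(mean(x))))
  # stats::kmeans would misread a length-1 centers object as a cluster count
  centers <- x[round(seq(1, length(x), length.out = k))]
  fit <- stats::kmeans(x, centers = matrix(centers, ncol = 1),
                       iter.max = 100L, algorithm = "Lloyd")
  sort(as.integer(round_half_away(as.numeric(fit$centers))))
}
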