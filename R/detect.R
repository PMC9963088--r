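#' Average overlapping window predictions into a per-sample trace
#'
#' Each sample's probability is the mean of the predictions of every window
#' covering it; samples covered by no window get probability 0 and coverage 0.
#'
#' @param window_predictions list of numeric probability vectors, one per
#'   window, all of the same length.
#' @param starts 0-based window start offsets (sorted).
#' @param n_samples record length.
#' @return An object of class `prob_trace` with numeric `values` and integer
#'   `coverage`, both of length `n_samples`.
#' @export
average_overlaps <- function(window_predictions, starts, n_samples) {
  stopifnot(length(window_predictions) == length(starts))
  acc <- numeric(n_samples)
  cov <- integer(n_samples)
  for (i in seq_along(starts)) {
    p <- window_predictions[[i]]
    rows <- (starts[i] + 1L):(starts[i] + length(p))
    acc[rows] <- acc[rows] + p
    cov[rows] <- cov[rows] + 1L
  }
  vals <- acc
  hit <- cov > 0L
  vals[hit] <- acc[hit] / cov[hit]
  structure(list(values = vals, coverage = cov), class = "prob_trace")
}

# deterministic hill-climb to a local maximum; plateaus resolve to their
# leftmost sample, two greater neighbours resolve to the greater (left on tie)
climb_to_max <- function(v, s) {
  n <- length(v)
  repeat {
    left <- if (s > 1L) v[s - 1L] else -Inf
    right <- if (s < n) v[s + 1L] else -Inf
    if (left > v[s] || right > v[s]) {
      s <- if (left >= right) s - 1L else s + 1L
    } else if (left == v[s]) {
      s <- s - 1L
    } else {
      return(s)
    }
  }
}

#' Extract consensus R-peaks from a probability trace
#'
#' Implements the threshold / local-maximum / minimum-support rule: samples
#' with probability strictly above the threshold are candidates; each
#' candidate hill-climbs to its local maximum; a maximum gathering at least
#' `min_support` candidates (itself included when above threshold) is
#' retained as one R-peak.
#'
#' @param trace a `prob_trace` (or plain numeric vector of probabilities).
#' @param threshold probability threshold (strict; default 0.5).
#' @param min_support minimum number of supporting above-threshold samples
#'   per retained peak (default 5, matching the five-sample label masks).
#' @return A tibble of class `detected_peaks` with columns `sample_index`
#'   (0-based), `probability`, `support`.
#' @export
#' @examples
#' v <- c(rep(0, 5), 0.6, 0.8, 0.95, 0.8, 0.6, rep(0, 5))
#' extract_peaks(v)
extract_peaks <- function(trace, threshold = 0.5, min_support = 5L) {
  v <- if (inherits(trace, "prob_trace")) trace$values else as.numeric(trace)
  cand <- which(v > threshold)
  if (!length(cand)) {
    return(new_detected_peaks(integer(0), numeric(0), integer(0)))
  }
  term <- integer(length(cand))
  memo <- new.env(parent = emptyenv(), size = length(cand))
  for (i in seq_along(cand)) {
    key <- as.character(cand[i])
    t <- memo[[key]]
    if (is.null(t)) {
      t <- climb_to_max(v, cand[i])
      memo[[key]] <- t
    }
    term[i] <- t
  }
  tab <- table(term)
  keep <- as.integer(names(tab)[tab >= min_support])
  keep <- sort(keep)
  new_detected_peaks(keep - 1L, v[keep], as.integer(tab[as.character(keep)]))
}

new_detected_peaks <- function(sample_index, probability, support) {
  out <- tibble::tibble(
    sample_index = as.integer(sample_index),
    probability = as.numeric(probability),
    support = as.integer(support)
  )
  class(out) <- c("detected_peaks", class(out))
  out
}

#' Detect R-peaks in a vectorcardiogram record
#'
#' End-to-end inference: half-overlapping normalised windows, per-window
#' network prediction in evaluation mode, per-sample overlap averaging, and
#' consensus peak extraction. Indices are 0-based record coordinates at the
#' record's sampling rate.
#'
#' @param model a trained `unet_model`.
#' @param vcg a `vcg_record` (3 channels) or any record whose channel count
#'   matches the model input.
#' @param threshold,min_support see [extract_peaks()].
#' @return A `detected_peaks` tibble with an additional `time_s` column.
#' @export
detect_rpeaks <- function(model, vcg, threshold = 0.5, min_support = 5L) {
  stopifnot(inherits(model, "unet_model"))
  L <- model$config$input_length
  sig <- vcg$vectors %||% vcg$signal
  n <- nrow(sig)
  if (n < L) {
    vcg_abort(sprintf("record (%d samples) shorter than one window (%d)",
                      n, L), "vcg_record_too_short")
  }
  # pad by edge replication so the half-stride tiling covers the ragged
  # tail; the trace is trimmed back to the record length afterwards
  stride <- L %/% 2L
  pad_n <- as.integer(ceiling(max(n - L, 0) / stride) * stride + L)
  if (pad_n > n) {
    sig <- rbind(sig, sig[rep(n, pad_n - n), , drop = FALSE])
  }
  padded <- list(vectors = sig, sampling_rate = vcg$sampling_rate,
                 record_id = vcg$record_id)
  segs <- make_inference_set(padded, L)
  preds <- predict_window(model, segs$data)
  trace <- average_overlaps(preds, segs$starts, pad_n)
  trace$values <- trace$values[seq_len(n)]
  trace$coverage <- trace$coverage[seq_len(n)]
  peaks <- extract_peaks(trace, threshold, min_support)
  peaks$time_s <- peaks$sample_index / vcg$sampling_rate
  peaks
}
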