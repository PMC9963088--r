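#' Start offsets of fixed-length windows
#'
#' Returns the 0-based start offsets `0, stride, 2*stride, ...` of every
#' window that fits entirely inside the record; the ragged tail is dropped.
#'
#' @param n_samples record length in samples.
#' @param length window length in samples.
#' @param stride hop between consecutive windows in samples.
#' @return Integer vector of 0-based starts (empty when the record is shorter
#'   than one window).
#' @export
#' @examples
#' window_starts(5000, 2048, 2048) # 2 non-overlapping windows
#' length(window_starts(900000, 2048, 2048)) # 439 per 30-min 500 Hz record
window_starts <- function(n_samples, length, stride) {
  stopifnot(is_count(length), length >= 1, is_count(stride), stride >= 1)
  if (n_samples < length) return(integer(0))
  seq.int(0L, as.integer(n_samples - length), by = as.integer(stride))
}

#' Binary label mask with five-sample runs centred on each R-peak
#'
#' Marks `p - 2 ... p + 2` with ones for every peak `p` (clipped at the array
#' borders); runs of nearby peaks merge by union.
#'
#' @param n mask length in samples.
#' @param peaks sorted 0-based peak indices, all in `[0, n)`.
#' @param halfwidth samples marked on each side of a peak (default 2, i.e. a
#'   five-sample run).
#' @return Integer vector of `n` zeros and ones.
#' @export
#' @examples
#' which(build_label_mask(20, 10) == 1) - 1 # 8 9 10 11 12
build_label_mask <- function(n, peaks, halfwidth = 2L) {
  peaks <- as.integer(peaks)
  if (length(peaks) && (min(peaks) < 0L || max(peaks) >= n)) {
    vcg_abort("peak index outside [0, n)", "vcg_bad_peaks")
  }
  mask <- integer(n)
  for (p in peaks) {
    lo <- max(0L, p - halfwidth)
    hi <- min(n - 1L, p + halfwidth)
    mask[(lo + 1L):(hi + 1L)] <- 1L
  }
  mask
}

new_segment_set <- function(window_length, stride, starts, data, masks,
                            record_ids, sampling_rate) {
  structure(
    list(
      window_length = as.integer(window_length),
      stride = as.integer(stride),
      starts = as.integer(starts),
      data = data,
      masks = masks,
      record_ids = record_ids,
      sampling_rate = sampling_rate
    ),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf(
    "<segment_set: %d windows of %d samples (stride %d)%s>\n",
    length(x$data), x$window_length, x$stride,
    if (is.null(x$masks)) "" else ", labelled"
  ))
  invisible(x)
}

#' @export
length.segment_set <- function(x) length(x$data)

#' Build a labelled training set from a vectorcardiogram record
#'
#' Cuts the record into non-overlapping windows (stride equal to the window
#' length, ragged tail dropped), min-max normalises each window per channel,
#' and builds the five-sample R-peak label mask from the annotations that fall
#' inside each window (runs are truncated at window edges, never spilled into
#' a neighbour).
#'
#' @param vcg a `vcg_record` (or any object with `vectors`/`signal` matrix,
#'   `sampling_rate` and `record_id`).
#' @param annotations a [beat_annotations()] for the same record.
#' @param window_length window length in samples (default 2048, ~4 s at
#'   500 Hz).
#' @return A `segment_set` with `masks`.
#' @export
make_training_set <- function(vcg, annotations, window_length = 2048L) {
  sig <- vcg$vectors %||% vcg$signal
  n <- nrow(sig)
  starts <- window_starts(n, window_length, window_length)
  if (!length(starts)) {
    warn("record shorter than one window: empty training set")
    return(new_segment_set(window_length, window_length, integer(0),
                           list(), list(), character(0), vcg$sampling_rate))
  }
  peaks <- annotations$sample_indices
  data <- vector("list", length(starts))
  masks <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    rows <- (s + 1L):(s + window_length)
    data[[i]] <- normalize_channels(sig[rows, , drop = FALSE])
    inside <- peaks[peaks >= s & peaks < s + window_length]
    masks[[i]] <- build_label_mask(window_length, inside - s)
  }
  new_segment_set(window_length, window_length, starts, data, masks,
                  rep(vcg$record_id, length(starts)), vcg$sampling_rate)
}

#' Build a half-overlapping inference set from a vectorcardiogram record
#'
#' Windows advance by half the window length so that every sample of the
#' tiled prefix is covered once or twice; predictions from overlapping
#' windows are later averaged per sample. Windows are normalised per channel;
#' no label masks are built.
#'
#' @inheritParams make_training_set
#' @return A `segment_set` without masks.
#' @export
make_inference_set <- function(vcg, window_length = 2048L) {
  sig <- vcg$vectors %||% vcg$signal
  n <- nrow(sig)
  if (n < window_length) {
    vcg_abort(sprintf("record (%d samples) shorter than one window (%d)",
                      n, window_length), "vcg_record_too_short")
  }
  stride <- window_length %/% 2L
  starts <- window_starts(n, window_length, stride)
  data <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    rows <- (starts[i] + 1L):(starts[i] + window_length)
    data[[i]] <- normalize_channels(sig[rows, , drop = FALSE])
  }
  new_segment_set(window_length, stride, starts, data, NULL,
                  rep(vcg$record_id, length(starts)), vcg$sampling_rate)
}

#' Concatenate segment sets (e.g. across training records)
#'
#' @param sets list of `segment_set` objects with identical window length.
#' @return A single `segment_set`; masks are kept only if all inputs have
#'   them.
#' @export
bind_segment_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  wl <- unique(vapply(sets, function(s) s$window_length, integer(1)))
  if (length(wl) != 1L) {
    vcg_abort("segment sets have differing window lengths", "vcg_bad_segments")
  }
  masks <- if (all(vapply(sets, function(s) !is.null(s$masks), logical(1)))) {
    do.call(c, lapply(sets, `[[`, "masks"))
  } else {
    NULL
  }
  new_segment_set(
    wl, sets[[1L]]$stride,
    do.call(c, lapply(sets, `[[`, "starts")),
    do.call(c, lapply(sets, `[[`, "data")),
    masks,
    do.call(c, lapply(sets, `[[`, "record_ids")),
    sets[[1L]]$sampling_rate
  )
}
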