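#' Kors regression transformation matrix
#'
#' The published 8x3 regression coefficients mapping the eight independent
#' ECG leads (rows, in order I, II, V1-V6) to the three vectorcardiogram axes
#' (columns X, Y, Z).
#'
#' @return An 8x3 numeric matrix with dimnames.
#' @export
#' @examples
#' kors_matrix()["I", ]
kors_matrix <- function() {
  m <- matrix(c(
     0.38, -0.07,  0.11,
    -0.07,  0.93, -0.23,
    -0.13,  0.06, -0.43,
     0.05, -0.02, -0.06,
    -0.01, -0.05, -0.14,
     0.14,  0.06, -0.20,
     0.06, -0.17, -0.11,
     0.54,  0.13,  0.31
  ), nrow = 8, byrow = TRUE,
  dimnames = list(KORS_LEADS, c("X", "Y", "Z")))
  m
}

#' Convert an 8-lead ECG record to a 3D vectorcardiogram
#'
#' Applies the Kors regression transformation `V = E %*% M`, where each row of
#' `E` holds the eight lead values of one sample. The record must carry
#' exactly the leads I, II, V1-V6 in that order; a 12-lead record should be
#' reduced first with [select_leads()] (the derived leads III, aVR, aVL, aVF
#' add no information and are refused rather than silently dropped).
#'
#' @param record an [ecg_record()] with exactly the 8 independent leads in
#'   canonical order.
#' @return An object of class `vcg_record` with a `n_samples x 3` matrix
#'   `vectors` (columns X, Y, Z).
#' @export
kors_transform <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  if (!identical(record$lead_names, KORS_LEADS)) {
    bad <- if (length(record$lead_names) != 8L) {
      sprintf("got %d leads", length(record$lead_names))
    } else {
      mism <- which(record$lead_names != KORS_LEADS)[1L]
      sprintf("lead %d is '%s', expected '%s'",
              mism, record$lead_names[mism], KORS_LEADS[mism])
    }
    vcg_abort(
      sprintf("record must have leads %s in order (%s); use select_leads()",
              paste(KORS_LEADS, collapse = ", "), bad),
      "vcg_bad_leads"
    )
  }
  vectors <- record$signal %*% kors_matrix()
  structure(
    list(
      record_id = record$record_id,
      sampling_rate = record$sampling_rate,
      vectors = vectors,
      n_samples = nrow(vectors)
    ),
    class = "vcg_record"
  )
}

#' @export
print.vcg_record <- function(x, ...) {
  cat(sprintf(
    "<vcg_record '%s': %d samples @ %g Hz (X, Y, Z)>\n",
    x$record_id, x$n_samples, x$sampling_rate
  ))
  invisible(x)
}

#' Min-max scale each channel to [-1, 1]
#'
#' Each column is scaled independently so that its minimum maps to -1 and its
#' maximum to +1. A constant column cannot be scaled and maps to all zeros
#' (with a warning).
#'
#' @param segment numeric matrix (samples x channels) or vector.
#' @return Matrix of the same shape with every non-constant column spanning
#'   exactly `[-1, 1]`.
#' @export
#' @examples
#' normalize_channels(matrix(c(0, 5, 10), ncol = 1))
normalize_channels <- function(segment) {
  x <- as.matrix(segment)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    warn("constant channel(s) mapped to zero during normalization")
    rng[flat] <- 1
  }
  out <- 2 * (x - rep(lo, each = nrow(x))) / rep(rng, each = nrow(x)) - 1
  out[, flat] <- 0
  out
}
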