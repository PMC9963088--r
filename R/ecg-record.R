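#' Multi-lead ECG record
#'
#' Light container for a uniformly sampled multi-lead ECG. The signal is a
#' numeric matrix with one row per sample and one column per lead, in
#' millivolts. Lead names follow the usual clinical labels; the eight
#' independent leads of a 12-lead acquisition are I, II and V1-V6 (III, aVR,
#' aVL and aVF are linear combinations of I and II and carry no extra
#' information).
#'
#' @param signal numeric matrix, `n_samples x n_leads`, millivolts.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param lead_names character vector of unique lead names, one per column.
#' @param record_id record identifier.
#' @return An object of class `ecg_record` with fields `record_id`,
#'   `sampling_rate`, `lead_names`, `signal`, `n_samples`.
#' @export
#' @examples
#' rec <- ecg_record(matrix(0, 100, 2), 500, c("I", "II"))
#' rec$n_samples
ecg_record <- function(signal, sampling_rate, lead_names,
                       record_id = "record") {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    vcg_abort("`sampling_rate` must be a positive number", "vcg_bad_record")
  }
  if (nrow(signal) < 1L) {
    vcg_abort("record must contain at least one sample", "vcg_bad_record")
  }
  lead_names <- as.character(lead_names)
  if (length(lead_names) != ncol(signal)) {
    vcg_abort("one lead name per signal column is required", "vcg_bad_record")
  }
  if (anyDuplicated(lead_names)) {
    vcg_abort("lead names must be unique", "vcg_bad_record")
  }
  colnames(signal) <- lead_names
  structure(
    list(
      record_id = as.character(record_id),
      sampling_rate = as.numeric(sampling_rate),
      lead_names = lead_names,
      signal = signal,
      n_samples = nrow(signal)
    ),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record '%s': %d samples @ %g Hz (%.1f s), leads: %s>\n",
    x$record_id, x$n_samples, x$sampling_rate,
    x$n_samples / x$sampling_rate, paste(x$lead_names, collapse = ", ")
  ))
  invisible(x)
}

#' Ground-truth beat annotations
#'
#' Sorted 0-based sample indices of annotated R-peaks for one record. The
#' reference lead records which lead's timing convention the annotations
#' follow (lead II in the databases this package targets).
#'
#' @param sample_indices integer vector of 0-based sample indices.
#' @param record_id record identifier.
#' @param reference_lead lead whose timings the annotations follow.
#' @param n_samples optional record length used to validate the range.
#' @return An object of class `beat_annotations`.
#' @export
beat_annotations <- function(sample_indices, record_id = "record",
                             reference_lead = "II", n_samples = NULL) {
  idx <- sort(unique(as.integer(round(sample_indices))))
  if (any(idx < 0L)) {
    vcg_abort("annotation indices must be >= 0", "vcg_bad_annotations")
  }
  if (!is.null(n_samples) && length(idx) && max(idx) >= n_samples) {
    vcg_abort("annotation index beyond record end", "vcg_bad_annotations")
  }
  structure(
    list(
      record_id = as.character(record_id),
      sample_indices = idx,
      reference_lead = as.character(reference_lead)
    ),
    class = "beat_annotations"
  )
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf(
    "<beat_annotations '%s': %d beats (lead %s)>\n",
    x$record_id, length(x$sample_indices), x$reference_lead
  ))
  invisible(x)
}

#' @export
length.beat_annotations <- function(x) length(x$sample_indices)

#' Reorder or subset the leads of an ECG record
#'
#' @param record an [ecg_record()].
#' @param leads requested lead names, in the requested output order.
#' @return An `ecg_record` whose columns are exactly `leads`, in order.
#' @export
select_leads <- function(record, leads) {
  missing <- setdiff(leads, record$lead_names)
  if (length(missing)) {
    vcg_abort(
      sprintf("lead(s) not found in record: %s", paste(missing, collapse = ", ")),
      "vcg_lead_not_found"
    )
  }
  ecg_record(
    record$signal[, leads, drop = FALSE],
    record$sampling_rate, leads, record$record_id
  )
}

# canonical order of the 8 independent leads
KORS_LEADS <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
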