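#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   facet_wrap labs theme_minimal geom_hline
#' @export
ggplot2::autoplot

#' Plot a multi-lead ECG record
#'
#' @param object an `ecg_record`.
#' @param from,to time range to show, seconds.
#' @param ... unused.
#' @return A ggplot with one facet per lead.
#' @export
autoplot.ecg_record <- function(object, from = 0,
                                to = min(10, object$n_samples /
                                           object$sampling_rate), ...) {
  fs <- object$sampling_rate
  rows <- seq(max(1L, floor(from * fs) + 1L), min(object$n_samples,
                                                  ceiling(to * fs)))
  df <- tibble::tibble(
    time_s = rep((rows - 1) / fs, times = length(object$lead_names)),
    mV = as.vector(object$signal[rows, ]),
    lead = factor(rep(object$lead_names, each = length(rows)),
                  levels = object$lead_names)
  )
  ggplot(df, aes(.data$time_s, .data$mV)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~lead, ncol = 1, strip.position = "right") +
    labs(x = "time (s)", y = "amplitude (mV)", title = object$record_id) +
    theme_minimal()
}

#' Plot a vectorcardiogram record
#'
#' @param object a `vcg_record`.
#' @inheritParams autoplot.ecg_record
#' @export
autoplot.vcg_record <- function(object, from = 0,
                                to = min(10, object$n_samples /
                                           object$sampling_rate), ...) {
  fs <- object$sampling_rate
  rows <- seq(max(1L, floor(from * fs) + 1L), min(object$n_samples,
                                                  ceiling(to * fs)))
  df <- tibble::tibble(
    time_s = rep((rows - 1) / fs, times = 3),
    mV = as.vector(object$vectors[rows, ]),
    axis = factor(rep(c("X", "Y", "Z"), each = length(rows)),
                  levels = c("X", "Y", "Z"))
  )
  ggplot(df, aes(.data$time_s, .data$mV)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~axis, ncol = 1, strip.position = "right") +
    labs(x = "time (s)", y = "amplitude (mV)", title = object$record_id) +
    theme_minimal()
}

#' Plot a probability trace with detected peaks
#'
#' @param object a `prob_trace`.
#' @param peaks optional `detected_peaks` to overlay.
#' @param fs sampling rate for the time axis (samples when omitted).
#' @param ... unused.
#' @export
autoplot.prob_trace <- function(object, peaks = NULL, fs = NULL, ...) {
  xx <- seq_along(object$values) - 1
  xlab <- "sample"
  if (!is.null(fs)) {
    xx <- xx / fs
    xlab <- "time (s)"
  }
  g <- ggplot(tibble::tibble(x = xx, p = object$values),
              aes(.data$x, .data$p)) +
    geom_line(linewidth = 0.3) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    labs(x = xlab, y = "R-peak probability") +
    theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    px <- peaks$sample_index
    if (!is.null(fs)) px <- px / fs
    g <- g + geom_point(
      data = tibble::tibble(x = px, p = peaks$probability),
      aes(.data$x, .data$p), colour = "red", shape = 17, size = 2
    )
  }
  g
}

#' Plot the training loss curve
#'
#' @param object a `unet_fit`.
#' @param ... unused.
#' @export
autoplot.unet_fit <- function(object, ...) {
  ggplot(object$history, aes(.data$epoch, .data$loss)) +
    geom_line() +
    labs(x = "epoch", y = "binary cross-entropy") +
    theme_minimal()
}

#' Overlay detections and reference annotations on one lead
#'
#' @param record an `ecg_record` (or `vcg_record`).
#' @param detections `detected_peaks`.
#' @param annotations optional [beat_annotations()].
#' @param lead lead (or axis) to show.
#' @param from,to time range, seconds.
#' @return A ggplot.
#' @export
plot_detections <- function(record, detections, annotations = NULL,
                            lead = "II", from = 0, to = 10) {
  fs <- record$sampling_rate
  sig <- if (inherits(record, "vcg_record")) record$vectors else record$signal
  rows <- seq(max(1L, floor(from * fs) + 1L),
              min(nrow(sig), ceiling(to * fs)))
  df <- tibble::tibble(time_s = (rows - 1) / fs, mV = sig[rows, lead])
  g <- ggplot(df, aes(.data$time_s, .data$mV)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = sprintf("%s (mV)", lead)) +
    theme_minimal()
  det_t <- detections$sample_index / fs
  det_t <- det_t[det_t >= from & det_t <= to]
  if (length(det_t)) {
    g <- g + geom_vline(xintercept = det_t, colour = "red",
                        linetype = "solid", alpha = 0.5)
  }
  if (!is.null(annotations)) {
    ann_t <- annotations$sample_indices / fs
    ann_t <- ann_t[ann_t >= from & ann_t <= to]
    if (length(ann_t)) {
      g <- g + geom_vline(xintercept = ann_t, colour = "blue",
                          linetype = "dotted")
    }
  }
  g
}
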