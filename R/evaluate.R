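#' Restrict detections to the annotated span of a record
#'
#' Records are only scored over their annotated cardiac cycles:
#' detections earlier than the first annotation minus the tolerance, or later
#' than the last annotation plus the tolerance, are dropped (un-annotated
#' first/last cycles must not count as false positives).
#'
#' @param detections a `detected_peaks` tibble (column `sample_index`).
#' @param annotations a [beat_annotations()].
#' @param fs sampling rate in Hz.
#' @param tolerance_ms tolerance in milliseconds (default 75).
#' @return The filtered `detected_peaks`.
#' @export
restrict_to_annotated_span <- function(detections, annotations, fs,
                                       tolerance_ms = 75) {
  if (!length(annotations$sample_indices)) {
    vcg_abort("annotations are empty", "vcg_empty_annotations")
  }
  tol <- tolerance_ms / 1000 * fs
  lo <- min(annotations$sample_indices) - tol
  hi <- max(annotations$sample_indices) + tol
  detections[detections$sample_index >= lo & detections$sample_index <= hi, ]
}

#' Match detections to annotations within a time tolerance
#'
#' One-to-one greedy matching: all (annotation, detection) pairs within the
#' tolerance (inclusive, compared in seconds) are considered in increasing
#' order of absolute time difference (ties favour the earlier annotation);
#' each annotation and detection is used at most once. Unmatched annotations
#' are false negatives, unmatched detections false positives.
#'
#' @param detections `detected_peaks` tibble or integer vector of 0-based
#'   sample indices.
#' @param annotations [beat_annotations()] or integer vector.
#' @param fs sampling rate in Hz.
#' @param tolerance_ms tolerance in milliseconds (default 75, half the
#'   maximum QRS duration).
#' @return An object of class `match_result`: tibble `pairs` (columns
#'   `annotation`, `detection`, `dt_ms`), integer vectors `fn` and `fp`,
#'   and the tolerance.
#' @export
match_peaks <- function(detections, annotations, fs, tolerance_ms = 75) {
  det <- if (is.data.frame(detections)) detections$sample_index else
    as.integer(detections)
  ann <- if (inherits(annotations, "beat_annotations"))
    annotations$sample_indices else as.integer(annotations)
  det <- sort(det)
  ann <- sort(ann)
  tol_s <- tolerance_ms / 1000
  pairs <- tibble::tibble(annotation = integer(0), detection = integer(0),
                          dt_ms = numeric(0))
  if (length(det) && length(ann)) {
    dt <- abs(outer(ann, det, `-`)) / fs
    ok <- which(dt <= tol_s, arr.ind = TRUE)
    if (nrow(ok)) {
      ord <- order(dt[ok], ann[ok[, 1L]], det[ok[, 2L]])
      ok <- ok[ord, , drop = FALSE]
      used_a <- logical(length(ann))
      used_d <- logical(length(det))
      keep_a <- integer(0)
      keep_d <- integer(0)
      for (r in seq_len(nrow(ok))) {
        ia <- ok[r, 1L]
        id <- ok[r, 2L]
        if (!used_a[ia] && !used_d[id]) {
          used_a[ia] <- TRUE
          used_d[id] <- TRUE
          keep_a <- c(keep_a, ia)
          keep_d <- c(keep_d, id)
        }
      }
      ordp <- order(ann[keep_a])
      pairs <- tibble::tibble(
        annotation = ann[keep_a][ordp],
        detection = det[keep_d][ordp],
        dt_ms = (det[keep_d][ordp] - ann[keep_a][ordp]) / fs * 1000
      )
    }
  }
  structure(
    list(
      pairs = pairs,
      fn = setdiff(ann, pairs$annotation),
      fp = setdiff(det, pairs$detection),
      tolerance_ms = tolerance_ms,
      fs = fs
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: TP %d, FN %d, FP %d (tol %g ms)>\n",
              nrow(x$pairs), length(x$fn), length(x$fp), x$tolerance_ms))
  invisible(x)
}

#' Detection metrics from matched counts
#'
#' Recall = 100 TP / (TP + FN), precision = 100 TP / (TP + FP), F1 their
#' harmonic mean, all in percent. A metric whose denominator is zero is
#' undefined and reported as `NA` (never as 0 or 100).
#'
#' @param match a `match_result`, or `NULL` if counts are given directly.
#' @param tp,fn,fp counts, taken from `match` when supplied.
#' @return A one-row tibble of class `metrics_report` with columns `tp`,
#'   `fn`, `fp`, `recall`, `precision`, `f1`.
#' @export
#' @examples
#' compute_metrics(tp = 175631, fn = 276, fp = 16)
compute_metrics <- function(match = NULL, tp = NULL, fn = NULL, fp = NULL) {
  if (!is.null(match)) {
    stopifnot(inherits(match, "match_result"))
    tp <- nrow(match$pairs)
    fn <- length(match$fn)
    fp <- length(match$fp)
  }
  if (tp + fn == 0 && tp + fp == 0) {
    warn("no annotations and no detections: metrics undefined")
  }
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  out <- tibble::tibble(tp = as.integer(tp), fn = as.integer(fn),
                        fp = as.integer(fp),
                        recall = recall, precision = precision, f1 = f1)
  class(out) <- c("metrics_report", class(out))
  out
}

#' Aggregate per-record metrics
#'
#' Pooled aggregation sums the TP/FN/FP counts and applies the metric
#' formulas once; macro aggregation takes the unweighted mean of the defined
#' per-record percentages (records with undefined metrics are dropped from
#' the corresponding mean with a warning). Macro F1 is reported both ways:
#' `f1` is the harmonic mean of macro recall and macro precision, and
#' `f1_mean` is the mean of the per-record F1 scores.
#'
#' @param reports a `metrics_report` tibble with one row per record (rows
#'   are simply stacked [compute_metrics()] outputs).
#' @param mode `"pooled"` or `"macro"`.
#' @return A one-row `metrics_report` tibble (macro mode adds `f1_mean`).
#' @export
aggregate_metrics <- function(reports, mode = c("pooled", "macro")) {
  mode <- match.arg(mode)
  if (!nrow(reports)) vcg_abort("no reports to aggregate", "vcg_empty_reports")
  if (mode == "pooled") {
    return(compute_metrics(tp = sum(reports$tp), fn = sum(reports$fn),
                           fp = sum(reports$fp)))
  }
  mean_def <- function(x, what) {
    if (anyNA(x)) {
      warn(sprintf("record(s) with undefined %s excluded from macro average",
                   what),
           class = "vcg_undefined_metric")
    }
    mean(x, na.rm = TRUE)
  }
  recall <- mean_def(reports$recall, "recall")
  precision <- mean_def(reports$precision, "precision")
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    tp = sum(reports$tp), fn = sum(reports$fn), fp = sum(reports$fp),
    recall = recall, precision = precision, f1 = f1,
    f1_mean = mean_def(reports$f1, "F1")
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Heart-rate and heart-rate-variability summary
#'
#' RR intervals are successive beat-to-beat differences in seconds;
#' instantaneous heart rate is 60/RR. `avg_hr` and `sd_hr` are the mean and
#' (population) standard deviation of the instantaneous heart rates, and
#' `rmssd` is the root mean square of successive RR differences in
#' milliseconds. With several records, intervals are formed within each
#' record only (never across a record boundary) and the statistics are pooled
#' over the concatenated interval lists.
#'
#' @param beats sorted 0-based beat sample indices, or a list of such vectors
#'   (one per record).
#' @param fs sampling rate in Hz.
#' @return A one-row tibble of class `hrv_summary` with columns `avg_hr`,
#'   `sd_hr` (beats/min), `rmssd` (ms) and `n_beats`; statistics that need
#'   more beats than available are `NA`.
#' @export
#' @examples
#' hrv_summary(seq(0, 4500, by = 500), fs = 500) # 60 bpm, rmssd 0
hrv_summary <- function(beats, fs) {
  recs <- if (is.list(beats)) beats else list(beats)
  rr <- lapply(recs, function(b) diff(sort(as.numeric(b))) / fs)
  drr <- lapply(rr, diff)
  rr_all <- unlist(rr, use.names = FALSE)
  drr_all <- unlist(drr, use.names = FALSE)
  n_beats <- sum(lengths(recs))
  hr <- 60 / rr_all
  avg_hr <- if (length(hr) >= 1) mean(hr) else NA_real_
  sd_hr <- if (length(hr) >= 2) sqrt(mean((hr - mean(hr))^2)) else NA_real_
  rmssd <- if (length(drr_all) >= 1) 1000 * sqrt(mean(drr_all^2)) else NA_real_
  out <- tibble::tibble(avg_hr = avg_hr, sd_hr = sd_hr, rmssd = rmssd,
                        n_beats = n_beats)
  class(out) <- c("hrv_summary", class(out))
  out
}

#' Score one record end to end
#'
#' Restricts detections to the annotated span, matches them at the tolerance,
#' and computes the metrics.
#'
#' @inheritParams match_peaks
#' @return A `metrics_report` row with the record id attached.
#' @export
score_record <- function(detections, annotations, fs, tolerance_ms = 75) {
  kept <- restrict_to_annotated_span(detections, annotations, fs, tolerance_ms)
  m <- match_peaks(kept, annotations, fs, tolerance_ms)
  rep <- compute_metrics(m)
  rep$record_id <- if (inherits(annotations, "beat_annotations"))
    annotations$record_id else NA_character_
  rep
}
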