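#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a fitted network
#'
#' @param x a `unet_fit`.
#' @param ... unused.
#' @return Tibble with `epoch` and `loss`.
#' @export
tidy.unet_fit <- function(x, ...) x$history

#' One-row summary of a fitted network
#'
#' @param x a `unet_fit`.
#' @param ... unused.
#' @return Tibble with `epochs`, `best_loss`, `parameters`.
#' @export
glance.unet_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_loss = min(x$history$loss),
    parameters = count_parameters(x$model)
  )
}

#' Per-event view of a peak-matching result
#'
#' @param x a `match_result`.
#' @param ... unused.
#' @return Tibble with one row per event: `type` (TP/FN/FP), `annotation`,
#'   `detection`, `dt_ms`.
#' @export
tidy.match_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$pairs, type = "TP"),
    tibble::tibble(annotation = x$fn, detection = NA_integer_,
                   dt_ms = NA_real_, type = "FN"),
    tibble::tibble(annotation = NA_integer_, detection = x$fp,
                   dt_ms = NA_real_, type = "FP")
  )
}

#' Counts and metrics of a peak-matching result
#'
#' @param x a `match_result`.
#' @param ... unused.
#' @return A one-row `metrics_report` tibble.
#' @export
glance.match_result <- function(x, ...) compute_metrics(x)

#' Per-record metrics of a leave-one-out run
#'
#' @param x a `loo_result`.
#' @param ... unused.
#' @export
tidy.loo_result <- function(x, ...) x$per_record

#' Aggregated metrics of a leave-one-out run
#'
#' @param x a `loo_result`.
#' @param ... unused.
#' @return One-row tibble: pooled counts and both aggregations' percentages.
#' @export
glance.loo_result <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$per_record),
    tp = x$pooled$tp, fn = x$pooled$fn, fp = x$pooled$fp,
    recall_pooled = x$pooled$recall, precision_pooled = x$pooled$precision,
    f1_pooled = x$pooled$f1,
    recall_macro = x$macro$recall, precision_macro = x$macro$precision,
    f1_macro = x$macro$f1
  )
}

#' Per-record metrics of a cross-database run
#'
#' @param x a `crossdb_result`.
#' @param ... unused.
#' @export
tidy.crossdb_result <- function(x, ...) x$per_record

#' Pooled metrics of a cross-database run
#'
#' @param x a `crossdb_result`.
#' @param ... unused.
#' @export
glance.crossdb_result <- function(x, ...) x$pooled
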