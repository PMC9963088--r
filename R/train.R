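#' Training hyperparameters
#'
#' Defaults follow the study protocol: Adam with learning rate 0.001, binary
#' cross-entropy loss, no weight decay, up to 500 epochs with early stopping
#' at a patience of 10 epochs, batch size 64.
#'
#' @param learning_rate Adam learning rate.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience in epochs; training stops when the
#'   monitored training loss has not strictly improved (by more than 1e-6)
#'   for this many consecutive epochs, and the best-loss weights are
#'   restored.
#' @param batch_size windows per optimisation step.
#' @param random_seed seed controlling shuffling, dropout and (when a model
#'   is built inside a protocol) weight initialisation.
#' @param verbose print per-epoch losses.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 500L,
                         patience = 10L, batch_size = 64L,
                         random_seed = 1L, verbose = FALSE) {
  structure(
    list(
      learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
      patience = as.integer(patience), batch_size = as.integer(batch_size),
      random_seed = as.integer(random_seed), verbose = isTRUE(verbose)
    ),
    class = "train_config"
  )
}

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the segmentation network
#'
#' Minimises the mean binary cross-entropy between the per-sample probability
#' map and the five-sample R-peak label masks with Adam. Windows are
#' reshuffled every epoch; the monitored quantity for early stopping is the
#' epoch-mean training loss, and the weights of the best epoch are restored
#' at the end. With a fixed seed the loss history is reproducible.
#'
#' @param model a `unet_model`.
#' @param segments a labelled `segment_set` (from [make_training_set()] /
#'   [bind_segment_sets()]).
#' @param config a [train_config()].
#' @return A list of class `unet_fit`: `model` (trained), `history` (tibble
#'   with `epoch`, `loss`), `config`.
#' @export
train_unet <- function(model, segments, config = train_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(segments, "segment_set"))
  if (!length(segments$data)) {
    vcg_abort("training set is empty", "vcg_empty_training")
  }
  if (is.null(segments$masks)) {
    vcg_abort("training requires a labelled segment set", "vcg_no_masks")
  }
  set.seed(config$random_seed)
  L <- model$config$input_length
  n_win <- length(segments$data)
  opt <- adam_init(model$params)
  best_loss <- Inf
  best <- NULL
  wait <- 0L
  history <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_win)
    ep_loss <- 0
    ep_n <- 0L
    i <- 1L
    while (i <= n_win) {
      idx <- ord[i:min(i + config$batch_size - 1L, n_win)]
      N <- length(idx)
      X <- do.call(rbind, segments$data[idx])
      y <- unlist(segments$masks[idx], use.names = FALSE)
      fw <- unet_forward(model, X, N, training = TRUE)
      model <- fw$model # batch-norm running statistics advance
      p <- fw$prob
      loss <- bce_loss(p, y)
      dlogit <- matrix((p - y) / length(y), ncol = 1L)
      grads <- unet_backward(model, fw$cache, dlogit, N)
      st <- adam_step(model$params, grads, opt, lr = config$learning_rate)
      model$params <- st$params
      opt <- st$opt
      ep_loss <- ep_loss + loss * N
      ep_n <- ep_n + N
      i <- i + config$batch_size
    }
    ep_loss <- ep_loss / ep_n
    history <- c(history, ep_loss)
    if (config$verbose) {
      message(sprintf("epoch %d: loss %.6f", epoch, ep_loss))
    }
    if (ep_loss < best_loss - 1e-6) {
      best_loss <- ep_loss
      best <- list(params = model$params, state = model$state)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  if (!is.null(best)) {
    model$params <- best$params
    model$state <- best$state
  }
  model$trained <- TRUE
  structure(
    list(
      model = model,
      history = tibble::tibble(epoch = seq_along(history), loss = history),
      config = config
    ),
    class = "unet_fit"
  )
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit: %d epochs, best loss %.6f>\n",
              nrow(x$history), min(x$history$loss)))
  invisible(x)
}

# shared scoring helper used by both protocols
score_detections <- function(model, vcg, ann, tolerance_ms = 75) {
  det <- detect_rpeaks(model, vcg)
  score_record(det, ann, vcg$sampling_rate, tolerance_ms)
}

#' Leave-one-out cross-validation over a set of records
#'
#' For each record, a fresh model is trained on the windows of all other
#' records and evaluated on the held-out one. Returns per-record reports plus
#' macro (unweighted mean of per-record percentages) and pooled (summed
#' counts) aggregates. Records without annotations cannot be scored and are
#' excluded from the aggregates with a warning.
#'
#' @param records list of `list(vcg = , annotations = )` pairs.
#' @param config a [train_config()].
#' @param model_config a [unet_config()].
#' @param tolerance_ms scoring tolerance.
#' @return A list of class `loo_result`: `per_record` (metrics tibble),
#'   `macro`, `pooled`.
#' @export
run_leave_one_out <- function(records, config = train_config(),
                              model_config = unet_config(),
                              tolerance_ms = 75) {
  stopifnot(length(records) >= 2)
  reports <- vector("list", length(records))
  for (i in seq_along(records)) {
    train_idx <- setdiff(seq_along(records), i)
    segs <- bind_segment_sets(lapply(records[train_idx], function(r) {
      make_training_set(r$vcg, r$annotations, model_config$input_length)
    }))
    model <- build_unet(model_config, seed = config$random_seed)
    fit <- train_unet(model, segs, config)
    held <- records[[i]]
    if (!length(held$annotations$sample_indices)) {
      warn(sprintf("record %d has no annotations and is excluded from aggregates", i),
           class = "vcg_unscoreable_record")
      next
    }
    reports[[i]] <- score_detections(fit$model, held$vcg, held$annotations,
                                     tolerance_ms)
  }
  per_record <- dplyr::bind_rows(reports)
  list_out <- list(
    per_record = per_record,
    macro = aggregate_metrics(per_record, "macro"),
    pooled = aggregate_metrics(per_record, "pooled")
  )
  structure(list_out, class = "loo_result")
}

#' Cross-database validation
#'
#' Trains one model on every training record and scores it on every test
#' record; returns the per-record reports and the pooled aggregate.
#'
#' @param train_records,test_records lists of `list(vcg = , annotations = )`;
#'   record identifiers must not overlap.
#' @inheritParams run_leave_one_out
#' @return A list of class `crossdb_result`: `fit`, `per_record`, `pooled`,
#'   `macro`.
#' @export
run_cross_database <- function(train_records, test_records,
                               config = train_config(),
                               model_config = unet_config(),
                               tolerance_ms = 75) {
  if (!length(test_records)) {
    vcg_abort("test set is empty", "vcg_bad_protocol")
  }
  train_ids <- vapply(train_records, function(r) r$vcg$record_id, character(1))
  test_ids <- vapply(test_records, function(r) r$vcg$record_id, character(1))
  if (length(intersect(train_ids, test_ids))) {
    vcg_abort("training and test record identifiers overlap",
              "vcg_bad_protocol")
  }
  segs <- bind_segment_sets(lapply(train_records, function(r) {
    make_training_set(r$vcg, r$annotations, model_config$input_length)
  }))
  model <- build_unet(model_config, seed = config$random_seed)
  fit <- train_unet(model, segs, config)
  reports <- lapply(test_records, function(r) {
    score_detections(fit$model, r$vcg, r$annotations, tolerance_ms)
  })
  per_record <- dplyr::bind_rows(reports)
  structure(
    list(
      fit = fit,
      per_record = per_record,
      pooled = aggregate_metrics(per_record, "pooled"),
      macro = aggregate_metrics(per_record, "macro")
    ),
    class = "crossdb_result"
  )
}
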