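# training tests run on reduced window lengths so each optimisation step is
# cheap; the full-size end-to-end experiment lives in test-acceptance.R

test_that("training rejects unlabelled or empty segment sets", {
  cfg <- tiny_unet_config()
  m <- build_unet(cfg, seed = 1)
  empty <- vcgrpeak:::new_segment_set(64L, 64L, integer(0), list(), list(),
                                      character(0), 500)
  expect_error(train_unet(m, empty), class = "vcg_empty_training")
  nolab <- vcgrpeak:::new_segment_set(64L, 64L, 0L,
                                      list(matrix(0, 64, 2)), NULL, "r", 500)
  expect_error(train_unet(m, nolab), class = "vcg_no_masks")
})

test_that("a single repeated window is overfit to near-zero loss", {
  withr::local_seed(51)
  cfg <- tiny_unet_config(input_length = 256L, in_channels = 3L)
  w <- normalize_channels(matrix(rnorm(256 * 3), 256, 3))
  mask <- build_label_mask(256, c(60L, 180L))
  segs <- duplicated_window_set(w, mask, 16L)
  m <- build_unet(cfg, seed = 2)
  fit <- train_unet(m, segs, train_config(max_epochs = 400, random_seed = 3))
  expect_lt(min(fit$history$loss), 0.01)
  p <- predict_window(fit$model, w)
  expect_gt(min(p[mask == 1]), 0.5)
})

test_that("a fixed seed reproduces the loss history exactly", {
  cfg <- tiny_unet_config(input_length = 64L)
  withr::local_seed(52)
  wins <- lapply(1:12, function(i) {
    normalize_channels(matrix(rnorm(64 * 2), 64, 2))
  })
  masks <- lapply(1:12, function(i) build_label_mask(64, sample(5:58, 1)))
  segs <- vcgrpeak:::new_segment_set(64L, 64L, rep(0L, 12), wins, masks,
                                     rep("r", 12), 500)
  run <- function() {
    m <- build_unet(cfg, seed = 5)
    train_unet(m, segs, train_config(max_epochs = 6, batch_size = 4,
                                     random_seed = 6))$history
  }
  expect_identical(run(), run())
})

test_that("early stopping fires patience epochs after the last improvement", {
  # learning rate zero freezes the loss: the first epoch is the only
  # improvement, so training must stop after exactly 1 + patience epochs
  cfg <- tiny_unet_config(input_length = 64L, dropout_rate = 0)
  withr::local_seed(53)
  w <- normalize_channels(matrix(rnorm(64 * 2), 64, 2))
  segs <- duplicated_window_set(w, build_label_mask(64, 30L), 4L)
  m <- build_unet(cfg, seed = 7)
  fit <- train_unet(m, segs,
                    train_config(learning_rate = 0, max_epochs = 100,
                                 patience = 4, random_seed = 8))
  expect_identical(nrow(fit$history), 1L + 4L)
  # and the cap applies when improvement continues
  fit2 <- train_unet(build_unet(cfg, seed = 7), segs,
                     train_config(max_epochs = 3, random_seed = 8))
  expect_identical(nrow(fit2$history), 3L)
})

test_that("leave-one-out isolates the held-out record and reports all folds", {
  withr::local_seed(54)
  cfg <- tiny_unet_config(input_length = 64L, in_channels = 3L)
  make_rec <- function(id, n_ann = 4L) {
    n <- 64L * 4L
    ann <- if (n_ann > 0) sort(sample(5:(n - 5), n_ann)) else integer(0)
    list(
      vcg = list(vectors = matrix(rnorm(n * 3), n, 3), sampling_rate = 500,
                 record_id = id),
      annotations = beat_annotations(ann, id, n_samples = n)
    )
  }
  records <- list(make_rec("a"), make_rec("b"), make_rec("c"))
  # untrained folds may detect nothing: undefined-precision warnings expected
  res <- suppressWarnings(
    run_leave_one_out(records, train_config(max_epochs = 1, random_seed = 9),
                      model_config = cfg),
    classes = "vcg_undefined_metric"
  )
  expect_identical(nrow(res$per_record), 3L)
  # conservation per record: TP + FN equals the number of annotations
  for (i in 1:3) {
    expect_identical(res$per_record$tp[i] + res$per_record$fn[i],
                     length(records[[i]]$annotations$sample_indices))
  }
  # a record without annotations is excluded from the aggregates
  records[[2]] <- make_rec("b", n_ann = 0L)
  expect_warning(
    res2 <- suppressWarnings(
      run_leave_one_out(records, train_config(max_epochs = 1,
                                              random_seed = 9),
                        model_config = cfg),
      classes = "vcg_undefined_metric"
    ),
    class = "vcg_unscoreable_record"
  )
  expect_identical(nrow(res2$per_record), 2L)
})

test_that("cross-database protocol enforces disjoint train/test sets", {
  withr::local_seed(55)
  cfg <- tiny_unet_config(input_length = 64L, in_channels = 3L)
  mk <- function(id) {
    n <- 64L * 3L
    list(vcg = list(vectors = matrix(rnorm(n * 3), n, 3),
                    sampling_rate = 500, record_id = id),
         annotations = beat_annotations(c(30L, 100L), id, n_samples = n))
  }
  tr <- list(mk("t1"), mk("t2"))
  te <- list(mk("e1"))
  res <- suppressWarnings(
    run_cross_database(tr, te, train_config(max_epochs = 1, random_seed = 10),
                       model_config = cfg),
    classes = "vcg_undefined_metric"
  )
  expect_s3_class(res$pooled, "metrics_report")
  expect_true(all(c(res$pooled$tp, res$pooled$fn, res$pooled$fp) >= 0))
  expect_lte(res$pooled$tp, 2L)
  expect_error(run_cross_database(tr, list(mk("t1")),
                                  model_config = cfg),
               class = "vcg_bad_protocol")
  expect_error(run_cross_database(tr, list(), model_config = cfg),
               class = "vcg_bad_protocol")
})

test_that("tidy and glance summarise a fit", {
  withr::local_seed(56)
  cfg <- tiny_unet_config(input_length = 64L)
  w <- normalize_channels(matrix(rnorm(64 * 2), 64, 2))
  segs <- duplicated_window_set(w, build_label_mask(64, 30L), 4L)
  fit <- train_unet(build_unet(cfg, seed = 1), segs,
                    train_config(max_epochs = 2, random_seed = 2))
  expect_identical(generics::tidy(fit), fit$history)
  g <- generics::glance(fit)
  expect_identical(g$epochs, 2L)
  expect_identical(g$parameters, count_parameters(fit$model))
})
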