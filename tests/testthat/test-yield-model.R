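yield_fixture <- function(n = 30L, seed = 41L) {
  d <- make_synthetic_dataset(tiny_spec(n = n, seed = seed))
  d <- stratified_split(d, ratio = c(4L, 1L, 1L), seed = 2L)
  v <- tiny_vocab_for(d)
  list(d = d, model = tiny_model_for(v))
}

test_that("the supervised loss is the sum of squared errors", {
  expect_equal(stage2_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(stage2_loss(c(1, 0), c(0, 0)), 1)
  expect_equal(stage2_loss(0.5, 0.1), 0.16)
  expect_error(stage2_loss(c(1, 2), 1), "lengths differ")
})

test_that("yield prediction returns one clipped scalar per reaction", {
  fx <- yield_fixture(n = 8L)
  pred <- predict_yield(fx$d, fx$model)
  expect_identical(nrow(pred), 8L)
  expect_identical(pred$record_id, names(fx$d$records))
  expect_true(all(pred$y_pred >= 0 & pred$y_pred <= 100))
  pred2 <- predict_yield(fx$d, fx$model)
  expect_identical(pred, pred2)   # eval determinism
})

test_that("missing conformers error unless the sequence-only fallback is on", {
  fx <- yield_fixture(n = 8L)
  r <- fx$d$records[[1L]]
  r$reactants[[1L]]$coords <- NULL
  expect_error(predict_yield(list(r), fx$model), "missing conformers")
  p <- predict_yield(list(r), fx$model, fallback = TRUE)
  expect_true(is.finite(p$y_pred))
  # the fallback equals the predictor applied to [h_s ; 0] explicitly
  enc <- encode_reaction(fx$d$records[[1L]], fx$model$vocab,
                         max_len = fx$model$max_len)
  hs <- encode_sequence_view(list(enc), fx$model$seq_cfg,
                             fx$model$params$seq)
  pn <- mvrxn:::params_to_nodes(NULL, fx$model$params$pred)
  manual <- mvrxn:::pred_forward(NULL, mvrxn:::tp_node(NULL, hs),
                                 mvrxn:::tp_node(NULL, 0 * hs), pn)$value
  expect_equal(p$y_pred, min(max(as.numeric(manual) * 100, 0), 100),
               tolerance = 1e-12)
})

test_that("freezing the encoders updates only the predictor", {
  fx <- yield_fixture(n = 18L)
  cfg <- stage2_config(epochs = 2L, batch_size = 6L, freeze = TRUE,
                       seed = 3L)
  fit <- train_yield_model(fx$d, fx$model, cfg)
  expect_identical(fit$model$params$seq, fx$model$params$seq)
  expect_identical(fit$model$params$conf, fx$model$params$conf)
  expect_false(identical(fit$model$params$pred, fx$model$params$pred))
})

test_that("training is reproducible and reduces the training loss", {
  fx <- yield_fixture(n = 24L)
  cfg <- stage2_config(epochs = 3L, batch_size = 8L, lr = 3e-3, seed = 5L)
  fit1 <- train_yield_model(fx$d, fx$model, cfg)
  fit2 <- train_yield_model(fx$d, fx$model, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_lt(utils::tail(fit1$history$train_loss, 1L),
            fit1$history$train_loss[1L])
  expect_error(train_yield_model(
    stratified_split(fx$d, ratio = c(1L, 0L, 0L)), fx$model, cfg),
    "no validation split")
})

test_that("the absolute-error objective trains and only changes the objective", {
  fx <- yield_fixture(n = 18L)
  cfg <- stage2_config(epochs = 2L, batch_size = 6L, loss = "mae", seed = 7L)
  fit <- train_yield_model(fx$d, fx$model, cfg)
  expect_true(all(is.finite(fit$history$train_loss)))
  test_ids <- mvrxn:::split_ids(fx$d, "test")
  y <- mvrxn:::dataset_yields(fx$d)[test_ids]
  pred <- predict_yield(fx$d$records[test_ids], fit$model)
  m <- regression_metrics(y, pred$y_pred)
  expect_named(m, c("mae", "rmse", "r2"))
})

test_that("the default fine-tuning grid has the 36 published cells", {
  g <- fine_tune_grid()
  expect_identical(nrow(g), 36L)
  expect_setequal(unique(g$lr), c(3e-4, 1e-3, 3e-3))
  expect_setequal(unique(g$dropout), c(0.1, 0.3))
  expect_setequal(unique(g$weight_decay), c(0, 1e-4, 1e-5))
  expect_setequal(unique(g$loss), c("mse", "mae"))
})

test_that("grid search reports every cell and rejects a crippling cell", {
  fx <- yield_fixture(n = 30L)
  grid <- data.frame(lr = c(3e-3, 30), dropout = c(0.1, 0.1),
                     weight_decay = c(0, 0), loss = c("mse", "mse"),
                     stringsAsFactors = FALSE)
  res <- grid_search_finetune(fx$d, fx$model, grid, eval_fraction = 0.2,
                              epochs = 2L, batch_size = 8L, seed = 9L)
  expect_identical(nrow(res$report), 2L)
  expect_identical(res$best_config$lr, 3e-3)
  single <- grid_search_finetune(fx$d, fx$model, grid[1L, ],
                                 eval_fraction = 0.2, epochs = 1L,
                                 batch_size = 8L, seed = 9L)
  expect_identical(nrow(single$report), 1L)
  expect_error(grid_search_finetune(fx$d, fx$model, grid, eval_fraction = 0),
               "config error")
})

test_that("initializing from a checkpoint restores encoder weights exactly", {
  fx <- yield_fixture(n = 12L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fx$model, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params$seq, fx$model$params$seq)
  expect_identical(m2$params$conf, fx$model$params$conf)
  p1 <- predict_yield(fx$d, fx$model)
  p2 <- predict_yield(fx$d, m2)
  expect_identical(p1, p2)
})
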