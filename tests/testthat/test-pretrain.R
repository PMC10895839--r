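test_that("alignment losses reproduce hand-derived values", {
  # d = 2, x_s = (0,0) -> P = (1/2, 1/2); x_c = (ln 2, 0) -> Q = (2/3, 1/3)
  expect_lt(abs(jeffreys_alignment_loss(matrix(c(0, 0), 1L),
                                        matrix(c(log(2), 0), 1L)) -
                  0.057762), 1e-6)
  expect_lt(abs(infonce_loss(diag(2L), diag(2L), tau = 1) - 0.313262), 1e-6)
  expect_equal(infonce_loss(matrix(0, 2L, 4L), matrix(0, 2L, 4L), tau = 1),
               log(2), tolerance = 1e-12)
  expect_equal(infonce_loss(matrix(rnorm(8), 1L), matrix(rnorm(8), 1L)), 0)
})

test_that("vectorized losses agree with naive double-loop references", {
  withr::local_seed(20L)
  for (i in 1:25) {
    n <- sample(1:8, 1L)
    dd <- sample(2:16, 1L)
    Xs <- matrix(rnorm(n * dd, sd = 2), n, dd)
    Xc <- matrix(rnorm(n * dd, sd = 2), n, dd)
    tau <- runif(1, 0.05, 2)
    expect_equal(jeffreys_alignment_loss(Xs, Xc), naive_jeffreys(Xs, Xc),
                 tolerance = 1e-6)
    expect_equal(infonce_loss(Xs, Xc, tau), naive_infonce(Xs, Xc, tau),
                 tolerance = 1e-6)
  }
})

test_that("loss symmetries and bounds hold", {
  withr::local_seed(21L)
  Xs <- matrix(rnorm(40), 5L)
  Xc <- matrix(rnorm(40), 5L)
  expect_equal(jeffreys_alignment_loss(Xs, Xs), 0)
  expect_equal(jeffreys_alignment_loss(Xs, Xc),
               jeffreys_alignment_loss(Xc, Xs))
  expect_gte(jeffreys_alignment_loss(Xs, Xc), 0)
  expect_gte(infonce_loss(Xs, Xc, 0.5), 0)
  expect_error(infonce_loss(Xs, Xc, tau = 0), "config error")
  expect_error(jeffreys_alignment_loss(Xs * NA, Xc), "numeric error")
  # i.i.d. random embeddings at tau = 1: mean loss near ln N
  n <- 128L
  losses <- vapply(1:3, function(i) {
    a <- matrix(rnorm(n * 128L, sd = 0.1), n)
    b <- matrix(rnorm(n * 128L, sd = 0.1), n)
    infonce_loss(a, b, tau = 1)
  }, numeric(1))
  expect_lt(abs(mean(losses) - log(n)) / log(n), 0.15)
})

test_that("the combined objective is L_KL + lambda * L_InfoNCE", {
  withr::local_seed(22L)
  Xs <- matrix(rnorm(24), 4L)
  Xc <- matrix(rnorm(24), 4L)
  r1 <- stage1_loss(Xs, Xc, stage1_config(lambda_weight = 1))
  r0 <- stage1_loss(Xs, Xc, stage1_config(lambda_weight = 0))
  rh <- stage1_loss(Xs, Xc, stage1_config(lambda_weight = 0.5))
  expect_equal(r0$L_I, r0$L_KL)
  expect_equal(r1$L_I, r1$L_KL + r1$L_InfoNCE)
  expect_equal(rh$L_I - rh$L_KL, (r1$L_I - r1$L_KL) / 2)
  expect_equal(stage1_loss(Xs, Xs, stage1_config())$L_KL, 0)
})

test_that("the shared projector treats both views identically", {
  withr::local_seed(23L)
  proj <- list(l1 = mvrxn:::nn_init_dense(16L, 16L),
               l2 = mvrxn:::nn_init_dense(16L, 8L))
  h <- matrix(rnorm(48), 3L)
  xs <- project_to_alignment_space(h, proj)
  xc <- project_to_alignment_space(h, proj)
  expect_identical(xs, xc)
  expect_identical(dim(xs), c(3L, 8L))
  z <- project_to_alignment_space(matrix(0, 1L, 16L), proj)
  expect_equal(as.numeric(z),
               as.numeric(sweep(matrix(pmax(proj$l1$b, 0), 1L) %*% proj$l2$W,
                                2L, proj$l2$b, `+`)))
  expect_error(project_to_alignment_space(matrix(0, 1L, 7L), proj),
               "dimension mismatch")
})

test_that("a short stage-I run is seeded, reproducible, and improves", {
  d <- make_synthetic_dataset(tiny_spec(n = 24L, seed = 31L))
  d <- stratified_split(d, ratio = c(4L, 1L, 1L), seed = 1L)
  v <- tiny_vocab_for(d)
  model <- tiny_model_for(v)
  cfg <- stage1_config(epochs = 4L, batch_size = 8L, lr = 5e-3, seed = 6L)
  fit1 <- train_stage1(d, model, cfg)
  fit2 <- train_stage1(d, model, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_lt(fit1$history$L_I[4L], fit1$history$L_I[1L])
  expect_error(train_stage1(reaction_dataset(list()), model, cfg),
               "empty dataset")
})

test_that("checkpoints round-trip and refuse a mismatched vocabulary", {
  d <- make_synthetic_dataset(tiny_spec(n = 6L, seed = 33L))
  v <- tiny_vocab_for(d)
  model <- tiny_model_for(v)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  m2 <- load_checkpoint(path, vocab = v)
  expect_identical(m2$params, model$params)
  other <- build_vocabulary(list(c("C", "N")), min_frequency = 1L)
  expect_error(load_checkpoint(path, vocab = other), "vocabulary mismatch")
})
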