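# Supervised yield modelling: a two-layer perceptron predictor on the
# concatenated view representations h_s (+) h_c, end-to-end training with a
# squared- or absolute-error objective on [0, 1]-normalized yields, and the
# fine-tuning hyper-parameter grid search.

#' Stage-II / fine-tuning configuration
#'
#' @param epochs training epochs.
#' @param batch_size batch size.
#' @param lr Adam learning rate.
#' @param weight_decay L2 weight decay coefficient.
#' @param loss `"mse"` (squared error) or `"mae"` (absolute error);
#'   reported metrics are unaffected by the choice.
#' @param dropout predictor dropout ratio.
#' @param freeze update only the predictor, leaving encoder weights fixed.
#' @param seed integer seed.
#' @return a `mvrxn_stage2_config` list.
#' @export
stage2_config <- function(epochs = 10L, batch_size = 32L, lr = 1e-3,
                          weight_decay = 0, loss = c("mse", "mae"),
                          dropout = 0.1, freeze = FALSE, seed = 1L) {
  loss <- match.arg(loss)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, loss = loss,
                 dropout = dropout, freeze = isTRUE(freeze),
                 seed = as.integer(seed)),
            class = "mvrxn_stage2_config")
}

# predictor forward on the tape: concat(h_s, h_c) -> scalar per row
pred_forward <- function(tape, hs, hc, pnodes, dropout = 0, train = FALSE) {
  h <- tp_concat_cols(tape, hs, hc)
  z <- tp_relu(tape, tp_dense(tape, h, pnodes$l1))
  if (train && dropout > 0) {
    m <- matrix(stats::rbinom(length(z$value), 1L, 1 - dropout) / (1 - dropout),
                nrow(z$value), ncol(z$value))
    z <- tp_dropout(tape, z, m)
  }
  tp_dense(tape, z, pnodes$l2)
}

#' Predict yields for reactions
#'
#' Computes both view representations in evaluation mode, applies the
#' predictor to their concatenation (sequence view first), rescales to the
#' 0-100 percentage scale, and clips the report to [0, 100].  With
#' `fallback = TRUE`, reactions lacking conformers are predicted from the
#' sequence view alone (the conformer half of the input is zeroed).
#'
#' @param reactions an `mvrxn_dataset`, list of reactions, or one reaction.
#' @param model a trained `mvrxn_model`.
#' @param fallback allow sequence-only prediction when conformers are
#'   missing (default FALSE: missing conformers are an error).
#' @return data.frame with `record_id`, `y_pred` (clipped percent).
#' @export
predict_yield <- function(reactions, model, fallback = FALSE) {
  if (inherits(reactions, "mvrxn_dataset")) reactions <- reactions$records
  if (inherits(reactions, "mvrxn_reaction")) reactions <- list(reactions)
  encs <- lapply(reactions, encode_reaction, v = model$vocab,
                 max_len = model$max_len)
  b <- encoded_batch(encs)
  pn <- params_to_nodes(NULL, model$params)
  hs <- seq_forward(NULL, b$tokens, b$lengths, model$seq_cfg, pn$seq)
  has_conf <- vapply(reactions, function(r)
    all(vapply(reaction_molecules(r), function(m) !is.null(m$coords),
               logical(1))), logical(1))
  if (!all(has_conf) && !fallback)
    stop("error: missing conformers for record(s) ",
         paste(vapply(reactions[!has_conf], function(r) r$record_id,
                      character(1)), collapse = ", "),
         " (set fallback = TRUE for sequence-only prediction)")
  hc_val <- matrix(0, length(reactions), 2L * model$conf_cfg$hidden_dim)
  if (any(has_conf)) {
    hc_val[has_conf, ] <- conf_forward(NULL, reactions[has_conf],
                                       model$conf_cfg, pn$conf)$value
  }
  out <- pred_forward(NULL, hs, tp_node(NULL, hc_val), pn$pred)
  y <- as.numeric(out$value) * 100
  data.frame(record_id = vapply(reactions, function(r) r$record_id,
                                character(1)),
             y_pred = pmin(pmax(y, 0), 100),
             stringsAsFactors = FALSE)
}

#' Supervised squared-error loss on the normalized yield scale
#'
#' `sum_i (y_i - yhat_i)^2` with yields on [0, 1].
#' @param y,y_hat numeric vectors of equal length.
#' @return scalar sum of squared errors.
#' @export
stage2_loss <- function(y, y_hat) {
  if (length(y) != length(y_hat))
    stop("error: target and prediction lengths differ")
  sum((y - y_hat)^2)
}

#' Train the yield model (stage-II pre-training or fine-tuning)
#'
#' End-to-end optimization of both encoders and the predictor (or the
#' predictor alone with `freeze = TRUE`) on records with valid yields,
#' using the dataset's train split; the checkpoint with the best
#' validation loss is returned.  Yields are normalized to [0, 1] for
#' optimization.
#'
#' @param d an `mvrxn_dataset` with yields and split labels (a `valid`
#'   split must exist).
#' @param model an `mvrxn_model` (random init or a stage-I checkpoint).
#' @param cfg a `mvrxn_stage2_config`.
#' @param verbose print per-epoch losses.
#' @return list with `model`, `history`.
#' @export
train_yield_model <- function(d, model, cfg = stage2_config(),
                              verbose = FALSE) {
  y_all <- dataset_yields(d)
  if (anyNA(y_all))
    stop("error: all records need valid yields for supervised training")
  train_ids <- split_ids(d, "train")
  valid_ids <- split_ids(d, "valid")
  if (!length(valid_ids)) stop("error: no validation split")
  encs <- prepare_encodings(d, model)
  trainable <- if (cfg$freeze) "pred" else c("seq", "conf", "pred")
  params <- model$params[trainable]
  opt <- adam_new(params, lr = cfg$lr, weight_decay = cfg$weight_decay)
  hist <- data.frame()
  best <- list(loss = Inf, params = params)
  yn <- y_all / 100
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(train_ids)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      tot <- 0; nb <- 0L
      for (bt in batches) {
        tape <- tape_new()
        pnodes <- params_to_nodes(tape, params)
        full <- model$params
        full[trainable] <- pnodes[trainable]
        fixed <- params_to_nodes(NULL, full[setdiff(c("seq", "conf", "pred"),
                                                    trainable)])
        pn <- c(pnodes, fixed)[c("seq", "conf", "pred")]
        vw <- views_forward(tape, bt, d, encs, model, pn, train = !cfg$freeze)
        out <- pred_forward(tape, vw$hs, vw$hc, pn$pred,
                            dropout = cfg$dropout, train = TRUE)
        tgt <- tp_const(tape, matrix(yn[bt], ncol = 1L))
        err <- tp_sub(tape, out, tgt)
        loss <- if (cfg$loss == "mse") {
          tp_mean(tape, tp_mul(tape, err, err))
        } else {
          # smooth |e| via sqrt(e^2 + eps) keeps the tape simple
          sq <- tp_mul(tape, err, err)
          tp_mean(tape, tp_sqrt_eps(tape, sq, 1e-8))
        }
        tape_backward(tape, loss)
        params <- adam_step(opt, params, collect_grads(pnodes))
        tot <- tot + loss$value * length(bt)
        nb <- nb + length(bt)
      }
      m2 <- model; m2$params[trainable] <- params
      vpred <- predict_yield(d$records[valid_ids], m2)
      vloss <- mean((yn[valid_ids] - vpred$y_pred / 100)^2)
      if (vloss < best$loss) best <- list(loss = vloss, params = params)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tot / nb,
                                     valid_mse = vloss))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  valid %.5f", ep, tot / nb,
                        vloss))
    }
  })
  model$params[trainable] <- best$params
  list(model = model, history = hist)
}

tp_sqrt_eps <- function(tape, a, eps) {
  v <- sqrt(a$value + eps)
  tp_node(tape, v, list(a), function(nd) acc_grad(a, nd$grad * 0.5 / v))
}

#' The fine-tuning hyper-parameter grid
#'
#' Learning rates {3e-4, 1e-3, 3e-3}, dropout ratios {0.1, 0.3}, weight
#' decays {0, 1e-4, 1e-5}, and loss functions {squared error, absolute
#' error} — 36 cells.
#' @return data.frame with one row per grid cell in deterministic order.
#' @export
fine_tune_grid <- function(lr = c(3e-4, 1e-3, 3e-3), dropout = c(0.1, 0.3),
                           weight_decay = c(0, 1e-4, 1e-5),
                           loss = c("mse", "mae")) {
  stopifnot(length(lr) > 0, length(dropout) > 0, length(weight_decay) > 0,
            length(loss) > 0)
  expand.grid(lr = lr, dropout = dropout, weight_decay = weight_decay,
              loss = loss, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Grid-search fine-tuning
#'
#' For each grid cell the model is trained on `(1 - eval_fraction)` of the
#' training records and scored by RMSE (yield points) on the held-out
#' fraction; the best cell (ties: first in grid order) is then retrained
#' on the full training set.
#'
#' @param d an `mvrxn_dataset` with yields; records labelled `train` are
#'   used for the search (others ignored).
#' @param model starting `mvrxn_model` (e.g. a stage-I checkpoint).
#' @param grid data.frame from [fine_tune_grid()].
#' @param eval_fraction held-out fraction of the training records in
#'   (0, 1), default 0.1.
#' @param epochs epochs per cell.
#' @param batch_size batch size.
#' @param seed integer seed.
#' @param verbose print per-cell scores.
#' @return list with `best_config` (one-row data.frame), `model`
#'   (retrained on the full training set), and `report` (per-cell RMSE).
#' @export
grid_search_finetune <- function(d, model, grid = fine_tune_grid(),
                                 eval_fraction = 0.1, epochs = 5L,
                                 batch_size = 32L, seed = 1L,
                                 verbose = FALSE) {
  stopifnot(nrow(grid) >= 1L)
  if (eval_fraction <= 0 || eval_fraction >= 1)
    stop("config error: eval_fraction must lie in (0, 1)")
  train_ids <- if (is.null(d$split_labels)) names(d$records) else
    split_ids(d, "train")
  n_eval <- max(1L, round(length(train_ids) * eval_fraction))
  if (n_eval >= length(train_ids) - 1L)
    stop("error: degenerate grid-search split")
  withr::with_seed(as.integer(seed), {
    eval_ids <- sample(train_ids, n_eval)
  })
  fit_ids <- setdiff(train_ids, eval_ids)
  y <- dataset_yields(d)
  rmse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    labels <- c(stats::setNames(rep("train", length(fit_ids)), fit_ids),
                stats::setNames(rep("valid", length(eval_ids)), eval_ids))
    dg <- subset_dataset(d, c(fit_ids, eval_ids))
    dg$split_labels <- labels[names(dg$records)]
    cfg <- stage2_config(epochs = epochs, batch_size = batch_size,
                         lr = grid$lr[g], weight_decay = grid$weight_decay[g],
                         loss = grid$loss[g], dropout = grid$dropout[g],
                         seed = seed)
    fit <- train_yield_model(dg, model, cfg)
    pred <- predict_yield(dg$records[eval_ids], fit$model)
    rmse[g] <- sqrt(mean((y[eval_ids] - pred$y_pred)^2))
    if (verbose)
      message(sprintf("cell %2d/%d  lr %.0e  drop %.1f  wd %.0e  %s  RMSE %.3f",
                      g, nrow(grid), grid$lr[g], grid$dropout[g],
                      grid$weight_decay[g], grid$loss[g], rmse[g]))
  }
  best <- which.min(rmse)
  report <- cbind(grid, rmse = rmse)
  # retrain on the full training records with the winning cell
  labels <- stats::setNames(rep("train", length(train_ids)), train_ids)
  labels[eval_ids] <- "valid"
  df <- subset_dataset(d, train_ids)
  df$split_labels <- labels[names(df$records)]
  cfg <- stage2_config(epochs = epochs, batch_size = batch_size,
                       lr = grid$lr[best], weight_decay = grid$weight_decay[best],
                       loss = grid$loss[best], dropout = grid$dropout[best],
                       seed = seed)
  fit <- train_yield_model(df, model, cfg)
  list(best_config = grid[best, , drop = FALSE], model = fit$model,
       report = report)
}

#' Repeated seeded evaluation
#'
#' Trains and evaluates `k` times with seeds `seed + 0:(k-1)` and reports
#' mean and standard deviation of each regression metric on the test
#' split.
#'
#' @param d labelled `mvrxn_dataset` with train/valid/test splits.
#' @param model starting model.
#' @param cfg a `mvrxn_stage2_config` (its seed is overridden per run).
#' @param k number of runs (default 5).
#' @return data.frame with one row per metric: mean and sd.
#' @export
evaluate_repeated <- function(d, model, cfg = stage2_config(), k = 5L) {
  y <- dataset_yields(d)
  test_ids <- split_ids(d, "test")
  mets <- matrix(NA_real_, k, 3L, dimnames = list(NULL, c("mae", "rmse", "r2")))
  for (i in seq_len(k)) {
    cfg$seed <- cfg$seed + (i - 1L)
    fit <- train_yield_model(d, model, cfg)
    pred <- predict_yield(d$records[test_ids], fit$model)
    m <- regression_metrics(y[test_ids], pred$y_pred)
    mets[i, ] <- c(m$mae, m$rmse, m$r2)
  }
  data.frame(metric = colnames(mets), mean = colMeans(mets),
             sd = apply(mets, 2L, stats::sd))
}
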