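# Stage-I self-supervised pre-training: a shared projection head maps both
# view representations into the alignment space, where a Jeffreys-divergence
# distribution-alignment loss acts on positive pairs and a symmetric InfoNCE
# loss contrasts in-batch negatives.  Combined objective:
#   L_I = L_KL + lambda * L_InfoNCE.

#' Build a multi-view reaction model
#'
#' Bundles the vocabulary, both encoder configurations, the shared
#' projection head, and the yield predictor, with all parameters drawn
#' from a seeded initializer.
#'
#' @param vocab an `mvrxn_vocab`.
#' @param seq_cfg sequence-encoder configuration (defaults from
#'   [seq_encoder_config()] at this vocabulary size).
#' @param conf_cfg conformer-encoder configuration.
#' @param align_dim alignment-space dimension d (default 128).
#' @param predictor_hidden hidden width of the yield predictor (default 256).
#' @param predictor_dropout dropout in the predictor (default 0.1).
#' @param max_len maximum encoded sequence length.
#' @param seed integer seed for initialization.
#' @return an object of class `mvrxn_model`.
#' @export
build_model <- function(vocab,
                        seq_cfg = seq_encoder_config(vocab_size(vocab)),
                        conf_cfg = schnet_config(),
                        align_dim = 128L, predictor_hidden = 256L,
                        predictor_dropout = 0.1,
                        max_len = 256L, seed = 1L) {
  rep_dim <- 2L * seq_cfg$hidden_dim
  stopifnot(2L * conf_cfg$hidden_dim == rep_dim)
  params <- withr::with_seed(as.integer(seed), list(
    seq = seq_encoder_init(seq_cfg),
    conf = conf_encoder_init(conf_cfg),
    proj = list(l1 = nn_init_dense(rep_dim, rep_dim),
                l2 = nn_init_dense(rep_dim, align_dim)),
    pred = list(l1 = nn_init_dense(2L * rep_dim, predictor_hidden),
                l2 = nn_init_dense(predictor_hidden, 1L))))
  structure(list(vocab = vocab, seq_cfg = seq_cfg, conf_cfg = conf_cfg,
                 align_dim = as.integer(align_dim),
                 predictor_hidden = as.integer(predictor_hidden),
                 predictor_dropout = predictor_dropout,
                 max_len = as.integer(max_len),
                 vocab_hash = vocab_hash(vocab), params = params),
            class = "mvrxn_model")
}

#' @export
print.mvrxn_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), length, integer(1)))
  cat("<mvrxn_model>", length(x$vocab$tokens), "tokens |",
      "h_s/h_c dim", 2L * x$seq_cfg$hidden_dim, "| align dim", x$align_dim,
      "|", np, "parameters\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores configurations, parameters, and the vocabulary
#' hash; loading against a different vocabulary is refused.
#' @param model an `mvrxn_model`; `path` file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param vocab when given, the checkpoint's vocabulary hash must match.
#' @export
load_checkpoint <- function(path, vocab = NULL) {
  model <- readRDS(path)
  if (!inherits(model, "mvrxn_model"))
    stop("checkpoint error: ", path, " does not hold a model")
  if (!is.null(vocab) && !identical(vocab_hash(vocab), model$vocab_hash))
    stop("checkpoint error: vocabulary mismatch for ", path)
  model
}

#' Stage-I training configuration
#'
#' @param lambda_weight weight on the contrastive term (default 1.0).
#' @param temperature InfoNCE temperature tau (default 0.1).
#' @param batch_size batch size N (default 32; contrastive terms need
#'   N >= 2).
#' @param epochs training epochs.
#' @param lr Adam learning rate (default 1e-3, Adam defaults otherwise).
#' @param seed integer seed.
#' @param normalize_embeddings L2-normalize alignment embeddings before the
#'   InfoNCE dot product (off by default: the similarity is the raw dot
#'   product).
#' @return a `mvrxn_stage1_config` list.
#' @export
stage1_config <- function(lambda_weight = 1.0, temperature = 0.1,
                          batch_size = 32L, epochs = 10L, lr = 1e-3,
                          seed = 1L, normalize_embeddings = FALSE) {
  if (temperature <= 0) stop("config error: temperature must be positive")
  if (lambda_weight < 0) stop("config error: lambda_weight must be >= 0")
  structure(list(lambda_weight = lambda_weight, temperature = temperature,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed),
                 normalize_embeddings = isTRUE(normalize_embeddings)),
            class = "mvrxn_stage1_config")
}

#' Project representations into the alignment space
#'
#' Two-layer perceptron with one ReLU nonlinearity; the same parameters are
#' applied to both views (a single shared head g).
#'
#' @param h numeric matrix of representations (rows = reactions).
#' @param params the model's `proj` parameter list.
#' @return matrix with `align_dim` columns.
#' @export
project_to_alignment_space <- function(h, params) {
  h <- if (is.matrix(h)) h else matrix(h, nrow = 1L)
  if (ncol(h) != nrow(params$l1$W))
    stop("dimension mismatch: projector expects ", nrow(params$l1$W),
         " input columns")
  pn <- params_to_nodes(NULL, params)
  proj_forward(NULL, tp_node(NULL, h), pn)$value
}

proj_forward <- function(tape, h, pnodes) {
  tp_dense(tape, tp_relu(tape, tp_dense(tape, h, pnodes$l1)), pnodes$l2)
}

# ---- losses ----------------------------------------------------------------

row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

row_log_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  x - log(rowSums(exp(x)))
}

#' Jeffreys-divergence distribution alignment loss
#'
#' Each alignment embedding is turned into a distribution over its d
#' features by a softmax; the loss is the symmetrized Kullback-Leibler
#' divergence between the two views, averaged over the batch:
#' `(1/2N) sum_i [KL(P_i || Q_i) + KL(Q_i || P_i)]`, computed in log space.
#' Nonnegative, symmetric in its arguments, and zero iff the two views
#' induce identical distributions.
#'
#' @param X_s,X_c N x d matrices of alignment embeddings (sequence and
#'   conformer views).
#' @return scalar loss.
#' @export
jeffreys_alignment_loss <- function(X_s, X_c) {
  X_s <- as.matrix(X_s); X_c <- as.matrix(X_c)
  stopifnot(all(dim(X_s) == dim(X_c)))
  if (!all(is.finite(X_s)) || !all(is.finite(X_c)))
    stop("numeric error: non-finite alignment embeddings")
  lp <- row_log_softmax(X_s)
  lq <- row_log_softmax(X_c)
  p <- exp(lp); q <- exp(lq)
  sum((p - q) * (lp - lq)) / (2 * nrow(X_s))
}

#' Symmetric InfoNCE contrastive loss
#'
#' Similarities are raw dot products scaled by the temperature; each view's
#' matching partner is classified against the in-batch negatives in both
#' directions: `-(1/2N) sum_i [log softmax_k(s_ik)|_{k=i} +
#' log softmax_k(s_ki)|_{k=i}]`.  Log-sum-exp stabilized.
#'
#' @param X_s,X_c N x d matrices of alignment embeddings.
#' @param tau temperature (> 0).
#' @return scalar loss (>= 0 up to floating point).
#' @export
infonce_loss <- function(X_s, X_c, tau = 0.1) {
  if (tau <= 0) stop("config error: temperature must be positive")
  X_s <- as.matrix(X_s); X_c <- as.matrix(X_c)
  stopifnot(all(dim(X_s) == dim(X_c)))
  S <- tcrossprod(X_s, X_c) / tau
  ls_row <- row_log_softmax(S)
  ls_col <- row_log_softmax(t(S))
  -(sum(diag(ls_row)) + sum(diag(ls_col))) / (2 * nrow(S))
}

#' Combined stage-I loss
#'
#' `L_I = L_KL + lambda * L_InfoNCE`.
#' @param X_s,X_c N x d alignment embeddings.
#' @param cfg a `mvrxn_stage1_config`.
#' @return list with `L_KL`, `L_InfoNCE`, `L_I`.
#' @export
stage1_loss <- function(X_s, X_c, cfg = stage1_config()) {
  lkl <- jeffreys_alignment_loss(X_s, X_c)
  lnce <- infonce_loss(X_s, X_c, cfg$temperature)
  list(L_KL = lkl, L_InfoNCE = lnce,
       L_I = lkl + cfg$lambda_weight * lnce)
}

# tape version of the combined loss, gradients derived in closed form
tp_stage1_loss <- function(tape, xs, xc, cfg) {
  n <- nrow(xs$value)
  lp <- row_log_softmax(xs$value)
  lq <- row_log_softmax(xc$value)
  p <- exp(lp); q <- exp(lq)
  a <- lp - lq
  b <- p - q
  lkl <- sum(b * a) / (2 * n)
  S <- tcrossprod(xs$value, xc$value) / cfg$temperature
  A <- row_softmax(S)
  B <- row_softmax(t(S))
  lnce <- -(sum(diag(log(pmax(A, 1e-300)))) +
              sum(diag(log(pmax(B, 1e-300))))) / (2 * n)
  lam <- cfg$lambda_weight
  node <- tp_node(tape, lkl + lam * lnce, list(xs, xc), function(nd) {
    g <- nd$grad
    # Jeffreys part: d/dx_s = (1/2N)[p*a - p (p.a) + b], sym. for x_c
    gs <- (p * a - p * rowSums(p * a) + b) / (2 * n)
    gc <- (q * (-a) - q * rowSums(q * (-a)) - b) / (2 * n)
    # InfoNCE part through the similarity matrix
    dS <- ((A - diag(n)) + t(B - diag(n))) / (2 * n * cfg$temperature)
    gs <- gs + lam * (dS %*% xc$value)
    gc <- gc + lam * (crossprod(dS, xs$value))
    acc_grad(xs, g * gs)
    acc_grad(xc, g * gc)
  })
  attr(node, "parts") <- c(L_KL = lkl, L_InfoNCE = lnce)
  node
}

# ---- training --------------------------------------------------------------

# prepare per-record inputs once: encoded token sequences
prepare_encodings <- function(d, model) {
  lapply(d$records, encode_reaction, v = model$vocab, max_len = model$max_len)
}

split_ids <- function(d, split) {
  if (is.null(d$split_labels)) stop("error: dataset has no split labels")
  names(d$split_labels)[d$split_labels == split]
}

# forward both views for a batch of record ids -> list(hs, hc) nodes
views_forward <- function(tape, ids, d, encs, model, pnodes, train) {
  b <- encoded_batch(encs[ids])
  hs <- seq_forward(tape, b$tokens, b$lengths, model$seq_cfg, pnodes$seq,
                    train = train)
  hc <- conf_forward(tape, d$records[ids], model$conf_cfg, pnodes$conf,
                     train = train)
  list(hs = hs, hc = hc)
}

#' Stage-I self-supervised pre-training
#'
#' Jointly optimizes both encoders and the shared projector with Adam on
#' `L_I = L_KL + lambda * L_InfoNCE` over seeded shuffled batches.  When
#' the dataset carries split labels, the `train` part is optimized and the
#' per-epoch validation loss on the `valid` part is logged; the checkpoint
#' with the best validation loss is returned.
#'
#' @param d an `mvrxn_dataset` with conformers on every record.
#' @param model an `mvrxn_model`.
#' @param cfg a `mvrxn_stage1_config`.
#' @param verbose print per-epoch losses.
#' @return list with `model` (best checkpoint), `history` (per-epoch
#'   data.frame of L_KL, L_InfoNCE, L_I, valid_L_I).
#' @export
train_stage1 <- function(d, model, cfg = stage1_config(), verbose = FALSE) {
  if (length(d$records) == 0L) stop("error: empty dataset")
  encs <- prepare_encodings(d, model)
  train_ids <- if (is.null(d$split_labels)) names(d$records) else
    split_ids(d, "train")
  valid_ids <- if (is.null(d$split_labels)) character(0) else
    split_ids(d, "valid")
  params <- model$params[c("seq", "conf", "proj")]
  opt <- adam_new(params, lr = cfg$lr)
  hist <- data.frame()
  best <- list(loss = Inf, params = params)
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(train_ids)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_parts <- c(L_KL = 0, L_InfoNCE = 0, L_I = 0)
      nb <- 0L
      for (bt in batches) {
        if (length(bt) < 2L) next
        tape <- tape_new()
        pnodes <- params_to_nodes(tape, params)
        vw <- views_forward(tape, bt, d, encs, model, pnodes, train = TRUE)
        xs <- proj_forward(tape, vw$hs, pnodes$proj)
        xc <- proj_forward(tape, vw$hc, pnodes$proj)
        if (cfg$normalize_embeddings) {
          xs <- tp_scale_rows(tape, xs, 1 / sqrt(rowSums(xs$value^2) + 1e-12))
          xc <- tp_scale_rows(tape, xc, 1 / sqrt(rowSums(xc$value^2) + 1e-12))
        }
        loss <- tp_stage1_loss(tape, xs, xc, cfg)
        tape_backward(tape, loss)
        params <- adam_step(opt, params, collect_grads(pnodes))
        ep_parts <- ep_parts + c(attr(loss, "parts"),
                                 L_I = loss$value)
        nb <- nb + 1L
      }
      ep_parts <- ep_parts / nb
      vloss <- NA_real_
      if (length(valid_ids) >= 2L) {
        m2 <- model; m2$params[c("seq", "conf", "proj")] <- params
        vloss <- stage1_eval_loss(d, encs, m2, cfg, valid_ids)
      }
      sel_loss <- if (is.na(vloss)) ep_parts[["L_I"]] else vloss
      if (sel_loss < best$loss) best <- list(loss = sel_loss, params = params)
      hist <- rbind(hist, data.frame(epoch = ep, L_KL = ep_parts[["L_KL"]],
                                     L_InfoNCE = ep_parts[["L_InfoNCE"]],
                                     L_I = ep_parts[["L_I"]],
                                     valid_L_I = vloss))
      if (verbose)
        message(sprintf("epoch %3d  L_I %.4f  (KL %.4f, NCE %.4f)  valid %.4f",
                        ep, ep_parts[["L_I"]], ep_parts[["L_KL"]],
                        ep_parts[["L_InfoNCE"]], vloss))
    }
  })
  model$params[c("seq", "conf", "proj")] <- best$params
  list(model = model, history = hist)
}

# evaluation-mode stage-I loss over held-out ids (seeded batch layout)
stage1_eval_loss <- function(d, encs, model, cfg, ids) {
  pn <- params_to_nodes(NULL, model$params)
  batches <- split(ids, ceiling(seq_along(ids) / cfg$batch_size))
  tot <- 0; nb <- 0L
  for (bt in batches) {
    if (length(bt) < 2L) next
    vw <- views_forward(NULL, bt, d, encs, model, pn, train = FALSE)
    xs <- proj_forward(NULL, vw$hs, pn$proj)
    xc <- proj_forward(NULL, vw$hc, pn$proj)
    l <- stage1_loss(xs$value, xc$value, cfg)
    tot <- tot + l$L_I
    nb <- nb + 1L
  }
  tot / nb
}

#' Alignment embeddings of both views (evaluation mode)
#'
#' @param d an `mvrxn_dataset`; `model` an `mvrxn_model`.
#' @param ids record ids (default all).
#' @return list of matrices `X_s`, `X_c` (rows follow `ids`).
#' @export
alignment_embeddings <- function(d, model, ids = names(d$records)) {
  encs <- prepare_encodings(subset_dataset(d, ids), model)
  pn <- params_to_nodes(NULL, model$params)
  vw <- views_forward(NULL, ids, d, encs, model, pn, train = FALSE)
  list(X_s = proj_forward(NULL, vw$hs, pn$proj)$value,
       X_c = proj_forward(NULL, vw$hc, pn$proj)$value)
}
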