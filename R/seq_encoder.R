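# Sequence-view encoder: token embedding followed by a multi-layer
# bidirectional GRU.  The reaction representation h_s is the concatenation
# of the last layer's final hidden states of both directions (forward
# first), giving a vector of dimension 2 * hidden_dim.

#' Sequence encoder configuration
#'
#' @param vocab_size vocabulary size (including special tokens).
#' @param embedding_dim token embedding dimension (default 256).
#' @param hidden_dim GRU hidden size per direction (default 128).
#' @param num_layers stacked bidirectional layers (default 2).
#' @param dropout dropout ratio on embeddings and between layers
#'   (default 0.3, disabled in eval mode).
#' @return a `mvrxn_seq_config` list.
#' @export
seq_encoder_config <- function(vocab_size, embedding_dim = 256L,
                               hidden_dim = 128L, num_layers = 2L,
                               dropout = 0.3) {
  stopifnot(vocab_size > 4L, embedding_dim > 0L, hidden_dim > 0L,
            num_layers >= 1L, dropout >= 0, dropout < 1)
  structure(list(vocab_size = as.integer(vocab_size),
                 embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim),
                 num_layers = as.integer(num_layers),
                 dropout = dropout),
            class = "mvrxn_seq_config")
}

seq_encoder_init <- function(cfg) {
  layers <- vector("list", cfg$num_layers)
  for (l in seq_len(cfg$num_layers)) {
    nin <- if (l == 1L) cfg$embedding_dim else 2L * cfg$hidden_dim
    layers[[l]] <- list(fwd = nn_init_gru(nin, cfg$hidden_dim),
                        bwd = nn_init_gru(nin, cfg$hidden_dim))
  }
  list(emb = nn_init_embedding(cfg$vocab_size, cfg$embedding_dim),
       layers = layers)
}

# core forward: token matrix (N x T, 0-based) + lengths -> h_s node
seq_forward <- function(tape, tokens, lengths, cfg, pnodes, train = FALSE) {
  tt <- ncol(tokens)
  mask <- vapply(seq_len(tt), function(t) as.numeric(t <= lengths),
                 numeric(nrow(tokens)))
  if (nrow(tokens) == 1L) mask <- matrix(mask, nrow = 1L)
  x <- tp_embed_seq(tape, pnodes$emb, tokens)
  drop_seq <- function(x) {
    if (!train || cfg$dropout <= 0) return(x)
    masks <- lapply(x$value, function(v)
      matrix(stats::rbinom(length(v), 1L, 1 - cfg$dropout) / (1 - cfg$dropout),
             nrow(v), ncol(v)))
    tp_seq_dropout(tape, x, masks)
  }
  x <- drop_seq(x)
  fwd <- bwd <- NULL
  for (l in seq_len(cfg$num_layers)) {
    fwd <- tp_gru(tape, x, pnodes$layers[[l]]$fwd, mask)
    xr <- tp_seq_reverse(tape, x, lengths)
    bwd <- tp_gru(tape, xr, pnodes$layers[[l]]$bwd, mask)
    if (l < cfg$num_layers) {
      bwd_al <- tp_seq_reverse(tape, bwd, lengths)
      x <- drop_seq(tp_seq_concat(tape, fwd, bwd_al))
    }
  }
  tp_concat_cols(tape, tp_seq_last(tape, fwd), tp_seq_last(tape, bwd))
}

# assemble the (tokens, lengths) batch matrices from encoded reactions
encoded_batch <- function(encs) {
  lengths <- vapply(encs, function(e) e$length, integer(1))
  tt <- max(lengths)
  tokens <- t(vapply(encs, function(e) e$ids[seq_len(tt)], integer(tt)))
  if (tt == 1L) tokens <- matrix(tokens, ncol = 1L)
  list(tokens = tokens, lengths = lengths)
}

#' Encode a batch of reactions through the sequence view
#'
#' @param encs list of `mvrxn_encoded` (from [encode_reaction()]).
#' @param cfg a `mvrxn_seq_config`.
#' @param params parameters from the model (see [build_model()]).
#' @param mode `"eval"` (deterministic, no dropout) or `"train"`.
#' @return numeric matrix, one 2*hidden_dim row per reaction.
#' @export
encode_sequence_view <- function(encs, cfg, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  stopifnot(length(encs) >= 1L)
  if (any(vapply(encs, function(e) e$length, integer(1)) == 0L))
    stop("encode error: zero-length sequence")
  b <- encoded_batch(encs)
  if (any(b$tokens >= cfg$vocab_size))
    stop("encode error: token index exceeds vocab_size")
  tape <- tape_new()
  pnodes <- params_to_nodes(tape, params)
  out <- seq_forward(tape, b$tokens, b$lengths, cfg, pnodes,
                     train = (mode == "train"))
  out$value
}

#' Concatenate final bidirectional GRU states
#'
#' `h_s = [forward_final ; backward_final]`, forward first.
#' @param forward_final,backward_final numeric vectors (or matrices with
#'   matching row count) from the last GRU layer.
#' @return the concatenation.
#' @export
pool_bigru_states <- function(forward_final, backward_final) {
  if (is.matrix(forward_final) || is.matrix(backward_final)) {
    if (nrow(as.matrix(forward_final)) != nrow(as.matrix(backward_final)))
      stop("dimension mismatch between direction states")
    return(cbind(forward_final, backward_final))
  }
  c(forward_final, backward_final)
}
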