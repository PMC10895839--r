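# Conformer-view encoder.  Each molecule is embedded by a SchNet-style
# network: atomic-number embedding, K interaction blocks built around a
# continuous-filter convolution (neighbor features modulated elementwise by
# a filter generated from the Gaussian-RBF-expanded interatomic distance),
# an atom-wise output network, and a mean readout over atoms.  Only
# pairwise distances enter, so the embedding is invariant under rigid
# rotations, translations, and atom permutations.  A bidirectional GRU
# over the molecule sequence (canonical order, shared with the sequence
# view) then yields the 2*hidden_dim reaction representation h_c.

#' SchNet conformer-encoder configuration
#'
#' @param num_interactions number of interaction blocks K (default 4).
#' @param num_rbf number of Gaussian radial basis functions (default 64).
#' @param cutoff neighbor threshold and RBF span in Angstrom (default 10).
#' @param feature_dim atom feature / filter dimension (default 128).
#' @param rbf_gamma Gaussian width parameter in 1/A^2 (default 10).
#' @param hidden_dim molecule-GRU hidden size per direction (default 128).
#' @param num_layers molecule-GRU layers (default 2).
#' @param dropout molecule-GRU dropout ratio (default 0.3).
#' @param residual include residual connections inside interaction blocks
#'   (standard SchNet); `FALSE` gives the plain update `e <- MLP(agg)`.
#' @param atom_vocab atomic numbers supported.
#' @return a `mvrxn_schnet_config` list.
#' @export
schnet_config <- function(num_interactions = 4L, num_rbf = 64L, cutoff = 10,
                          feature_dim = 128L, rbf_gamma = 10,
                          hidden_dim = 128L, num_layers = 2L, dropout = 0.3,
                          residual = TRUE, atom_vocab = unname(ELEMENT_Z)) {
  stopifnot(num_interactions >= 1L, cutoff > 0, num_rbf >= 2L,
            feature_dim > 0L, rbf_gamma > 0)
  structure(list(num_interactions = as.integer(num_interactions),
                 num_rbf = as.integer(num_rbf), cutoff = cutoff,
                 feature_dim = as.integer(feature_dim),
                 rbf_gamma = rbf_gamma, hidden_dim = as.integer(hidden_dim),
                 num_layers = as.integer(num_layers), dropout = dropout,
                 residual = isTRUE(residual),
                 atom_vocab = sort(as.integer(atom_vocab))),
            class = "mvrxn_schnet_config")
}

rbf_centers <- function(cfg) seq(0, cfg$cutoff, length.out = cfg$num_rbf)

#' Gaussian radial basis expansion of distances
#'
#' Component k is `exp(-gamma * (d - mu_k)^2)` with centers mu_k evenly
#' spaced on [0, cutoff].
#'
#' @param distance nonnegative distances (vector).
#' @param cfg a `mvrxn_schnet_config`.
#' @return matrix `length(distance) x num_rbf`, entries in (0, 1].
#' @export
gaussian_rbf_expand <- function(distance, cfg = schnet_config()) {
  if (any(distance < 0)) stop("error: negative distance")
  mu <- rbf_centers(cfg)
  exp(-cfg$rbf_gamma * outer(distance, mu, `-`)^2)
}

conf_encoder_init <- function(cfg) {
  fd <- cfg$feature_dim
  block_init <- function() list(
    atom_in = nn_init_dense(fd, fd),
    filt1 = nn_init_dense(cfg$num_rbf, fd),
    filt2 = nn_init_dense(fd, fd),
    out1 = nn_init_dense(fd, fd),
    out2 = nn_init_dense(fd, fd))
  layers <- vector("list", cfg$num_layers)
  for (l in seq_len(cfg$num_layers)) {
    nin <- if (l == 1L) fd else 2L * cfg$hidden_dim
    layers[[l]] <- list(fwd = nn_init_gru(nin, cfg$hidden_dim),
                        bwd = nn_init_gru(nin, cfg$hidden_dim))
  }
  list(atom_emb = nn_init_embedding(length(cfg$atom_vocab), fd),
       blocks = lapply(seq_len(cfg$num_interactions),
                       function(i) block_init()),
       final1 = nn_init_dense(fd, fd),
       final2 = nn_init_dense(fd, fd),
       layers = layers)
}

# neighbor structure of a stacked batch of molecules: ordered pairs within
# the cutoff, excluding self-pairs, plus their RBF expansions
molecule_graph <- function(coords_list, cfg) {
  natoms <- vapply(coords_list, nrow, integer(1))
  offs <- cumsum(c(0L, natoms))
  ii <- jj <- integer(0)
  dd <- numeric(0)
  for (m in seq_along(coords_list)) {
    co <- coords_list[[m]]
    n <- nrow(co)
    if (n > 1L) {
      dm <- as.matrix(stats::dist(co))
      sel <- which(dm <= cfg$cutoff & upper.tri(dm) | dm <= cfg$cutoff &
                     lower.tri(dm), arr.ind = TRUE)
      ii <- c(ii, offs[m] + sel[, 1L])
      jj <- c(jj, offs[m] + sel[, 2L])
      dd <- c(dd, dm[sel])
    }
  }
  list(i = ii, j = jj,
       rbf = if (length(dd)) gaussian_rbf_expand(dd, cfg) else
         matrix(0, 0L, cfg$num_rbf),
       n_atoms = sum(natoms), natoms = natoms)
}

# one interaction block on the tape; e: node (n_atoms x F)
schnet_block <- function(tape, e, graph, bp, cfg) {
  a <- tp_dense(tape, e, bp$atom_in)
  if (length(graph$i)) {
    rbf <- tp_const(tape, graph$rbf)
    filt <- tp_dense(tape, tp_ssp(tape, tp_dense(tape, rbf, bp$filt1)),
                     bp$filt2)
    msg <- tp_mul(tape, tp_gather_rows(tape, a, graph$j), filt)
    agg <- tp_aggregate_rows(tape, msg, graph$i, graph$n_atoms)
  } else {
    agg <- tp_scale(tape, a, 0)
  }
  v <- tp_dense(tape, tp_ssp(tape, tp_dense(tape, agg, bp$out1)), bp$out2)
  if (cfg$residual) tp_add(tape, e, v) else v
}

# SchNet over a stacked batch of molecules -> per-molecule embeddings node
schnet_forward <- function(tape, z, coords_list, cfg, pnodes) {
  graph <- molecule_graph(coords_list, cfg)
  zi <- match(z, cfg$atom_vocab)
  if (anyNA(zi))
    stop("unsupported element: atomic number ",
         paste(unique(z[is.na(zi)]), collapse = ", "))
  e <- tp_gather_rows(tape, pnodes$atom_emb, zi)
  for (bp in pnodes$blocks) e <- schnet_block(tape, e, graph, bp, cfg)
  e <- tp_dense(tape, tp_ssp(tape, tp_dense(tape, e, pnodes$final1)),
                pnodes$final2)
  mol_id <- rep(seq_along(graph$natoms), graph$natoms)
  pooled <- tp_aggregate_rows(tape, e, mol_id, length(graph$natoms))
  tp_scale_rows(tape, pooled, 1 / graph$natoms)
}

#' One SchNet interaction block (plain-matrix interface)
#'
#' Runs a single continuous-filter convolution block on explicit atom
#' features and coordinates.  Exposed so the block can be compared against
#' a brute-force per-pair reference.
#'
#' @param features n x feature_dim matrix of atom features.
#' @param coords n x 3 coordinate matrix in Angstrom.
#' @param cfg a `mvrxn_schnet_config`.
#' @param params one element of the encoder's `blocks` parameter list; a
#'   fresh seeded block is drawn when omitted.
#' @return n x feature_dim matrix of updated features.
#' @export
schnet_interaction <- function(features, coords, cfg = schnet_config(),
                               params = NULL) {
  features <- as.matrix(features)
  coords <- as.matrix(coords)
  if (nrow(features) != nrow(coords))
    stop("error: features and coords disagree on atom count")
  if (ncol(features) != cfg$feature_dim)
    stop("error: features must have ", cfg$feature_dim, " columns")
  if (is.null(params)) {
    params <- withr::with_seed(1L, conf_encoder_init(cfg)$blocks[[1L]])
  }
  tape <- NULL
  pn <- params_to_nodes(tape, params)
  e <- tp_node(tape, features)
  graph <- molecule_graph(list(coords), cfg)
  schnet_block(tape, e, graph, pn, cfg)$value
}

#' Embed a single molecule with the SchNet encoder
#'
#' Atomic-number embedding, K interaction blocks, final atom-wise MLP, and
#' mean readout over atoms.
#'
#' @param mol an `mvrxn_molecule` with coordinates.
#' @param cfg a `mvrxn_schnet_config`.
#' @param params conformer-encoder parameters (see [build_model()]).
#' @return numeric vector of length `feature_dim`.
#' @export
embed_molecule <- function(mol, cfg, params) {
  if (is.null(mol$coords))
    stop("error: molecule '", mol$smiles, "' has no coordinates")
  z <- atoms_to_z(mol$atoms)
  pn <- params_to_nodes(NULL, params)
  as.numeric(schnet_forward(NULL, z, list(mol$coords), cfg, pn)$value)
}

# reaction batch -> molecule stacking plan shared by training and eval
conformer_batch <- function(reactions) {
  z <- list()
  coords <- list()
  nmol <- integer(length(reactions))
  for (i in seq_along(reactions)) {
    mols <- reaction_molecules(reactions[[i]])
    nmol[i] <- length(mols)
    for (m in mols) {
      if (is.null(m$coords))
        stop("error: record '", reactions[[i]]$record_id,
             "' lacks conformer coordinates")
      z[[length(z) + 1L]] <- atoms_to_z(m$atoms)
      coords[[length(coords) + 1L]] <- m$coords
    }
  }
  list(z = unlist(z), coords = coords, nmol = nmol)
}

# full conformer-view forward for a batch of reactions -> h_c node
conf_forward <- function(tape, reactions, cfg, pnodes, train = FALSE) {
  cb <- conformer_batch(reactions)
  hm <- schnet_forward(tape, cb$z, cb$coords, cfg, pnodes)
  # arrange molecule embeddings into a padded sequence per reaction
  n <- length(reactions)
  tt <- max(cb$nmol)
  offs <- cumsum(c(0L, cb$nmol))
  hm_pad <- tp_pad_row(tape, hm)
  pad_idx <- nrow(hm$value) + 1L
  xlist <- lapply(seq_len(tt), function(t) {
    idx <- ifelse(t <= cb$nmol, offs[seq_len(n)] + t, pad_idx)
    tp_gather_rows(tape, hm_pad, idx)
  })
  x <- tp_node(tape, lapply(xlist, function(nd) nd$value),
               parents = xlist, backward = local({
                 xl <- xlist
                 function(nd) for (t in seq_along(xl))
                   acc_grad(xl[[t]], nd$grad[[t]])
               }))
  mask <- vapply(seq_len(tt), function(t) as.numeric(t <= cb$nmol),
                 numeric(n))
  if (n == 1L) mask <- matrix(mask, nrow = 1L)
  drop_seq <- function(x) {
    if (!train || cfg$dropout <= 0) return(x)
    masks <- lapply(x$value, function(v)
      matrix(stats::rbinom(length(v), 1L, 1 - cfg$dropout) / (1 - cfg$dropout),
             nrow(v), ncol(v)))
    tp_seq_dropout(tape, x, masks)
  }
  fwd <- bwd <- NULL
  for (l in seq_len(cfg$num_layers)) {
    fwd <- tp_gru(tape, x, pnodes$layers[[l]]$fwd, mask)
    xr <- tp_seq_reverse(tape, x, cb$nmol)
    bwd <- tp_gru(tape, xr, pnodes$layers[[l]]$bwd, mask)
    if (l < cfg$num_layers) {
      bwd_al <- tp_seq_reverse(tape, bwd, cb$nmol)
      x <- drop_seq(tp_seq_concat(tape, fwd, bwd_al))
    }
  }
  tp_concat_cols(tape, tp_seq_last(tape, fwd), tp_seq_last(tape, bwd))
}

#' Encode reactions through the conformer view
#'
#' @param reactions list of `mvrxn_reaction`, every molecule carrying
#'   coordinates.
#' @param cfg a `mvrxn_schnet_config`.
#' @param params conformer-encoder parameters.
#' @param mode `"eval"` (deterministic) or `"train"`.
#' @return numeric matrix, one 2*hidden_dim row per reaction.
#' @export
encode_conformer_view <- function(reactions, cfg, params,
                                  mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (inherits(reactions, "mvrxn_reaction")) reactions <- list(reactions)
  tape <- tape_new()
  pnodes <- params_to_nodes(tape, params)
  conf_forward(tape, reactions, cfg, pnodes,
               train = (mode == "train"))$value
}
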