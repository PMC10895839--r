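# Seeded generator of valid synthetic reactions with both views and planted
# yields.  Molecules come from a curated fragment library of small organics
# (alkanes, alcohols, amines, halides, simple aromatics); yields are a
# linear function of tokenizer-derived molecular features plus Gaussian
# noise, so a linear oracle on the true features bounds what any encoder
# can recover.

DEFAULT_FRAGMENTS <- c(
  "C", "CC", "CCC", "CCCC", "CCO", "CC(C)O", "OCC(O)CO", "CCN", "CCCN",
  "CC(=O)O", "CC(=O)OC", "CCOC(C)=O", "C=CC", "C#N", "CCS",
  "c1ccccc1", "Cc1ccccc1", "c1ccncc1", "Oc1ccccc1",
  "CCCl", "CCBr", "CCI", "CCF", "ClCCCl", "BrCCBr", "Clc1ccccc1")

# fragments safe to splice by string concatenation (simple acyclic chains)
CHAINABLE <- c("C", "CC", "CCC", "CCCC", "CCO", "CCN")

#' Recipe for a synthetic reaction dataset
#'
#' @param n_reactions number of reactions to generate.
#' @param fragments SMILES fragment library; every entry must parse.
#' @param mol_range inclusive range for the total molecule count per
#'   reaction, default `c(2, 6)`.
#' @param beta named planted yield coefficients over the features returned
#'   by [reaction_features()], plus an `(Intercept)` term.
#' @param sigma Gaussian noise standard deviation, in yield points.
#' @param conformer_mode `"rule_based"` (deterministic idealized helix
#'   geometries, toolkit-free) or `"openbabel"` (toolkit 3D builder).
#' @param seed integer seed.
#' @return an object of class `mvrxn_synthetic_spec`.
#' @export
synthetic_spec <- function(n_reactions = 200L,
                           fragments = DEFAULT_FRAGMENTS,
                           mol_range = c(2L, 6L),
                           beta = default_planted_beta(),
                           sigma = 5,
                           conformer_mode = c("rule_based", "openbabel"),
                           seed = 1L) {
  conformer_mode <- match.arg(conformer_mode)
  stopifnot(n_reactions >= 1L, sigma >= 0, length(fragments) >= 2L,
            mol_range[1L] >= 2L, mol_range[2L] >= mol_range[1L])
  can <- canonical_smiles(fragments)
  if (anyNA(can))
    stop("spec validation error: invalid fragment(s): ",
         paste(fragments[is.na(can)], collapse = ", "))
  structure(list(n_reactions = as.integer(n_reactions), fragments = fragments,
                 mol_range = as.integer(mol_range), beta = beta,
                 sigma = sigma, conformer_mode = conformer_mode,
                 seed = as.integer(seed)),
            class = "mvrxn_synthetic_spec")
}

#' Default planted yield coefficients
#'
#' Chosen so the noise-free yield spans most of (0, 100] over the default
#' fragment library and the signal standard deviation is large against the
#' default 5-point noise.
#' @return named numeric vector of coefficients.
#' @export
default_planted_beta <- function() {
  c("(Intercept)" = 60, n_halogen = -12, n_oxygen = 7, n_aromatic = -1.5,
    n_ring_bond = 5, n_molecules = 4, seq_length = -0.5)
}

#' Interpretable token-level features of a reaction
#'
#' Computed from the same tokenizer the sequence encoder sees, over all
#' molecules in canonical order: halogen atom tokens (F, Cl, Br, I),
#' oxygen tokens, aromatic-carbon tokens, ring-bond digit tokens, molecule
#' count, and total token count.
#'
#' @param r an `mvrxn_reaction`.
#' @return named numeric feature vector.
#' @export
reaction_features <- function(r) {
  toks <- unlist(lapply(reaction_molecules(r),
                        function(m) tokenize_smiles(m$smiles)))
  c(n_halogen = sum(toks %in% c("F", "Cl", "Br", "I")),
    n_oxygen = sum(toks %in% c("O", "o")),
    n_aromatic = sum(toks == "c"),
    n_ring_bond = sum(grepl("^[0-9]$|^%[0-9][0-9]$", toks)) / 2,
    n_molecules = n_molecules(r),
    seq_length = length(toks))
}

#' Deterministic rule-based 3D embedder
#'
#' Places the heavy atoms of a molecule on an idealized helix with
#' bond-scale spacing — deterministic, toolkit-free coordinates for tests
#' of geometric invariance and plumbing.  Ignores the seed by design.
#'
#' @return an embedder function `(smiles, seed) -> m x 3 matrix`.
#' @export
rule_based_embedder <- function(radius = 1.4, pitch = 0.5, turn = 0.7) {
  function(smiles, seed = 0L) {
    atoms <- smiles_atoms(smiles)
    m <- length(atoms)
    if (m == 0L) return(NULL)
    i <- seq_len(m) - 1L
    z <- tryCatch(atoms_to_z(atoms), error = function(e) NULL)
    if (is.null(z)) return(NULL)
    cbind(radius * cos(turn * i),
          radius * sin(turn * i),
          pitch * i + 0.05 * (z %% 7))
  }
}

#' Toolkit 3D embedder (Open Babel gen3d)
#'
#' @return an embedder function `(smiles, seed) -> m x 3 matrix or NULL`.
#' @export
openbabel_embedder <- function() {
  function(smiles, seed = 0L) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SMI", "SDF", smiles,
        options = data.frame(names = "gen3d", args = ""))),
      error = function(e) "")
    if (!nzchar(sdf)) return(NULL)
    lines <- strsplit(sdf, "\n", fixed = TRUE)[[1L]]
    na <- suppressWarnings(as.integer(substr(lines[4L], 1L, 3L)))
    if (is.na(na) || na < 1L) return(NULL)
    atom_lines <- lines[4L + seq_len(na)]
    co <- t(vapply(atom_lines, function(l) {
      c(as.numeric(substr(l, 1L, 10L)), as.numeric(substr(l, 11L, 20L)),
        as.numeric(substr(l, 21L, 30L)))
    }, numeric(3)))
    sym <- trimws(substr(atom_lines, 32L, 34L))
    atoms <- smiles_atoms(smiles)
    # gen3d adds explicit hydrogens; keep the heavy-atom block, which Open
    # Babel writes in input order.  Molecules with explicit bracket
    # hydrogens are reported as failures rather than guessed at.
    if ("H" %in% atoms) return(NULL)
    co <- co[sym != "H", , drop = FALSE]
    rownames(co) <- NULL
    if (nrow(co) != length(atoms)) return(NULL)
    co
  }
}

spec_embedder <- function(spec) {
  switch(spec$conformer_mode,
         rule_based = rule_based_embedder(),
         openbabel = openbabel_embedder())
}

#' Generate synthetic molecules
#'
#' Samples `k` molecules from the fragment library; with small probability
#' two chainable fragments are spliced into a longer chain.  Coordinates
#' are attached according to the spec's conformer mode.
#'
#' @param spec an `mvrxn_synthetic_spec`.
#' @param k number of molecules.
#' @param seed integer seed (defaults to the spec seed).
#' @return list of `mvrxn_molecule` with coordinates.
#' @export
generate_synthetic_molecules <- function(spec, k, seed = spec$seed) {
  embedder <- spec_embedder(spec)
  withr::with_seed(as.integer(seed), {
    smls <- vapply(seq_len(k), function(i) {
      if (stats::runif(1) < 0.25) {
        paste0(sample(CHAINABLE, 1L), sample(CHAINABLE, 1L))
      } else {
        sample(spec$fragments, 1L)
      }
    }, character(1))
  })
  lapply(smls, function(s) {
    can <- canonical_smiles(s)
    mseed <- (as.numeric(spec$seed) + stable_string_hash(can)) %% 2147483647
    molecule(can, coords = embedder(can, as.integer(mseed)),
             canonicalize = FALSE)
  })
}

#' Assemble a synthetic reaction dataset
#'
#' `n_reactions` records with reactants, agents, and products drawn from
#' generated molecules; the total molecule count per reaction varies over
#' the configured range; both views (SMILES and conformers) are present.
#'
#' @param spec an `mvrxn_synthetic_spec`.
#' @return an `mvrxn_dataset` (unlabelled; see [plant_yield_labels()]).
#' @export
assemble_synthetic_reactions <- function(spec) {
  records <- vector("list", spec$n_reactions)
  withr::with_seed(spec$seed, {
    plans <- lapply(seq_len(spec$n_reactions), function(i) {
      n_tot <- sample(seq(spec$mol_range[1L], spec$mol_range[2L]), 1L)
      n_prod <- sample(seq_len(min(2L, n_tot - 1L)), 1L)
      n_react <- sample(seq_len(min(3L, n_tot - n_prod)), 1L)
      n_ag <- n_tot - n_prod - n_react
      list(n_react = n_react, n_ag = n_ag, n_prod = n_prod,
           seed = sample.int(2147483646L, 1L))
    })
  })
  for (i in seq_along(plans)) {
    pl <- plans[[i]]
    mols <- generate_synthetic_molecules(
      spec, pl$n_react + pl$n_ag + pl$n_prod, seed = pl$seed)
    records[[i]] <- reaction(
      reactants = mols[seq_len(pl$n_react)],
      agents = if (pl$n_ag > 0L) mols[pl$n_react + seq_len(pl$n_ag)] else list(),
      products = mols[pl$n_react + pl$n_ag + seq_len(pl$n_prod)],
      record_id = sprintf("syn%05d", i))
  }
  reaction_dataset(records, provenance = "synthetic")
}

#' Plant yield labels on a dataset
#'
#' `y = clip(beta . features + N(0, sigma), 0.5, 100)`, features computed by
#' [reaction_features()] from the same tokenizer the model sees, so the
#' signal is learnable by construction.  The 0.5 floor keeps every label
#' valid under the (0, 100] yield rule.
#'
#' @param d an `mvrxn_dataset`.
#' @param spec an `mvrxn_synthetic_spec` carrying `beta`, `sigma`, `seed`.
#' @return the dataset with `yield_pct` set on every record.
#' @export
plant_yield_labels <- function(d, spec) {
  feats <- t(vapply(d$records, reaction_features,
                    numeric(length(reaction_features(d$records[[1L]])))))
  bn <- setdiff(names(spec$beta), "(Intercept)")
  if (!all(bn %in% colnames(feats)))
    stop("spec validation error: beta names must match reaction_features()")
  mu <- spec$beta[["(Intercept)"]] +
    as.numeric(feats[, bn, drop = FALSE] %*% spec$beta[bn])
  withr::with_seed(spec$seed + 1L, {
    y <- mu + stats::rnorm(length(mu), 0, spec$sigma)
  })
  y <- pmin(pmax(y, 0.5), 100)
  for (i in seq_along(d$records)) d$records[[i]]$yield_pct <- y[i]
  d
}

#' Generate a complete labelled synthetic dataset
#'
#' Convenience wrapper: assemble reactions, plant yields.
#' @param spec an `mvrxn_synthetic_spec`.
#' @return a labelled `mvrxn_dataset`.
#' @export
make_synthetic_dataset <- function(spec) {
  plant_yield_labels(assemble_synthetic_reactions(spec), spec)
}
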