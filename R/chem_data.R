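# Reaction and molecule data model: parsing of reaction SMILES, toolkit
# canonicalization (Open Babel via ChemmineOB), and element extraction.

# atomic numbers for the element set the conformer encoder supports
ELEMENT_Z <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Na = 11L,
               Si = 14L, P = 15L, S = 16L, Cl = 17L, K = 19L, Br = 35L,
               I = 53L)

# memo cache: canonicalization is called heavily on a small molecule pool
.canon_cache <- new.env(parent = emptyenv())

#' Canonical SMILES via the chemistry toolkit
#'
#' Vectorized canonicalization through Open Babel.  Invalid SMILES give
#' `NA`.  Batch conversion is attempted first; Open Babel truncates its
#' output at the first invalid entry, so on a count mismatch the function
#' falls back to per-molecule conversion.
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES, `NA` where invalid.
#' @export
canonical_smiles <- function(smiles) {
  out <- character(length(smiles))
  cached <- vapply(smiles, function(s) exists(s, envir = .canon_cache,
                                              inherits = FALSE), logical(1))
  out[cached] <- vapply(smiles[cached], get, character(1), envir = .canon_cache)
  todo <- which(!cached)
  if (length(todo)) {
    fresh <- vapply(unique(smiles[todo]), canonicalize_one, character(1))
    for (i in seq_along(fresh)) {
      assign(names(fresh)[i], fresh[i], envir = .canon_cache)
    }
    out[todo] <- fresh[smiles[todo]]
  }
  out[out == ""] <- NA_character_
  unname(out)
}

canonicalize_one <- function(s) {
  if (!nzchar(s)) return("")
  res <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
    error = function(e) "")
  res <- sub("[\t\n ].*$", "", res)
  if (is.na(res)) res <- ""
  res
}

is_valid_smiles <- function(smiles) !is.na(canonical_smiles(smiles))

#' Construct a molecule
#'
#' A molecule is a canonical-SMILES string plus the ordered element-symbol
#' list derived from it and, optionally, an m x 3 matrix of Cartesian
#' coordinates in Angstrom.
#'
#' @param smiles SMILES string (canonicalized on construction unless
#'   `canonicalize = FALSE`).
#' @param coords optional m x 3 numeric matrix, rows matching `atoms`.
#' @param canonicalize canonicalize through the toolkit (default TRUE).
#' @return an object of class `mvrxn_molecule`.
#' @export
molecule <- function(smiles, coords = NULL, canonicalize = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (canonicalize) {
    can <- canonical_smiles(smiles)
    if (is.na(can)) stop("validity error: unparseable SMILES '", smiles, "'")
    smiles <- can
  }
  atoms <- smiles_atoms(smiles)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != length(atoms))
      stop("invariant violation: ", nrow(coords), " coordinate rows for ",
           length(atoms), " atoms in '", smiles, "'")
    if (!all(is.finite(coords)))
      stop("invariant violation: non-finite coordinates in '", smiles, "'")
  }
  structure(list(smiles = smiles, atoms = atoms, coords = coords),
            class = "mvrxn_molecule")
}

#' Heavy-atom element symbols of a SMILES string
#'
#' Walks the token stream and returns element symbols in order of
#' appearance.  Inside a bracket atom only the leading element symbol
#' counts (hydrogen-count suffixes are not atoms, but `[H+]` itself is).
#'
#' @param smiles SMILES string.
#' @return character vector of element symbols.
#' @export
smiles_atoms <- function(smiles) {
  toks <- tokenize_smiles(smiles, dialect = "bracket")
  atoms <- character(0L)
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    tk <- toks[i]
    if (tk == "[") {
      j <- i + 1L
      # skip isotope digits, then the first element token is the atom
      while (j <= n && grepl("^[0-9]$", toks[j])) j <- j + 1L
      if (j <= n && toks[j] != "]") {
        sym <- toks[j]
        if (grepl("^[a-z]", sym)) {
          sym <- paste0(toupper(substr(sym, 1L, 1L)), substring(sym, 2L))
        }
        if (sym %in% PERIODIC_SYMBOLS) atoms <- c(atoms, sym)
      }
      while (i <= n && toks[i] != "]") i <- i + 1L
      i <- i + 1L
      next
    }
    if (tk %in% PERIODIC_SYMBOLS) {
      atoms <- c(atoms, tk)
    } else if (grepl("^[bcnops]$", tk)) {
      atoms <- c(atoms, toupper(tk))
    }
    i <- i + 1L
  }
  atoms
}

atoms_to_z <- function(atoms) {
  z <- ELEMENT_Z[atoms]
  if (anyNA(z)) {
    bad <- atoms[is.na(z)]
    stop("unsupported element: ", paste(unique(bad), collapse = ", "))
  }
  unname(z)
}

#' Construct a reaction
#'
#' @param reactants,agents,products lists of `mvrxn_molecule` (agents may
#'   be empty; reactants and products must not be).
#' @param yield_pct optional yield percentage in (0, 100].
#' @param record_id opaque identifier string.
#' @return an object of class `mvrxn_reaction`.
#' @export
reaction <- function(reactants, agents = list(), products,
                     yield_pct = NA_real_, record_id = NULL) {
  stopifnot(length(reactants) >= 1L, length(products) >= 1L)
  if (length(reactants) + length(agents) + length(products) < 2L)
    stop("invariant violation: a reaction needs at least two molecules")
  if (!is.na(yield_pct) && (yield_pct <= 0 || yield_pct > 100))
    stop("invariant violation: yield_pct must lie in (0, 100], got ", yield_pct)
  structure(list(reactants = reactants, agents = agents, products = products,
                 yield_pct = as.numeric(yield_pct),
                 record_id = record_id %||% ""),
            class = "mvrxn_reaction")
}

#' Parse a reaction SMILES string
#'
#' Splits `"reactants>agents>products"` on the two `>` separators and `.`
#' within each field; each molecule is canonicalized.  The agents field may
#' be empty; reactant and product fields may not.
#'
#' @param text reaction SMILES string.
#' @param record_id identifier attached to the parsed record.
#' @param yield_pct optional yield percentage.
#' @return an `mvrxn_reaction`.
#' @export
parse_reaction_smiles <- function(text, record_id = NULL, yield_pct = NA_real_) {
  stopifnot(is.character(text), length(text) == 1L)
  fields <- strsplit(text, ">", fixed = TRUE)[[1L]]
  ngt <- nchar(gsub("[^>]", "", text))
  if (ngt != 2L)
    stop("parse error: reaction SMILES needs exactly two '>' separators, ",
         "got ", ngt, " in '", text, "'")
  fields <- c(fields, rep("", 3L - length(fields)))[1:3]
  if (!nzchar(fields[1L]) || !nzchar(fields[3L]))
    stop("parse error: empty reactant or product field in '", text, "'")
  parse_field <- function(f) {
    if (!nzchar(f)) return(list())
    parts <- strsplit(f, ".", fixed = TRUE)[[1L]]
    lapply(parts, function(p) {
      if (!is_valid_smiles(p))
        stop("parse error: unparseable molecule '", p, "' in '", text, "'")
      molecule(p)
    })
  }
  reaction(reactants = parse_field(fields[1L]),
           agents = parse_field(fields[2L]),
           products = parse_field(fields[3L]),
           yield_pct = yield_pct, record_id = record_id)
}

#' Canonicalize a reaction
#'
#' Replaces every molecule by its canonical SMILES and sorts molecules
#' within each role lexicographically — the deduplication key order.
#' Idempotent.
#'
#' @param r an `mvrxn_reaction`.
#' @return the canonicalized reaction.
#' @export
canonicalize_reaction <- function(r) {
  canon_role <- function(mols) {
    mols <- lapply(mols, function(m) {
      can <- canonical_smiles(m$smiles)
      if (is.na(can)) stop("validity error: unparseable SMILES '", m$smiles, "'")
      if (identical(can, m$smiles)) m else molecule(can, coords = NULL,
                                                   canonicalize = FALSE)
    })
    mols[order(vapply(mols, function(m) m$smiles, character(1)),
               method = "radix")]
  }
  r$reactants <- canon_role(r$reactants)
  r$agents <- canon_role(r$agents)
  r$products <- canon_role(r$products)
  r
}

#' Canonical duplicate key of a reaction
#'
#' `"reactants>agents>products"` over role-sorted canonical SMILES; yields
#' are not part of the key.
#' @param r an `mvrxn_reaction` (already canonicalized).
#' @return a string key.
#' @export
reaction_key <- function(r) {
  role_key <- function(mols) {
    s <- sort(vapply(mols, function(m) m$smiles, character(1)),
              method = "radix")
    paste(s, collapse = ".")
  }
  paste(role_key(r$reactants), role_key(r$agents), role_key(r$products),
        sep = ">")
}

#' Reaction SMILES of a reaction object (inverse of parsing)
#' @param r an `mvrxn_reaction`.
#' @export
reaction_smiles <- function(r) reaction_key(r)

# canonical molecule order shared by the sequence and conformer views:
# reactants, then agents, then products; lexicographic within each role
reaction_molecules <- function(r) {
  ord <- function(mols) mols[order(vapply(mols, function(m) m$smiles,
                                          character(1)), method = "radix")]
  c(ord(r$reactants), ord(r$agents), ord(r$products))
}

n_molecules <- function(r) {
  length(r$reactants) + length(r$agents) + length(r$products)
}

#' Construct a reaction dataset
#'
#' @param records list of `mvrxn_reaction` with unique, nonempty record ids.
#' @param provenance free-text metadata.
#' @param split_labels optional named character vector (record_id ->
#'   `"train"`/`"valid"`/`"test"`) covering every record exactly once.
#' @return an object of class `mvrxn_dataset`.
#' @export
reaction_dataset <- function(records, provenance = "", split_labels = NULL) {
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (any(!nzchar(ids))) {
    ids[!nzchar(ids)] <- sprintf("r%06d", which(!nzchar(ids)))
    records <- Map(function(r, id) { r$record_id <- id; r }, records, ids)
  }
  if (anyDuplicated(ids))
    stop("invariant violation: duplicate record_ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(records) <- ids
  if (!is.null(split_labels)) check_split_labels(split_labels, ids)
  structure(list(records = records, split_labels = split_labels,
                 provenance = provenance),
            class = "mvrxn_dataset")
}

check_split_labels <- function(split_labels, ids) {
  if (!setequal(names(split_labels), ids))
    stop("invariant violation: split labels must cover every record exactly once")
  if (!all(split_labels %in% c("train", "valid", "test")))
    stop("invariant violation: split labels must be train/valid/test")
  invisible(TRUE)
}

#' @export
print.mvrxn_dataset <- function(x, ...) {
  cat("<mvrxn_dataset>", length(x$records), "reactions")
  ny <- sum(!is.na(vapply(x$records, function(r) r$yield_pct, numeric(1))))
  cat(",", ny, "with yields")
  if (!is.null(x$split_labels)) {
    tb <- table(x$split_labels)
    cat(" | split:", paste(names(tb), tb, sep = "=", collapse = " "))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.mvrxn_dataset <- function(x) length(x$records)

dataset_yields <- function(d) {
  vapply(d$records, function(r) r$yield_pct, numeric(1))
}

subset_dataset <- function(d, keep_ids) {
  d$records <- d$records[keep_ids]
  if (!is.null(d$split_labels)) d$split_labels <- d$split_labels[keep_ids]
  d
}
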