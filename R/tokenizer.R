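# Character-level SMILES tokenization with three exceptions, vocabulary
# construction with a frequency floor, and reaction encoding with the
# [CLS]/[SEP]/[PAD]/[UNK] special-token layout.

# periodic-table symbols, used to recognise two-letter atoms
PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U")

SPECIAL_TOKENS <- c("[PAD]", "[CLS]", "[SEP]", "[UNK]")

#' Tokenize a SMILES string
#'
#' Splits a SMILES string at the character level with three exceptions:
#' `%` plus the following two digits is one ring-bond token; `Cl` and `Br`
#' outside brackets are single atom tokens; inside `[...]` a maximal element
#' symbol (including two-letter lowercase aromatic symbols such as `se`) is
#' one token.  Concatenating the returned tokens always reproduces the
#' input exactly.
#'
#' @param s a single SMILES string.
#' @param dialect `"bracket"` (default, element-aware inside brackets) or
#'   `"character"` (pure single characters apart from the `%dd` rule).
#' @return character vector of tokens.
#' @export
tokenize_smiles <- function(s, dialect = c("bracket", "character")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  tokens <- character(0L)
  i <- 1L
  in_bracket <- FALSE
  is_lower <- function(x) grepl("^[a-z]$", x)
  is_upper <- function(x) grepl("^[A-Z]$", x)
  while (i <= n) {
    c1 <- ch[i]
    if (c1 == "[") {
      if (in_bracket) stop("tokenization error: nested '[' in ", s)
      in_bracket <- TRUE
      tokens <- c(tokens, c1); i <- i + 1L; next
    }
    if (c1 == "]") {
      if (!in_bracket) stop("tokenization error: unbalanced ']' in ", s)
      in_bracket <- FALSE
      tokens <- c(tokens, c1); i <- i + 1L; next
    }
    if (!in_bracket) {
      if (c1 == "%") {
        if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(ch[i + 1L], ch[i + 2L])))
          stop("tokenization error: '%' not followed by two digits in ", s)
        tokens <- c(tokens, paste0("%", ch[i + 1L], ch[i + 2L])); i <- i + 3L; next
      }
      # Cl / Br are single tokens in both dialects: a bare 'l'/'r' is not
      # a SMILES atom, so the merge is unambiguous
      if (c1 == "C" && i < n && ch[i + 1L] == "l") {
        tokens <- c(tokens, "Cl"); i <- i + 2L; next
      }
      if (c1 == "B" && i < n && ch[i + 1L] == "r") {
        tokens <- c(tokens, "Br"); i <- i + 2L; next
      }
      tokens <- c(tokens, c1); i <- i + 1L; next
    }
    # inside brackets
    if (dialect == "bracket" && i < n) {
      pair <- paste0(c1, ch[i + 1L])
      two <- (is_upper(c1) && is_lower(ch[i + 1L]) && pair %in% PERIODIC_SYMBOLS) ||
        (is_lower(c1) && is_lower(ch[i + 1L]) &&
           paste0(toupper(c1), ch[i + 1L]) %in% PERIODIC_SYMBOLS)
      if (two) {
        tokens <- c(tokens, pair); i <- i + 2L; next
      }
    }
    tokens <- c(tokens, c1); i <- i + 1L
  }
  if (in_bracket) stop("tokenization error: unbalanced '[' in ", s)
  tokens
}

#' Build a token vocabulary from a corpus
#'
#' Tokens with corpus frequency below `min_frequency` are excluded and map
#' to `[UNK]` at encode time.  The four special tokens `[PAD]`, `[CLS]`,
#' `[SEP]`, `[UNK]` occupy indices 0-3; remaining tokens are ordered by
#' descending frequency with lexicographic tie-breaks, so the vocabulary is
#' a deterministic function of the corpus.
#'
#' @param corpus list of token vectors (from [tokenize_smiles()]).
#' @param min_frequency integer frequency floor (default 10).
#' @param dialect tokenizer dialect the corpus was produced with.
#' @return an object of class `mvrxn_vocab`.
#' @export
build_vocabulary <- function(corpus, min_frequency = 10L, dialect = "bracket") {
  if (min_frequency < 1L) stop("config error: min_frequency must be >= 1")
  stopifnot(length(corpus) > 0L)
  freq <- table(unlist(corpus, use.names = FALSE))
  freq <- freq[freq >= min_frequency]
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  toks <- c(SPECIAL_TOKENS, names(freq)[ord])
  idx <- stats::setNames(seq_along(toks) - 1L, toks)
  structure(list(tokens = toks, index = idx,
                 min_frequency = as.integer(min_frequency),
                 dialect = dialect),
            class = "mvrxn_vocab")
}

#' @export
print.mvrxn_vocab <- function(x, ...) {
  cat("<mvrxn_vocab>", length(x$tokens), "tokens (4 special), min_frequency =",
      x$min_frequency, ", dialect =", x$dialect, "\n")
  invisible(x)
}

#' Vocabulary size (including the four special tokens)
#' @param v an `mvrxn_vocab`.
#' @return integer.
#' @export
vocab_size <- function(v) length(v$tokens)

#' Save / load a vocabulary as plain text
#'
#' One token per line preceded by a single JSON header line with
#' `min_frequency` and `dialect`.
#' @param v vocabulary; `path` file path.
#' @export
write_vocabulary <- function(v, path) {
  hdr <- jsonlite::toJSON(list(min_frequency = v$min_frequency,
                               dialect = v$dialect), auto_unbox = TRUE)
  writeLines(c(as.character(hdr), v$tokens), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1L])
  toks <- lines[-1L]
  if (!identical(toks[1:4], SPECIAL_TOKENS))
    stop("I/O error: vocabulary file lacks the special-token header rows")
  structure(list(tokens = toks,
                 index = stats::setNames(seq_along(toks) - 1L, toks),
                 min_frequency = as.integer(hdr$min_frequency),
                 dialect = hdr$dialect),
            class = "mvrxn_vocab")
}

# stable hash of the vocabulary (for checkpoint compatibility checks)
vocab_hash <- function(v) {
  stable_string_hash(paste(c(v$tokens, v$min_frequency, v$dialect),
                           collapse = "\n"))
}

#' Encode a reaction as a token-index sequence
#'
#' Layout: `[CLS]`, tokens of molecule 1, `[SEP]`, tokens of molecule 2,
#' `[SEP]`, ... with molecules in the canonical order shared with the
#' conformer view (reactants, agents, products; lexicographic within each
#' role).  Unknown tokens become `[UNK]`; the sequence is padded with
#' `[PAD]` to `max_len`.  Indices are 0-based with `[PAD] = 0`.
#'
#' @param r an `mvrxn_reaction`.
#' @param v an `mvrxn_vocab`.
#' @param max_len maximum sequence length; longer sequences are an error.
#' @return an `mvrxn_encoded` object with fields `ids` and `length`.
#' @export
encode_reaction <- function(r, v, max_len = 256L) {
  mols <- reaction_molecules(r)
  ids <- v$index[["[CLS]"]]
  unk <- v$index[["[UNK]"]]
  lossy <- FALSE
  for (m in mols) {
    toks <- tokenize_smiles(m$smiles, dialect = v$dialect)
    ti <- unname(v$index[toks])
    if (anyNA(ti)) lossy <- TRUE
    ti[is.na(ti)] <- unk
    ids <- c(ids, ti, v$index[["[SEP]"]])
  }
  len <- length(ids)
  if (len > max_len)
    stop("length error: encoded sequence for record '", r$record_id,
         "' has ", len, " tokens > max_len = ", max_len)
  ids <- c(ids, rep(v$index[["[PAD]"]], max_len - len))
  structure(list(ids = as.integer(ids), length = as.integer(len),
                 lossy = lossy, record_id = r$record_id),
            class = "mvrxn_encoded")
}

#' Decode a token-index sequence back to per-molecule SMILES
#'
#' Strips special tokens, splits on `[SEP]`, and concatenates tokens per
#' molecule.  The result carries a `lossy` attribute when the sequence
#' contains `[UNK]`, in which case the round trip is not the identity.
#'
#' @param e an `mvrxn_encoded`; `v` the vocabulary it was encoded with.
#' @return character vector of SMILES, one per molecule.
#' @export
decode_tokens <- function(e, v) {
  ids <- e$ids[seq_len(e$length)]
  if (any(ids < 0L | ids >= vocab_size(v)))
    stop("decode error: token index out of range for this vocabulary")
  toks <- v$tokens[ids + 1L]
  toks <- toks[toks != "[CLS]" & toks != "[PAD]"]
  lossy <- any(toks == "[UNK]")
  mols <- character(0L)
  cur <- character(0L)
  for (tk in toks) {
    if (tk == "[SEP]") {
      mols <- c(mols, paste(cur, collapse = ""))
      cur <- character(0L)
    } else {
      cur <- c(cur, tk)
    }
  }
  if (length(cur)) mols <- c(mols, paste(cur, collapse = ""))
  attr(mols, "lossy") <- lossy
  mols
}

# deterministic 31-bit polynomial string hash (used for seed fan-out and
# artifact fingerprints; not cryptographic)
stable_string_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}
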