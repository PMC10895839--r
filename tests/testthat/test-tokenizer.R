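test_that("the three tokenization exceptions behave as specified", {
  expect_identical(tokenize_smiles("C%12CC%12"),
                   c("C", "%12", "C", "C", "%12"))
  expect_identical(tokenize_smiles("ClCCBr"), c("Cl", "C", "C", "Br"))
  expect_identical(tokenize_smiles("c1[cs]cc1"),
                   c("c", "1", "[", "cs", "]", "c", "c", "1"))
  expect_identical(tokenize_smiles("cscc"), c("c", "s", "c", "c"))
  # two-letter elements only merge inside brackets
  expect_identical(tokenize_smiles("[Se]"), c("[", "Se", "]"))
  expect_identical(tokenize_smiles("[NH4+]"), c("[", "N", "H", "4", "+", "]"))
  expect_identical(tokenize_smiles("[13CH4]"),
                   c("[", "1", "3", "C", "H", "4", "]"))
})

test_that("malformed strings are tokenization errors", {
  expect_error(tokenize_smiles("C[NH"), "unbalanced")
  expect_error(tokenize_smiles("CN]C"), "unbalanced")
  expect_error(tokenize_smiles("C%1C"), "two digits")
})

test_that("the character dialect splits bracket contents per character", {
  expect_identical(tokenize_smiles("c1[cs]cc1", dialect = "character"),
                   c("c", "1", "[", "c", "s", "]", "c", "c", "1"))
  expect_identical(tokenize_smiles("C%12C", dialect = "character"),
                   c("C", "%12", "C"))
})

test_that("segmentation is lossless over a large synthetic SMILES pool", {
  pool <- random_smiles_pool(1000L, seed = 42L)
  for (s in pool) {
    expect_identical(paste(tokenize_smiles(s), collapse = ""), s)
  }
})

test_that("vocabulary applies the frequency floor and is deterministic", {
  corpus <- c(rep(list(c("C", "O")), 9L), rep(list("C"), 91L))
  v <- build_vocabulary(corpus, min_frequency = 10L)
  expect_identical(v$tokens[1:4], c("[PAD]", "[CLS]", "[SEP]", "[UNK]"))
  expect_true("C" %in% v$tokens)
  expect_false("O" %in% v$tokens)  # frequency 9 < 10
  expect_identical(unname(v$index[["[PAD]"]]), 0L)
  v100 <- build_vocabulary(list(rep("C", 100L), rep("O", 100L)),
                           min_frequency = 10L)
  expect_identical(vocab_size(v100), 6L)
  expect_error(build_vocabulary(corpus, min_frequency = 0L), "config error")
  # determinism incl. the persisted form
  v2 <- build_vocabulary(corpus, min_frequency = 10L)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_vocabulary(v, f1)
  write_vocabulary(v2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(read_vocabulary(f1)$index, v$index)
})

test_that("encoding lays out [CLS]/[SEP]/[PAD] and round-trips", {
  r <- parse_reaction_smiles("CCO.CCN>>CCOC", record_id = "t1")
  corpus <- lapply(mvrxn:::reaction_molecules(r),
                   function(m) tokenize_smiles(m$smiles))
  v <- build_vocabulary(corpus, min_frequency = 1L)
  e <- encode_reaction(r, v, max_len = 32L)
  toks <- v$tokens[e$ids + 1L]
  expect_identical(toks[1L], "[CLS]")
  expect_identical(toks[e$length], "[SEP]")
  expect_true(all(toks[seq(e$length + 1L, 32L)] == "[PAD]"))
  expect_false(e$lossy)
  mols <- decode_tokens(e, v)
  expect_identical(as.character(mols),
                   vapply(mvrxn:::reaction_molecules(r),
                          function(m) m$smiles, character(1)))
  expect_false(attr(mols, "lossy"))
})

test_that("unknown tokens become [UNK] and flag the round trip lossy", {
  r <- parse_reaction_smiles("CCO>>CCBr", record_id = "t2")
  v <- build_vocabulary(list(c("C", "O", "(", ")")), min_frequency = 1L)
  e <- encode_reaction(r, v, max_len = 32L)
  expect_true(e$lossy)
  expect_true(v$index[["[UNK]"]] %in% e$ids)
  mols <- decode_tokens(e, v)
  expect_true(attr(mols, "lossy"))
})

test_that("over-length sequences raise a length error naming the record", {
  r <- parse_reaction_smiles("CCCCCCCCCC>>CCCCCCCCC", record_id = "long1")
  v <- build_vocabulary(list("C"), min_frequency = 1L)
  expect_error(encode_reaction(r, v, max_len = 8L), "long1")
})

test_that("encode/decode round trip is the identity on a synthetic corpus", {
  d <- assemble_synthetic_reactions(tiny_spec(n = 25L, seed = 3L))
  v <- tiny_vocab_for(d)
  for (r in d$records) {
    e <- encode_reaction(r, v, max_len = 256L)
    expect_false(e$lossy)
    expect_identical(as.character(decode_tokens(e, v)),
                     vapply(mvrxn:::reaction_molecules(r),
                            function(m) m$smiles, character(1)))
  }
})
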