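test_that("reaction SMILES parsing follows the grammar", {
  r <- parse_reaction_smiles("CCO.CC(=O)O>[H+]>CCOC(C)=O", record_id = "a")
  expect_length(r$reactants, 2L)
  expect_length(r$agents, 1L)
  expect_length(r$products, 1L)
  expect_identical(r$agents[[1L]]$smiles, canonical_smiles("[H+]"))
  r2 <- parse_reaction_smiles("CCO>>CC=O")
  expect_length(r2$agents, 0L)
  expect_error(parse_reaction_smiles("CCO>CC=O"), "two '>'")
  expect_error(parse_reaction_smiles("CCO>>CC>O"), "two '>'")
  expect_error(parse_reaction_smiles(">>CCO"), "empty reactant")
  expect_error(parse_reaction_smiles("CCO.X#Q>>CC"), "X#Q")
})

test_that("canonicalization normalizes and sorts molecules, idempotently", {
  r <- reaction(reactants = list(molecule("OCC", canonicalize = FALSE),
                                 molecule("CC(=O)O", canonicalize = FALSE)),
                products = list(molecule("CCOC(C)=O", canonicalize = FALSE)),
                record_id = "c1")
  rc <- canonicalize_reaction(r)
  smi <- vapply(rc$reactants, function(m) m$smiles, character(1))
  expect_identical(smi, sort(canonical_smiles(c("OCC", "CC(=O)O"))))
  expect_identical(canonicalize_reaction(rc), rc)
  bad <- reaction(reactants = list(molecule("X#Q", canonicalize = FALSE)),
                  products = list(molecule("C", canonicalize = FALSE)))
  expect_error(canonicalize_reaction(bad), "validity error")
})

test_that("molecule invariants are enforced", {
  expect_error(molecule("X#Q"), "validity error")
  expect_error(molecule("CCO", coords = matrix(0, 2L, 3L)),
               "coordinate rows")
  expect_error(molecule("CCO", coords = matrix(c(0, 0, Inf), 3L, 3L)),
               "non-finite")
  m <- molecule("OCC")
  expect_identical(m$smiles, canonical_smiles("OCC"))
  expect_identical(m$atoms, c("C", "C", "O"))
})

test_that("deduplication collapses permuted duplicates and prefers yields", {
  mk <- function(s, id, y = NA_real_) {
    canonicalize_reaction(parse_reaction_smiles(s, record_id = id,
                                                yield_pct = y))
  }
  d <- reaction_dataset(list(
    mk("CCO.CC(=O)O>>CCOC(C)=O", "r1"),
    mk("CC(=O)O.CCO>>CCOC(C)=O", "r2", y = 80),   # permuted reactants
    mk("CCO.CC(=O)O>>CCOC(C)=O", "r3"),
    mk("CCN>>CC=O", "r4")))
  res <- deduplicate_dataset(d)
  expect_length(res$dataset$records, 2L)
  expect_true("r2" %in% names(res$dataset$records))  # the yielded duplicate
  expect_identical(unname(res$report$counts),
                   c(4L, 2L))
  # idempotence
  res2 <- deduplicate_dataset(res$dataset)
  expect_identical(names(res2$dataset$records), names(res$dataset$records))
  # permuting molecules never changes the key
  expect_identical(reaction_key(d$records$r1), reaction_key(d$records$r2))
})

test_that("conformer attachment drops reactions with any failure", {
  d <- assemble_synthetic_reactions(tiny_spec(n = 10L, seed = 4L))
  flaky <- function(smiles, seed) {
    if (grepl("Cl|Br|I", smiles)) return(NULL)
    rule_based_embedder()(smiles, seed)
  }
  res <- attach_conformers(d, embedder = flaky, seed = 1L)
  has_halogen <- vapply(d$records, function(r)
    any(grepl("Cl|Br|I", vapply(mvrxn:::reaction_molecules(r),
                                function(m) m$smiles, character(1)))),
    logical(1))
  expect_identical(sort(names(res$dataset$records)),
                   sort(names(d$records)[!has_halogen]))
  expect_true(all(res$report$dropped$reason == "conformer embedding failed"))
  # every retained molecule carries one conformer
  for (r in res$dataset$records) {
    for (m in mvrxn:::reaction_molecules(r)) {
      expect_identical(nrow(m$coords), length(m$atoms))
    }
  }
  # determinism under a fixed seed
  res2 <- attach_conformers(d, embedder = flaky, seed = 1L)
  expect_identical(res$dataset, res2$dataset)
})

test_that("yield filtering enforces validity and samples low yields", {
  mk <- function(id, y) {
    r <- parse_reaction_smiles("CCO>>CC=O", record_id = id)
    r$yield_pct <- y
    r
  }
  d <- reaction_dataset(list(mk("a", 85), mk("b", 120), mk("c", NA),
                             mk("d", 30), mk("e", 0)))
  plain <- filter_by_yield(d, low_cut = 50, mode = "plain")
  expect_identical(sort(names(plain$dataset$records)), c("a", "d"))
  # low_fraction = 1 keeps all low-yield records
  aug1 <- filter_by_yield(d, low_cut = 50, low_fraction = 1, mode = "augment")
  expect_identical(sort(names(aug1$dataset$records)), c("a", "d"))
  expect_error(filter_by_yield(d, low_fraction = 1.5), "config error")
  # seeded half-sampling of 100 low-yield records keeps exactly 50
  dn <- reaction_dataset(c(lapply(1:100, function(i)
    mk(sprintf("lo%03d", i), runif(1, 1, 49))),
    lapply(1:20, function(i) mk(sprintf("hi%03d", i), runif(1, 60, 99)))))
  half <- filter_by_yield(dn, low_cut = 50, low_fraction = 0.5, seed = 7L,
                          mode = "augment")
  kept <- names(half$dataset$records)
  expect_identical(sum(grepl("^lo", kept)), 50L)
  expect_identical(sum(grepl("^hi", kept)), 20L)
  half2 <- filter_by_yield(dn, low_cut = 50, low_fraction = 0.5, seed = 7L,
                           mode = "augment")
  expect_identical(kept, names(half2$dataset$records))
})

test_that("dataset round trip through disk preserves everything", {
  d <- make_synthetic_dataset(tiny_spec(n = 8L, seed = 5L))
  d <- stratified_split(d, ratio = c(6L, 1L, 1L), seed = 2L)
  path <- withr::local_tempdir()
  write_dataset(d, path)
  d2 <- load_dataset(path)
  expect_identical(names(d2$records), names(d$records))
  expect_identical(d2$split_labels, d$split_labels)
  expect_equal(mvrxn:::dataset_yields(d2), mvrxn:::dataset_yields(d),
               tolerance = 1e-8)
  for (id in names(d$records)) {
    m1 <- mvrxn:::reaction_molecules(d$records[[id]])
    m2 <- mvrxn:::reaction_molecules(d2$records[[id]])
    expect_identical(vapply(m2, function(m) m$smiles, character(1)),
                     vapply(m1, function(m) m$smiles, character(1)))
    for (k in seq_along(m1)) {
      expect_equal(m2[[k]]$coords, m1[[k]]$coords, tolerance = 2e-4,
                   ignore_attr = TRUE)
    }
  }
})

test_that("loading rejects malformed tables with a line number", {
  path <- withr::local_tempdir()
  write.csv(data.frame(record_id = c("a", "b"),
                       reaction_smiles = c("CCO>>CC=O", "CCO>broken")),
            file.path(path, "reactions.csv"), row.names = FALSE)
  expect_error(load_dataset(path), "line 3")
  write.csv(data.frame(record_id = "a", reaction_smiles = "CCO>>CC=O"),
            file.path(path, "reactions.csv"), row.names = FALSE)
  expect_error(load_dataset(path, require_yields = TRUE), "yield_pct")
})

test_that("the SDF sidecar is readable by an independent SDF parser", {
  skip_if_not_installed("ChemmineR")
  d <- make_synthetic_dataset(tiny_spec(n = 4L, seed = 6L))
  path <- withr::local_tempdir()
  write_dataset(d, path)
  sdf <- suppressWarnings(
    ChemmineR::read.SDFset(file.path(path, "conformers.sdf")))
  n_mols <- sum(vapply(d$records, mvrxn:::n_molecules, integer(1)))
  expect_identical(length(sdf), n_mols)
  ab <- ChemmineR::atomblock(sdf[[1L]])
  m1 <- mvrxn:::reaction_molecules(d$records[[1L]])[[1L]]
  expect_equal(unname(ab[, 1:3]), unname(m1$coords), tolerance = 2e-4)
})

test_that("reaction-SMILES line files load with stable ids", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO>>CC=O", "", "CCN.CCO>[H+]>CCOCC"), path)
  d <- read_reaction_lines(path)
  expect_length(d$records, 2L)
  expect_identical(names(d$records), c("r000001", "r000002"))
})
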