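Package: mvrxn
Title: Multi-View Representation Learning for Chemical Reaction Yield
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns joint representations of chemical reactions from two
    complementary views - the SMILES token sequence and per-molecule 3D
    conformers - and predicts reaction yields.  Provides a reaction data
    model with a curation pipeline (canonicalization, deduplication,
    conformer attachment, yield filtering, stratified and component
    held-out splits), a character-level SMILES tokenizer with reaction
    special tokens, a bidirectional-GRU sequence encoder, a SchNet-style
    continuous-filter-convolution conformer encoder, two-stage
    pre-training (Jeffreys-divergence distribution alignment plus
    symmetric InfoNCE contrastive learning, then supervised yield
    regression), fine-tuning with a hyper-parameter grid search,
    regression and distribution-shift diagnostics, and a seeded synthetic
    reaction generator with planted yields so the whole pipeline is
    testable at desk scale.  The neural components run on a small built-in
    reverse-mode differentiation engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
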