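small_schnet_cfg <- function(...) {
  schnet_config(num_interactions = 2L, num_rbf = 16L, feature_dim = 12L,
                hidden_dim = 8L, num_layers = 2L, dropout = 0, ...)
}

test_that("the Gaussian RBF expansion follows its closed form", {
  cfg <- schnet_config(num_rbf = 5L, cutoff = 10, rbf_gamma = 2)
  mu <- seq(0, 10, length.out = 5L)
  e <- gaussian_rbf_expand(mu[3L], cfg)
  expect_equal(e[1L, 3L], 1)
  delta <- 0.7
  e2 <- gaussian_rbf_expand(mu[3L] + delta, cfg)
  expect_equal(e2[1L, 3L], exp(-2 * delta^2))
  vals <- gaussian_rbf_expand(c(0, 1.3, 9.9), cfg)
  expect_true(all(vals > 0 & vals <= 1))
  expect_error(gaussian_rbf_expand(-0.1, cfg), "negative")
})

test_that("the interaction block equals a brute-force per-pair loop", {
  cfg <- small_schnet_cfg()
  params <- withr::with_seed(7L, mvrxn:::conf_encoder_init(cfg)$blocks[[1L]])
  withr::local_seed(8L)
  for (m in c(2L, 5L, 8L)) {
    feats <- matrix(rnorm(m * cfg$feature_dim), m)
    coords <- matrix(rnorm(m * 3L, sd = 2), m)
    fast <- schnet_interaction(feats, coords, cfg, params)
    slow <- brute_schnet_interaction(feats, coords, cfg, params)
    expect_equal(fast, slow, tolerance = 1e-6)
  }
  # literal (non-residual) variant
  cfg2 <- small_schnet_cfg(residual = FALSE)
  feats <- matrix(rnorm(4L * cfg2$feature_dim), 4L)
  coords <- matrix(rnorm(12L), 4L)
  expect_equal(schnet_interaction(feats, coords, cfg2, params),
               brute_schnet_interaction(feats, coords, cfg2, params),
               tolerance = 1e-6)
})

test_that("an isolated atom is updated from the zero aggregate", {
  cfg <- small_schnet_cfg(cutoff = 1)
  params <- withr::with_seed(7L, mvrxn:::conf_encoder_init(cfg)$blocks[[1L]])
  feats <- matrix(rnorm(2L * cfg$feature_dim), 2L)
  coords <- rbind(c(0, 0, 0), c(50, 0, 0))   # far beyond the cutoff
  out <- schnet_interaction(feats, coords, cfg, params)
  ssp <- function(x) log1p(exp(-abs(x))) + pmax(x, 0) - log(2)
  zero_update <- sweep(
    ssp(sweep(matrix(0, 1L, cfg$feature_dim) %*% params$out1$W, 2L,
              params$out1$b, `+`)) %*% params$out2$W, 2L, params$out2$b, `+`)
  expect_equal(out[1L, ], feats[1L, ] + as.numeric(zero_update),
               tolerance = 1e-10)
})

test_that("molecule embeddings are invariant to rigid motion and atom order", {
  cfg <- small_schnet_cfg()
  params <- withr::with_seed(9L, mvrxn:::conf_encoder_init(cfg))
  mols <- generate_synthetic_molecules(tiny_spec(seed = 3L), 6L, seed = 21L)
  withr::local_seed(10L)
  for (mol in mols) {
    h0 <- embed_molecule(mol, cfg, params)
    expect_true(all(is.finite(h0)))
    for (rep in 1:3) {
      m2 <- mol
      m2$coords <- rigid_transform(mol$coords)
      expect_equal(embed_molecule(m2, cfg, params), h0,
                   tolerance = 1e-6)
    }
    perm <- sample(length(mol$atoms))
    m3 <- mol
    m3$atoms <- mol$atoms[perm]
    m3$coords <- mol$coords[perm, , drop = FALSE]
    expect_equal(embed_molecule(m3, cfg, params), h0, tolerance = 1e-10)
  }
})

test_that("a single-atom molecule embeds as a function of its element only", {
  cfg <- small_schnet_cfg()
  params <- withr::with_seed(9L, mvrxn:::conf_encoder_init(cfg))
  m1 <- molecule("C", coords = matrix(c(0, 0, 0), 1L))
  m2 <- molecule("C", coords = matrix(c(7, -2, 3), 1L))
  expect_identical(embed_molecule(m1, cfg, params),
                   embed_molecule(m2, cfg, params))
})

test_that("unsupported elements are an error naming the element", {
  cfg <- small_schnet_cfg(atom_vocab = c(6L, 8L))
  params <- withr::with_seed(9L, mvrxn:::conf_encoder_init(cfg))
  m <- molecule("CCN", coords = matrix(rnorm(9), 3L))
  expect_error(embed_molecule(m, cfg, params), "unsupported element")
})

test_that("reaction conformer representations are finite, 2 x hidden, and invariant", {
  cfg <- small_schnet_cfg()
  params <- withr::with_seed(12L, mvrxn:::conf_encoder_init(cfg))
  d <- make_synthetic_dataset(tiny_spec(n = 5L, seed = 14L))
  rs <- d$records
  h <- encode_conformer_view(rs, cfg, params)
  expect_identical(dim(h), c(5L, 16L))
  expect_true(all(is.finite(h)))
  # rigidly transform every molecule of one reaction
  withr::local_seed(15L)
  r2 <- rs[[2L]]
  transform_role <- function(mols) lapply(mols, function(m) {
    m$coords <- rigid_transform(m$coords)
    m
  })
  r2$reactants <- transform_role(r2$reactants)
  r2$agents <- transform_role(r2$agents)
  r2$products <- transform_role(r2$products)
  h2 <- encode_conformer_view(list(r2), cfg, params)
  expect_equal(as.numeric(h2), h[2L, ], tolerance = 1e-6)
  # single-molecule degenerate sequence
  rone <- reaction(reactants = rs[[1L]]$reactants[1L],
                   products = rs[[1L]]$reactants[1L], record_id = "one")
  hone <- encode_conformer_view(list(rone), cfg, params)
  expect_true(all(is.finite(hone)))
  # missing coordinates name the record
  rbad <- rs[[3L]]
  rbad$reactants[[1L]]$coords <- NULL
  expect_error(encode_conformer_view(list(rbad), cfg, params),
               rbad$record_id)
})

test_that("embeddings vary smoothly under small coordinate perturbations", {
  cfg <- small_schnet_cfg()
  params <- withr::with_seed(9L, mvrxn:::conf_encoder_init(cfg))
  mol <- generate_synthetic_molecules(tiny_spec(seed = 3L), 1L, seed = 5L)[[1L]]
  h0 <- embed_molecule(mol, cfg, params)
  deltas <- c(1e-3, 1e-2)
  drift <- vapply(deltas, function(eps) {
    m2 <- mol
    m2$coords[1L, 1L] <- m2$coords[1L, 1L] + eps
    max(abs(embed_molecule(m2, cfg, params) - h0))
  }, numeric(1))
  # O(eps): an order of magnitude in eps buys about one in the drift
  expect_lt(drift[1L], drift[2L])
  expect_lt(drift[2L], 1)
})
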