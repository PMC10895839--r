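# Shared fixtures and independent reference implementations ("oracles")
# used across the test files.  Everything is generated in code; no data
# files.

# ---- naive loss references (double loops, no vectorization) ----------------

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

naive_jeffreys <- function(X_s, X_c) {
  n <- nrow(X_s)
  tot <- 0
  for (i in seq_len(n)) {
    p <- softmax_vec(X_s[i, ])
    q <- softmax_vec(X_c[i, ])
    kl_pq <- sum(p * (log(p) - log(q)))
    kl_qp <- sum(q * (log(q) - log(p)))
    tot <- tot + kl_pq + kl_qp
  }
  tot / (2 * n)
}

naive_infonce <- function(X_s, X_c, tau) {
  n <- nrow(X_s)
  f <- function(x, y) exp(sum(x * y) / tau)
  tot <- 0
  for (i in seq_len(n)) {
    den_s <- 0
    den_c <- 0
    for (k in seq_len(n)) {
      den_s <- den_s + f(X_s[i, ], X_c[k, ])
      den_c <- den_c + f(X_c[i, ], X_s[k, ])
    }
    tot <- tot + log(f(X_s[i, ], X_c[i, ]) / den_s) +
      log(f(X_c[i, ], X_s[i, ]) / den_c)
  }
  -tot / (2 * n)
}

# ---- brute-force SchNet interaction block ----------------------------------

ssp_ref <- function(x) log1p(exp(-abs(x))) + pmax(x, 0) - log(2)

dense_ref <- function(x, p) sweep(x %*% p$W, 2L, p$b, `+`)

brute_schnet_interaction <- function(features, coords, cfg, params) {
  m <- nrow(features)
  a <- dense_ref(features, params$atom_in)
  mu <- seq(0, cfg$cutoff, length.out = cfg$num_rbf)
  agg <- matrix(0, m, cfg$feature_dim)
  for (u in seq_len(m)) {
    for (v in seq_len(m)) {
      if (u == v) next
      dist_uv <- sqrt(sum((coords[u, ] - coords[v, ])^2))
      if (dist_uv > cfg$cutoff) next
      rbf <- exp(-cfg$rbf_gamma * (dist_uv - mu)^2)
      filt <- dense_ref(dense_ref(matrix(rbf, 1L), params$filt1) |>
                          ssp_ref(), params$filt2)
      agg[u, ] <- agg[u, ] + a[v, ] * as.numeric(filt)
    }
  }
  v_out <- dense_ref(ssp_ref(dense_ref(agg, params$out1)), params$out2)
  if (cfg$residual) features + v_out else v_out
}

# ---- random geometry helpers -----------------------------------------------

random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3L, 3L))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

rigid_transform <- function(coords) {
  R <- random_rotation()
  t_vec <- rnorm(3L, sd = 5)
  sweep(coords %*% R, 2L, t_vec, `+`)
}

# ---- synthetic SMILES pool for tokenizer properties ------------------------

BRACKET_POOL <- c("[NH4+]", "[O-]C(=O)C", "C[Si](C)(C)C", "[13CH4]",
                  "c1cc[se]c1", "[Na+].[O-]C(=O)C", "[H+]", "[cs]",
                  "O=[N+]([O-])c1ccccc1")

random_smiles_pool <- function(n, seed) {
  frags <- mvrxn:::DEFAULT_FRAGMENTS
  chain <- c("C", "CC", "CCC", "CCO", "CCN")
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      u <- runif(1)
      if (u < 0.55) {
        sample(frags, 1L)
      } else if (u < 0.75) {
        paste0(sample(chain, 1L), sample(chain, 1L))
      } else if (u < 0.9) {
        sample(BRACKET_POOL, 1L)
      } else {
        # high ring-closure indices exercise the %dd rule
        "C%12CCCCC%12"
      }
    }, character(1))
  })
}

# ---- tiny model fixtures ---------------------------------------------------

tiny_spec <- function(n = 30L, seed = 1L, sigma = 5) {
  synthetic_spec(n_reactions = n, sigma = sigma, seed = seed)
}

tiny_vocab_for <- function(d) {
  corpus <- lapply(d$records, function(r)
    unlist(lapply(mvrxn:::reaction_molecules(r),
                  function(m) tokenize_smiles(m$smiles))))
  build_vocabulary(corpus, min_frequency = 1L)
}

tiny_model_for <- function(vocab, seed = 2L, hidden = 8L) {
  seq_cfg <- seq_encoder_config(vocab_size(vocab), embedding_dim = 12L,
                                hidden_dim = hidden, num_layers = 2L,
                                dropout = 0.1)
  conf_cfg <- schnet_config(num_interactions = 2L, num_rbf = 16L,
                            feature_dim = 12L, hidden_dim = hidden,
                            num_layers = 2L, dropout = 0.1)
  build_model(vocab, seq_cfg, conf_cfg, align_dim = 8L,
              predictor_hidden = 16L, max_len = 256L, seed = seed)
}

# central finite-difference gradient of f at x (vectorized over entries)
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- 0 * x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
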