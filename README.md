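# mvrxn — multi-view representation learning for reaction yield prediction

Predicting the yield of an organic reaction — the percentage of product
obtained relative to the limiting reactant — guides route selection and
catalyst screening, but engineered descriptors generalize poorly to
reactions whose components (ligands, additives, halides) were never seen
in training.  `mvrxn` is an R package for chemists and machine-learning
researchers that learns reaction representations from two complementary
views and regresses yields from them:

* the **sequence view**: the reaction SMILES token stream, encoded by a
  token embedding and a multi-layer bidirectional GRU;
* the **conformer view**: each molecule's 3D coordinates, encoded by a
  SchNet-style continuous-filter convolution network (rotation-,
  translation- and permutation-invariant by construction) and aggregated
  over the molecule sequence by a second bidirectional GRU.

Training has two pre-training stages followed by fine-tuning.  In stage I
a shared projection head `g` maps both representations into an alignment
space, where two self-supervised losses act on batches of N reactions:

    x_s = g(h_s),  x_c = g(h_c)
    L_KL      = (1/2N) Σ_i [ KL(P_i ‖ Q_i) + KL(Q_i ‖ P_i) ],
                P_i = softmax(x_{s_i}),  Q_i = softmax(x_{c_i})
    L_InfoNCE = −(1/2N) Σ_i [ log softmax_k(x_{s_i}·x_{c_k}/τ)|_{k=i}
                            + log softmax_k(x_{c_i}·x_{s_k}/τ)|_{k=i} ]
    L_I       = L_KL + λ · L_InfoNCE

The Jeffreys-divergence term pulls the two views of the same reaction
together; the symmetric InfoNCE term pushes different reactions apart
(in-batch negatives).  With λ = 0 both positive- and negative-pair
divergences collapse toward zero — the diagnostic
`pair_divergence_distribution()` makes this visible.  In stage II a
predictor `p` is trained on the concatenation,
`y = p(h_s ⊕ h_c)`, with squared error on [0, 1]-normalized yields;
fine-tuning searches the grid lr ∈ {3e-4, 1e-3, 3e-3} × dropout ∈
{0.1, 0.3} × weight decay ∈ {0, 1e-4, 1e-5} × loss ∈ {MSE, MAE}.

Around the model the package provides the full data path: reaction-SMILES
parsing and Open Babel canonicalization, a curation pipeline (validity,
deduplication, conformer attachment, yield filtering), stratified 18:1:1
and component-held-out splits with zero leakage, a character-level SMILES
tokenizer with the `%dd`, `Cl`/`Br` and bracket-element rules, regression
and histogram distribution-shift metrics, and a seeded synthetic reaction
generator with planted yields so everything is testable offline.  The
neural components run on a small built-in reverse-mode differentiation
engine whose gradients are verified against finite differences.

## Worked example

Generate 300 synthetic reactions with planted yields (σ = 5 yield
points), pre-train stage I, train the yield head, and evaluate:

```r
library(mvrxn)

spec <- synthetic_spec(n_reactions = 300, sigma = 5, seed = 42)
d <- make_synthetic_dataset(spec)
d <- stratified_split(d, ratio = c(18, 1, 1), n_bins = 10, seed = 42)
d
#> <mvrxn_dataset> 300 reactions, 300 with yields | split: test=15 train=270 valid=15

corpus <- lapply(d$records, function(r)
  unlist(lapply(list(r$reactants, r$agents, r$products), function(ms)
    unlist(lapply(ms, function(m) tokenize_smiles(m$smiles))))))
vocab <- build_vocabulary(corpus, min_frequency = 1)

model <- build_model(
  vocab,
  seq_encoder_config(vocab_size(vocab), embedding_dim = 64, hidden_dim = 32,
                     num_layers = 2, dropout = 0.1),
  schnet_config(num_interactions = 2, num_rbf = 32, feature_dim = 32,
                hidden_dim = 32, num_layers = 2, dropout = 0.1),
  align_dim = 32, predictor_hidden = 64, seed = 1)
model
#> <mvrxn_model> 19 tokens | h_s/h_c dim 64 | align dim 32 | 18337 parameters

s1 <- train_stage1(d, model, stage1_config(epochs = 10, batch_size = 32,
                                           lr = 5e-3, seed = 1))
tail(s1$history, 3)
#>    epoch        L_KL L_InfoNCE      L_I valid_L_I
#> 8      8 0.004859530  2.123975 2.128834  1.673810
#> 9      9 0.005559540  2.004024 2.009583  1.452842
#> 10    10 0.005499382  1.768998 1.774497  1.539325

s2 <- train_yield_model(d, s1$model,
                        stage2_config(epochs = 6, batch_size = 32,
                                      lr = 3e-3, seed = 1))
test_ids <- names(d$split_labels)[d$split_labels == "test"]
pred <- predict_yield(d$records[test_ids], s2$model)
y <- sapply(d$records[test_ids], function(r) r$yield_pct)
str(regression_metrics(y, pred$y_pred))
#> List of 3
#>  $ mae : num 7.92
#>  $ rmse: num 10.1
#>  $ r2  : num 0.672

pair_divergence_distribution(d, s2$model, batch_size = 32, seed = 1)
#> <mvrxn_divergence_cdf> 300 positive / 9060 negative pairs | medians 0.01412 vs 0.02916
```

The stage-I loss `L_I` falls as the two views align; after supervised
training the model explains about two thirds of the held-out yield
variance on this small 300-reaction run (larger runs recover more — see
below), with MAE/RMSE in yield points.  The divergence medians show
positive pairs (same reaction, two views) sitting well below negative
pairs in the alignment space.

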