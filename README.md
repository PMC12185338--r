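# repalign

Sparse, non-negative, interpretable object embeddings from triplet
odd-one-out behaviour — and tools to compare two such embeddings dimension by
dimension to localize where representations align and where they diverge.

## The problem

In the triplet odd-one-out task an observer sees three objects *i*, *j*, *k*
and picks the least similar one; the unchosen pair is implicitly judged most
similar. Millions of such judgements constrain a low-dimensional similarity
space. The same task can be "played" by any model that assigns objects a
feature vector **z**: the most similar pair maximises the dot product
S<sub>ab</sub> = **z**<sub>a</sub>ᵀ**z**<sub>b</sub>, so a feature matrix can
be sampled from exactly like a participant. Learning one embedding from
human choices and one from model-simulated choices on the *same task* makes
the two directly comparable.

`repalign` implements the full framework:

* **Choice simulation** (`simulate_choices()`, `sample_triplets()`): argmax
  odd-one-out decisions from any rectified feature matrix, with tie logging.
* **Variational embedding** (`vice_train()`): a sparse non-negative embedding
  of the SPoSE/VICE family. Each weight has a Gaussian mean-field posterior
  q(w) = N(μ, σ²) under a spike-and-slab Gaussian-mixture prior; weights are
  sampled by reparameterisation, rectified, and scored by the softmax triplet
  likelihood
  p(pair a,b) = exp(**y**<sub>a</sub>ᵀ**y**<sub>b</sub>) / Σ<sub>pairs</sub> exp(·).
  Dimensions lacking posterior support (< 5 objects with Pr(w > 0) ≥ 0.95)
  are pruned on a fixed cadence; training stops once the dimensionality has
  been stable for 500 epochs (or at 1,000). The trainer is compiled C++
  (RcppArmadillo) and bit-reproducible by seed.
* **Reliability** (`split_half_reliability()`, `select_best_run()`):
  odd/even-mask split-half reproducibility across seeds, Fisher-z averaged,
  used to select the final embedding.
* **Feature mapping** (`fit_ridge()`, `predict_dimensions()`, `am_loss()`):
  cross-validated ℓ2-regularised regression from raw features to embedding
  dimensions, plus the activation-maximisation loss
  −α·ŷ<sub>j</sub> − β·log p(ŷ<sub>j</sub>) as a pure function.
* **RSA** (`rsm_from_embedding()`, `rsm_correlation()`,
  `match_dimensions()`, `cumulative_rsa()`, `explainable_variance()`):
  similarity matrices of context-averaged triplet choice probabilities,
  dimension matching with and without replacement, cumulative
  variance-explained curves, and noise-ceiling normalisation.
* **Relevance** (`dimension_relevance()`, `divergent_triplets()`): jackknife
  importance of each dimension for an individual choice, and ranking of the
  triplets on which two embeddings disagree most confidently.
* **Synthetic ground truth** (`generate_embedding()`, `simulate_dataset()`):
  planted sparse embeddings and argmax/softmax choice generators, so every
  claim can be validated by parameter recovery.

## Worked example

Plant a 4-dimensional sparse truth over 40 objects, simulate 20,000
odd-one-out choices, and recover the structure:

```r
library(repalign)
truth   <- generate_embedding(m = 40, k = 4, sparsity = 0.5, seed = 3)
choices <- simulate_dataset(ground_truth(truth, seed = 3), 20000,
                            mode = "argmax", seed = 4)
fit <- vice_train(choices, train_config(p_init = 12, seed = 10),
                  prior_spec(), m = 40)
fit
#> variational embedding: 40 objects x 4 active dimensions
#>   trained 550 epochs, final mean loss 0.5854

emb <- point_estimate(fit)
rep <- recovery_report(truth, emb)
head(rep$matches, 4)
#>   dim_a dim_b         r
#> 1     2     2 0.9772207
#> 2     4     3 0.9712720
#> 3     1     1 0.9619520
#> 4     3     4 0.9381227
```

Starting from 12 candidate dimensions, pruning settles on exactly the 4 that
were planted, and each recovered dimension correlates r ≈ 0.94–0.98 with its
planted counterpart (matched greedily without replacement). The embeddings
also agree at the level of similarity structure:

```r
rsm_correlation(rsm_from_embedding(emb), rsm_from_embedding(truth))
#> [1] 0.9207
```

i.e. the reconstructed choice-probability similarity matrix correlates
r ≈ 0.92 with the planted one. Per-triplet, the jackknife shows which
dimension carries a given decision:

```r
prof <- dimension_relevance(emb, c(1, 2, 3))
round(prof$base_probs, 3)
#> odd_3 odd_2 odd_1
#> 0.914 0.081 0.005
prof$top_dim
#> [1] 4
```

Here the model is 91% confident that object 3 is the odd one out, and
removing dimension 4 changes that probability most.

A thin CLI over the same functions lives at `inst/cli/repalign.R`
(subcommands `synth`, `sample-triplets`, `simulate`, `train`, `reliability`,
`map`, `compare`, `relevance`, `run`), and `run_pipeline()` orchestrates the
whole multi-seed study from one YAML config with content-hash stage caching.

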