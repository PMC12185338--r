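---
title: "Models and methods behind repalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind repalign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repalign)
```

## The behavioural model

The package is built around a single behavioural currency: the triplet
odd-one-out judgement. Three objects $\{i, j, k\}$ are shown; the pair judged
most similar is recorded (equivalently, the remaining object is the odd one
out). Similarity between objects is the dot product of non-negative object
vectors, and choice probabilities are the softmax over the three pair
similarities:

$$
p\big(\{a,b\}\mid\{i,j,k\}, Y\big) \;=\;
\frac{\exp(\mathbf{y}_a^\top \mathbf{y}_b)}
     {\exp(\mathbf{y}_i^\top \mathbf{y}_j)
      + \exp(\mathbf{y}_i^\top \mathbf{y}_k)
      + \exp(\mathbf{y}_j^\top \mathbf{y}_k)}.
$$

Deterministic (argmax) readout of the same quantity is how a feature matrix
— for instance the rectified penultimate-layer activations of an image
classifier — is treated "like a participant": `simulate_choices()` picks the
pair with the largest dot product. Similarity is deliberately the *raw* dot
product: no cosine normalisation or centering, so overall feature magnitude
carries meaning (an object with larger norm is more "choosable" across
contexts).

**Tie handling.** With continuous features exact ties have measure zero, but
sparse synthetic embeddings produce them often (two disjoint-support pairs
both have similarity 0). Ties are resolved deterministically — the
lexicographically smallest sorted index pair wins — and *counted*:
`odd_one_out()` returns a `tie` flag and `simulate_choices()` records
`attr(., "n_ties")`. At the default synthetic settings (60% sparsity) around
a tenth of argmax trials are tied, so the flag is worth inspecting; tied
trials carry no similarity information and cap the accuracy any model can
reach on them.

## The variational embedding

Each of $m$ objects gets a row of $p$ weights. Every weight has an
independent Gaussian variational posterior $q(w) = \mathcal{N}(\mu,
\sigma^2)$; the prior is a zero-centred spike-and-slab Gaussian mixture
$\pi\,\mathcal{N}(0, \sigma_{\text{spike}}^2) + (1-\pi)\,\mathcal{N}(0,
\sigma_{\text{slab}}^2)$, the Bayesian analogue of an elastic net: the
narrow spike shrinks weights to zero, the wide slab holds the survivors.
Weights enter the likelihood through a reparameterised sample $W = \mu +
\sigma \odot \varepsilon$ rectified to $\max(W, 0)$ — during optimisation
*and* at inference — so the representation is non-negative by construction.
The per-trial objective is the usual negative ELBO: a complexity term
$\tfrac{1}{n}(\log q(W) - \log p(W))$ at the sample plus the mean negative
log-probability of the observed pair choices (`elbo_loss()` evaluates
exactly this estimator).

Training (`vice_train()`) is minibatch stochastic gradient descent with Adam
on $(\mu, \log\sigma)$, implemented in compiled C++ with hand-derived
pathwise gradients (the direct and pathwise derivatives of $\log q$ with
respect to $\mu$ cancel; with respect to $\sigma$ they collapse to the
entropy gradient $-1/\sigma$). All randomness — initialisation, batch
shuffling, reparameterisation noise — flows through R's RNG, so a seed gives
bit-identical fits.

### Pruning and stopping

A dimension is worth keeping only if some objects clearly use it. The rule:
dimension $j$ survives iff at least `prune_min_objects` = 5 objects have
$\Pr(w_{ij} > 0) = \Phi(\mu_{ij}/\sigma_{ij}) \ge 0.95$ (i.e.
`1 - prune_threshold`). The rule is evaluated every 50 epochs
(`prune_interval`); a checkpoint that would remove *every* dimension is
skipped, since early in training no dimension has accumulated support yet.
Training stops when the dimensionality has been unchanged for
`stability_epochs` = 500 epochs, or at `max_epochs` = 1000. The stopping
rule is dimensionality-based only; the optional held-out fraction
(`val_fraction`, default 10%) is used purely for logging choice accuracy.

### Two design choices that make pruning work

Both of these were settled by parameter-recovery experiments (below), and
both are exposed in `train_config()`.

**Zero-mean initialisation** (`init_mu_sd` = 0.1). Rectification gates
negative weights out of the likelihood. If all means start positive, every
dimension immediately participates, every dimension accumulates confidently
positive weights, and nothing ever dies. Starting $\mu \sim \mathcal{N}(0,
0.1^2)$ lets dimensions that lose the early competition drift negative,
leave the likelihood, and be pruned.

**Complexity tempering** (`kl_weight` = 16). Under the strict per-trial
weighting, the prior's gradient on a single weight is of order
$10^{-5}$ at $n = 5\times 10^4$ trials, while the minibatch likelihood
gradient noise is three to four orders of magnitude larger. Adam normalises
each coordinate by its gradient RMS, so a systematic signal that small
produces essentially zero drift: in recovery experiments *no* setting of the
prior itself (spike widths down to 0.01, spike mass up to 0.9, slab down to
0.5) ever pruned a single redundant dimension. Deterministic argmax data
compounds the problem — sharper softmax margins always pay, so redundant
copies of useful dimensions are actively rewarded and only the prior opposes
them. `kl_weight` multiplies the complexity term, restoring the prior's
visibility. The default 16 comes from a calibration sweep on the planted
recovery study: substantially smaller weights leave redundant dimensions
alive, substantially larger ones collapse the embedding before signal can
grow, and a broad middle region recovers the planted dimensionality with
high matched correlations (the acceptance suite re-runs this check at the
default). Setting `kl_weight = 1` recovers the strict objective.

### Prior and optimiser defaults

| parameter | default | notes |
|---|---|---|
| $\pi$ (spike mass) | 0.5 | agnostic between zero and non-zero |
| $\sigma_{\text{spike}}$ | 0.25 | narrow but not degenerate |
| $\sigma_{\text{slab}}$ | 1.0 | weights live at order 1 |
| learning rate | $10^{-3}$ | Adam |
| batch size | 256 triplets | |
| `init_sigma` | 0.5 | posterior sd start |
| `p_init` | 150 | canonical large-scale setting; small studies use less |

The final representation (`point_estimate()`) is the rectified posterior
mean on the surviving dimensions, columns sorted by descending column sum so
"dimension 1" is always the heaviest; column names record the original
dimension identities.

## Reliability across runs

Variational fits depend on their seed, so the protocol trains several runs
and keeps the most reproducible one. `split_half_reliability()` partitions
objects by stored-order parity into an odd and an even mask. For each run
and each of its dimensions, the best-correlating dimension among the pooled
dimensions of all *other* runs is found on the odd mask; the matched pair is
then scored on the disjoint even mask. Because selection and scoring use
disjoint objects, unrelated runs score near zero instead of inheriting
selection bias. Per-run scores are Fisher-$z$ averaged and back-transformed;
$|r| \ge 1$ (exact duplicates) is clipped to $1 - 10^{-7}$ before `atanh`.
Matching is many-to-one by design — no uniqueness constraint — and
zero-variance dimensions on a mask are dropped with a warning rather than
silently scored.

## Mapping features to dimensions

`fit_ridge()` links a feature matrix to the learned embedding with
per-dimension ridge regression: the penalty is selected per dimension by
5-fold cross-validated $R^2$ over a logarithmic grid
($10^{-3}$–$10^{3}$), and solutions along the whole grid come from one SVD
of the centred design, so they are exact rather than path-approximated.
Predictions (`predict_dimensions()`) are affine and rectified by default to
preserve the embedding's non-negativity (raw values via
`rectified = FALSE`).

`am_loss()` evaluates the activation-maximisation objective
$-\alpha \hat y_j - \beta \log p(\hat y_j)$ for a predicted embedding
vector: the first term rewards the size of the target dimension, the second
its specificity. The specificity density is not pinned down by the framework;
the package uses the softmax of $\hat y$ across dimensions — the simplest
density that "concentrates probability mass towards a dimension" — and
accepts any function mapping $\hat y$ to a probability vector as a drop-in
alternative. The generative image-search loop that would consume this loss
(latent-code optimisation through a pretrained generator) is out of scope;
only the loss itself is provided.

## Representational similarity analyses

`rsm_from_embedding()` reconstructs an $m \times m$ similarity matrix as
context-averaged choice probabilities:

$$
S_{ij} = \frac{1}{m - 2}\sum_{k \notin \{i, j\}}
\frac{\exp(\mathbf{y}_i^\top \mathbf{y}_j)}
     {\exp(\mathbf{y}_i^\top \mathbf{y}_j)
      + \exp(\mathbf{y}_i^\top \mathbf{y}_k)
      + \exp(\mathbf{y}_j^\top \mathbf{y}_k)}.
$$

Exact enumeration is $O(m^3)$; beyond a few hundred objects a uniform
context subsample per pair (`context = n`) is the intended mode. All
evaluations shift logits by their maximum (log-sum-exp), so large dot
products cannot overflow. The diagonal is 1 by convention, and RSM
correlations use the strict upper triangle only.

When a "ground-truth" RSM is needed from a raw feature matrix, the same
kernel is applied to the rectified features themselves — the framework
defines exactly one similarity-to-probability rule, so it is used everywhere.

**Dimension matching.** `match_dimensions()` pairs dimensions of two
embeddings by maximal absolute Pearson correlation over objects — each
source dimension independently (with replacement) or greedily retiring both
members of the globally best remaining pair (without replacement). Greedy
matching maximises the sorted correlation sequence lexicographically, which
the tests confirm against exhaustive search on small instances. Correlations
are computed on raw dimension values; no rank transform or z-scoring.

**Cumulative RSA.** `cumulative_rsa()` rebuilds the RSM from growing
prefixes of a dimension ranking and correlates each with a reference.
"Dimensions needed for a fraction $f$ of the variance" is resolved
*relative to the full ranking's own $r^2$*, because the curve asymptotes to
the full-embedding correlation, not to 1; an absolute mode
(`relative = FALSE`) is available. `explainable_variance()` divides $r^2$ by
a user-supplied noise ceiling — the package does not estimate ceilings from
repeat data; values above 1 are flagged, not clamped.

## Jackknife relevance

`dimension_relevance()` measures what each dimension contributes to one
specific choice: compute the softmax probability of the predicted
most-similar pair under the full embedding, zero out one dimension at a
time, and record $\Delta_d = p_{\text{full}} - p_{\setminus d}$. The tracked
probability is that of the pair the *full* embedding predicts (equivalently,
its odd-one-out identification), which keeps the score single-valued.
Ranking uses $|\Delta_d|$ — a dimension matters whether its removal raises
or lowers the probability — while signed values are reported.
`divergent_triplets()` scores disagreement between two embeddings as zero
when they predict the same odd-one-out and otherwise the mean of their own
confidences, so confidently contradictory triplets rank first.

## The synthetic ground truth

`generate_embedding()` plants a sparse non-negative embedding: entries are
zero with probability `sparsity` and exponential (mean `scale`) otherwise.
The exponential's heavy right tail mimics the weight distributions sparse
similarity embeddings produce in practice — most objects load weakly on a
dimension, a few strongly; all-zero columns are resampled.
`generate_features()` embeds the truth in a feature space via a non-negative
loading (block-structured by default) plus Gaussian noise, then rectifies,
so feature-space dot products mirror planted similarity.
`simulate_dataset()` generates choices by argmax or by sampling from the
softmax at a temperature (implemented by scaling the embedding by
$1/\sqrt{T}$, which scales all dot products by $1/T$); temperature 1 is
exactly the likelihood the model optimises and $T \to 0$ recovers argmax.

What the generator does *not* emulate: category structure or semantic
organisation among objects, heteroscedastic or participant-specific decision
noise, and the sheer scale of real behavioural datasets. Passing recovery
tests therefore demonstrates that the estimator is consistent with its own
generative assumptions at desk scale — not that any particular real dataset
has six dimensions.

## Problem sizes and numerical choices

The test suite and the acceptance script run deliberately small studies,
chosen as the smallest sizes at which each claim is meaningfully testable:
recovery uses $m = 60$ objects, $k = 6$ planted dimensions at 60% sparsity,
50,000 argmax trials, `p_init = 20`, three training seeds; reliability nulls
use $m = 200$, $k = 10$; exact-RSM oracles use $m = 12$; cumulative RSA uses
$m = 40$. Headline figures from the full-scale protocol (tens of dimensions
from millions of trials over ~1,800 objects) require the original
behavioural datasets and hours of optimisation, and are intentionally not
asserted anywhere in this package.

Numerical conventions, collected: rectification is `max(x, 0)` exactly;
softmax evaluations are log-sum-exp shifted; Fisher $z$ clips $|r| \ge 1$ to
$1 - 10^{-7}$ with a warning; undefined correlations (zero variance on a
mask or a constant dimension) are dropped with warnings, never imputed; all
argmax ties break to the lowest index; `prune_dimensions()` on an
already-pruned state is the identity; triplet files on disk are 0-based
(`i j k odd`, tab-separated) while the R API is 1-based, with conversion
confined to the readers and writers.

## Known limitations

* The mean-field posterior ignores weight correlations; posterior standard
  deviations are underestimates near the rectification boundary.
* Deterministic argmax data makes the likelihood scale-hungry; the
  complexity tempering default was calibrated for that regime and may be
  conservative for very noisy (high-temperature) choice data.
* Greedy matching without replacement is not the optimal assignment in
  general (it is lexicographically, not sum-, optimal).
* The pipeline's stage cache keys on configuration and input hashes, not on
  package version; clear the run directory after upgrading.
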