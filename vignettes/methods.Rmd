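---
title: "Methods: disentangling known and unknown attributes of single-cell expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disentangling known and unknown attributes of single-cell expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`latentsplit` fits a conditional generative model of single-cell expression
whose latent space is decomposed by construction. For each cell `c` with
measured features `x_c` (length M) and known attributes `y_c`:

- each **categorical attribute** contributes a code `z_y` looked up in a
  learned embedding table — the code is shared by every cell carrying the
  same label, so the table row *is* the attribute state's representation;
- each **ordered attribute** (dose, a chemical or gene-ontology-derived
  perturbation embedding, any numeric vector whose geometry matters)
  contributes `z_y = f(features)` through a small MLP encoder, which is
  what lets the model generalize to attribute values never seen in
  training;
- the **unknown attributes** of each cell — batch, unannotated programs,
  anything the labels do not explain — are captured by a per-cell code
  `z_u` optimized *directly as a model parameter*.

The decoder `G_θ` consumes the concatenation of all codes and outputs a
parametrization of the expression distribution. The objective is

```
L  =  NLL(x | G_θ) + τ · MSE(x, μ_θ)   +   λ · ‖z_u‖²
      └────────── completeness ─────┘      └─ minimality ─┘
```

with Gaussian noise `η ~ N(0, σ² I)` added to `z_u` during training.

Two design commitments follow the latent-optimization argument: there is
**no encoder from `x` to `z_u`** (an amortized encoder starts training in a
fully entangled state that later optimization struggles to undo), and
`z_u` is **initialized at zero**, which literally encodes "no information"
at step 0. The noise and the activation penalty jointly limit how much
information `z_u` can carry, pushing attribute-correlated variation into
the attribute codes, which is exactly what makes counterfactuals
attributable.

### Output families

* `zinb` (default, raw counts): per-entry mean `μ = L_c · softmax(o)_f`,
  i.e. the observed library size times decoded feature proportions;
  per-feature inverse-dispersion `θ_f` (a free parameter on the log scale);
  per-entry zero-inflation logits from a decoder head. The NLL uses the
  exact mixture pmf `π·1[x=0] + (1-π)·NB(x; μ, θ)`.
* `poisson` (raw counts/peaks): the same library-size × softmax mean.
* `gaussian` (log-normalized values): affine mean head, per-feature
  variance.

The library size defaults to the observed per-cell total, a deterministic
observable; there is no latent library. Dispersion is per-feature and
shared across cells — the standard count-decoder convention, and with
per-entry dispersion the model would be badly underdetermined at the
problem sizes this package targets.

### Semi-supervised extension

When labels are partially missing, each affected attribute gets a
classifier (categorical) or regressor (ordered) from measured expression,
trained jointly through an added loss `L_cls` (cross-entropy / MSE on
labeled cells only, averaged per attribute over its labeled cells). For
unlabeled cells the attribute's latent code is completed from the
classifier output. Two completions are possible and the choice is genuinely
open; the package defaults to the **soft** probability-weighted mixture of
category embeddings because it keeps the objective differentiable end to
end and lets the generator's reconstruction error inform the classifier
through the mixture. Hard argmax completion is available
(`soft_completion = FALSE`); it blocks that gradient path. The classifier
consumes standardized `log1p` counts (or standardized values for the
gaussian family), never the latent codes, so imputation remains meaningful
on cells whose codes were never trained. `L_cls` enters the sum unweighted
by default (`cls_weight = 1`), with the weight exposed because the relative
scale against an M-feature NLL is a legitimate tuning axis.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `n_latent_attr` | 32 | latent dimension per known attribute; unspecified by theory, stable at desk scale |
| `n_latent_u` | 32 | unknown-code dimension; should exceed the expected rank of unannotated structure |
| `encoder_depth`, `encoder_width` | 2, 256 | ordered-attribute MLP shape |
| `decoder_depth`, `decoder_width` | 2, 128 | decoder trunk shape (tanh layers) |
| `sigma` | 1 | std. dev. of training noise on `z_u`. **This default is this package's choice of a fixed value** — the framework requires some fixed σ but no canonical value exists; 1 is of the same order as trained code norms, making the regularization active without drowning the signal |
| `lambda` | 0.1 | minimality weight, log-unit-free; larger values shrink `‖z_u‖` monotonically (verified in the test suite) |
| `tau` | 1 | weight of the auxiliary MSE on predicted means |
| `lr_net`, `lr_emb` | 1e-3, 5e-3 | Adam rates; directly-optimized embeddings converge too slowly at the network rate, hence the split |
| `epochs`, `batch_size` | 300, 256 | minibatched Adam over the joint objective |

## Numerical choices

- **MSE scale.** The auxiliary MSE term is computed on `log1p` values for
  count families (raw-count MSE would be dominated by a handful of highly
  expressed features) and raw values for the gaussian family, averaged over
  features. Whether the term should be a per-feature mean or sum is not
  fixed by the objective's definition; the mean was chosen so `tau` has the
  same meaning at any M.
- **Noise only in training.** `η` is a regularizer. All inference paths —
  reconstruction, counterfactuals, refitting — run with the stored code
  exactly, so identical inputs give bit-identical outputs and the empty
  manipulation reproduces the reconstruction exactly.
- **Initialization.** Embedding tables start as small-scale Gaussians
  (sd 0.1), network weights as `N(0, 1/fan_in)`, `z_u` at zero,
  zero-inflation bias at −2 (little initial zero inflation), `log θ` at
  `log 5`.
- **Determinism.** One seed controls initialization, shuffling and noise;
  training is single-threaded R, so runs are bit-reproducible on a given
  platform.
- **New cells.** Without an amortized encoder, unseen cells get a code by
  minimizing the frozen single-cell objective over `z_u` (L-BFGS with the
  analytic gradient, zero start plus one small seeded restart, keeping the
  better optimum). The tanh activations keep this objective smooth.
- **Non-finite losses** abort with the epoch in the message rather than
  propagating NaNs into the parameters.

### Downstream conventions

- **Counterfactual evaluation.** `r2_mean_profile` is the coefficient of
  determination between mean predicted and mean observed profiles over all
  features (the perturbation-benchmarking convention; a per-cell variant is
  available but not the default, since per-cell r² mostly measures
  reconstruction of cell-specific noise). `nmse` divides the prediction's
  error by the error of predicting no perturbation effect, so "no change"
  scores exactly 1 and smaller is better. The naive control baseline is
  always reported: any useful counterfactual must beat it.
- **Association test.** Each reference cell's observed expression is paired
  with its own counterfactual *mean* (not a sampled draw — deterministic
  and less noisy), a two-sided dependent t test runs per feature, and
  Benjamini–Hochberg adjustment is applied across all M features. Features
  with zero-variance differences get p = 1 and a `constant` flag rather
  than an undefined statistic.
- **k-NN uncertainty.** The score multiplies the Shannon entropy of the
  covariate among the k nearest neighbors by `Σ 1/log d(i,j)`. The entropy
  does not depend on the neighbor index, so it is implemented factored out
  of the sum. The metric, the log base and the behavior at `d ≤ 1` are not
  fixed by the formula itself; the package completes it minimally with
  Euclidean distance on per-dimension z-scored embeddings, natural logs,
  and a lower clamp of distances at `1 + 1e-6` (otherwise `1/log d`
  explodes or flips sign), all three exposed as options. The sum is not
  normalized by k. Self is excluded from the neighborhood; homogeneous
  neighborhoods score exactly 0.
- **Composite perturbations.** For multi-component ordered manipulations an
  additive mode predicts the combined shift as the sum of single-component
  shifts around the reconstruction; only means are defined in that mode.
- **Tie-breaks.** Imputation argmax ties resolve to the first category in
  schema order (deterministic) and are flagged.

## What the synthetic generator emulates — and what it does not

The generator plants per-attribute additive effects (0.5–1.0 log units by
default) on disjoint target feature blocks, low-rank Gaussian cell-specific
nuisance structure *independent of all attributes* (defaults: rank 4,
loading sd 0.2 — precisely the structure `z_u` should absorb), log-normal
library-size variation, overdispersion and structural zeros. Ordered
attributes act through a dose-response linear in log-mean, which makes
generalization to unseen doses testable. Log-means are converted to
proportions by a softmax and scaled by the library size, so sequencing
depth is purely technical, as in real data. Defaults: 2000 cells, 200
features, a 3-class and a 2-class categorical attribute plus a
1-dimensional dose on a {0, 0.25, 0.5, 1} grid, ZINB counts — sized to
train in minutes on one CPU core.

It does **not** emulate: correlated attributes (each label is drawn
independently), gene–gene correlation beyond the low-rank nuisance,
batch-specific dispersion, feature-level zero-inflation gradients, or the
gene-level statistics of any particular published dataset. Passing tests
therefore demonstrate that the machinery recovers what it assumes — additive
attribute effects separable from independent nuisance — not that any real
dataset satisfies those assumptions.

## Problem sizes used by the tests and the acceptance script

Unit tests run on a 300 × 40 study (80 epochs, widths 16/32). The
acceptance checks and `scripts/acceptance.R` run the full default
conditions (2000 × 200): 150 epochs for the held-out-combination recovery,
60 epochs per penalty-sweep point, 80 epochs for the semi-supervised fit,
with encoder/decoder widths 32/64 and 16-dimensional codes. These sizes are
the package's chosen desk-scale working points; all of them are ordinary
function arguments.

## Known limitations

- Correlated attributes make counterfactuals over unseen combinations
  unreliable — a limitation shared by all disentanglement approaches; the
  decomposed representation itself remains inspectable per attribute.
- Latent optimization ties `z_u` to the training set; new cells require an
  explicit refit (`fit_new_cell_embedding`), which is a per-cell
  optimization rather than a forward pass.
- The association test inherits the usual caveat that counterfactual means
  are model outputs: its p-values rank features and calibrate on null
  differences, but systematic generator bias would propagate into the
  pairs.
- Pure-R training is practical to a few thousand cells and a few hundred
  features per minute of CPU; it is not a substitute for GPU-scale training
  on atlas-sized data.
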