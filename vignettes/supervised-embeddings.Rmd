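---
title: "Supervised autoencoder embeddings for imbalanced clinical risk data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised autoencoder embeddings for imbalanced clinical risk data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskembed)
```

## The model and its assumptions

`riskembed` learns dimensionality reduction and classification *jointly*.
An encoder $C$ compresses a record $x \in [0,1]^d$ into an embedding
$h = C(x) \in \mathbb{R}^m$ with $m < d$; a decoder $D$ maps it back; a
softmax head $M$ classifies from $h$. One objective ties them together:

$$L \;=\; w_c\,L_c\big((M \circ C)(X), Y\big)
      \;+\; \lambda\, \frac{1}{|X|}\sum_i \big\|(D \circ C)(x_i) - t_i\big\|^2
      \;+\; \alpha\,\overline{|C(X)|}.$$

The reconstruction target $t_i$ is where supervision enters the geometry
of the embedding:

| mapping | target $t_i$ | classification weight $w_c$ | intent |
|---|---|---|---|
| `semi` | $x_i$ | 1 | reconstruction as a regularizer |
| `sym` | $x_i$ if $y_i$, $-x_i$ otherwise | 1 | classes in opposite half-spaces |
| `zero` | $y_i \cdot x_i$ | 1 | healthy records decode to the origin |
| `unsupervised` | $x_i$ | 0 | label-free denoising autoencoder |
| `baseline` | — (no decoder) | 1 | plain feed-forward classifier |

The `sym` and `zero` mappings assume a **non-negative feature space in
which 0 means "absence of the risk pattern"** and larger values mean more
risk — exactly what the preprocessing produces. The zero mapping
additionally reads the origin as the "no risk conduct" prototype, so the
majority (healthy) class is pulled toward a single point: a natural fit
for rare-positive problems, where class overlap rather than the imbalance
ratio itself is what hurts classifiers. Because `sym` targets are negative
for one class, the decoder's output layer is linear; identity and zero
targets live in $[0,1]$ and remain representable.

The networks use PReLU activations (one learned slope per hidden layer,
initialized at 0.25), a denoising corruption layer that zeroes **at most
one uniformly chosen feature per record** with probability
`corruption_rate` — emulating a patient skipping one question — and an
optional *bypass* that concatenates the corrupted input with the embedding
at the classifier head only (the decoder always consumes the embedding
alone). Reconstruction targets are always built from the *clean* record,
so the autoencoder is denoising in the usual sense.

## Tunable parameters

* `depth` (hidden layers per branch, grid 1–6) and `width` (units per
  hidden layer **and** embedding size $m$, grid {10, 20}). One width knob
  governs both, so the bottleneck is `width < d` whenever `bypass = FALSE`
  (enforced).
* `lambda` ($\lambda \ge 0$, grid {0.01, 0.1}): the reconstruction
  trade-off. The model-selection grid's single "regularization" knob is
  interpreted as $\lambda$, since it is the only weight in the stated
  objective; the L1 sparsity weight `l1_weight` is exposed separately
  (default $10^{-4}$) because sparse embeddings are a qualitative device
  (each unit should combine few risk factors), not a grid dimension.
* `corruption_rate` (default 0.5): the ≤1-feature cap is the defining
  contract; the rate itself is a free parameter, and 0.5 gives every
  record a coin-flip chance of losing one answer.
* Optimizer: RMSProp with step $10^{-3}$, decay 0.9, $\epsilon = 10^{-8}$
  (conventional defaults, exposed), batch size 32, at most 500 epochs,
  early stopping after 100 epochs without validation improvement
  ("iterations" is read as epochs; configurable). The monitor is the full
  joint loss on a stratified 10% holdout of the training records; the
  returned parameters are those of the best monitored epoch.
* Initialization is variance-scaled Gaussian from `seed`; with one thread
  (the default; R's BLAS here is single-threaded) training is bit-for-bit
  reproducible.

## Preprocessing

Questionnaire columns are typed by a `feature_schema`: answerable
questions (`bool_integer`, `bool_boolean`) expand into an answered-flag
feature plus the value — refusals are informative, so the flag stays even
after imputation; categoricals expand one-of-K in declared level order
(a refused categorical gets an all-zero block, its refusal carried by the
missing mask); integers and booleans pass through. Mean imputation then
[0,1] min–max scaling complete the pipeline. Both steps fit their
statistics on **training folds only** and are reapplied to held-out
records (with clipping into $[0,1]$); a constant training feature maps to
0 rather than erroring, because sparse cohort folds routinely produce
constant columns. Screening-outcome columns appended as observable inputs
are required to be complete — the public-data convention that outcome
columns are never imputed when used as features.

## Model selection and evaluation

Evaluation uses stratified k-fold CV (class counts per fold balanced to
within one). Hyper-parameters are chosen by nested grid search: inside
each outer-training set, every grid point is scored by mean PR-AUC over 3
stratified inner folds; the winner is retrained on the whole outer-training
set. Ties break toward the simplest model (smaller depth, then width, then
no bypass, then smaller $\lambda$). PR-AUC is **average precision with the
step convention** and exact tie grouping — linear interpolation of PR
curves is optimistically biased, and an exactly defined convention is what
makes the brute-force oracle equivalence in the test suite meaningful.
Fold metrics are aggregated by mean (primary) and also pooled, since
either convention is defensible; paired t-tests compare methods on their
index-aligned per-fold scores, with degenerate difference vectors resolved
by convention (all-zero: $p = 1$; constant non-zero: trivially
significant) instead of failing. The retrain seed of an outer fold depends
only on the global seed and the fold index, so a one-point grid reproduces
plain cross-validation bit-for-bit — a useful equality for auditing the
selection machinery.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical *shape* the method assumes:
right-skewed non-negative numeric answers on integer scales, yes/no
indicators, small categoricals with one risk-elevated level, refusals on
answerable questions (optionally label-dependent, since refusal can itself
be a risk behaviour), and a rare outcome from a logistic model on a sparse
set of active features with non-negative effects — so every signal feature
is positively associated with the outcome and 0 means absence of risk. The
intercept is calibrated by root-finding so the expected positive rate
equals the requested prevalence (default 0.1; unreachable configurations
error after a bounded search). Screening-test columns are simulated as
noisy tests of the outcome with sensitivities 0.65/0.75/0.85 and
false-positive rates around 0.05 for Cytology/Hinselmann/Schiller, giving
the observability scenarios the expected ordering. `make_separable_cohort()`
instead constructs classes separated by a stated geometric margin, for
tests that need a recoverable signal.

What the generator does **not** emulate: the marginal distributions of any
real questionnaire, correlated refusal across questions, measurement
drift, or label noise in the biopsy itself. Passing tests on synthetic
cohorts therefore demonstrate that the machinery is correct and that the
mappings shape the embedding as intended — not that any particular PR-AUC
will be attained on real clinical data.

## Numerical choices and degenerate inputs

Probabilities are clipped at $10^{-7}$ inside both cross-entropy losses.
PReLU and the L1 penalty are non-differentiable at 0; backpropagation uses
the $z \le 0$ branch and sign(0) = 0 respectively, which matters on a
measure-zero set. Analytic gradients agree with central finite differences
to a relative error below $10^{-4}$ for every mapping (verified in the
suite; observed agreement is near $10^{-7}$). Non-finite losses abort
training with the epoch reported. Single-class cohorts, empty perturbation
domains, foreign model-container versions and dimension mismatches all
raise early, named errors.

## Problem sizes

The suite and the acceptance script run on one CPU in a few minutes total.
The sizes were chosen as the smallest at which each property is
informative: separability recovery and zero-mapping geometry use
$n = 500$, $d = 20$ (3-fold CV, ≤150 epochs); selection and leakage audits
use $n \approx 200$–300 with reduced epochs, since they test machinery,
not asymptotics; gradient checks use networks with $d \le 8$, width
$\le 5$, depth $\le 2$, where finite differences are trustworthy; metric
oracles enumerate all label patterns at $n \le 8$.

## Design choices where the design was open

* **Unsupervised variant.** A `class_weight` factor on $L_c$ makes the
  label-free autoencoder a point in the same family ($w_c = 0$) rather
  than a separate code path, keeping the gradient check uniform. Its
  classifier head receives no gradient and is not meant for prediction.
* **Depth 0.** The constructor accepts `depth = 0` (encoder = embedding
  layer only); with slope 1 this is an exactly linear encoder, which is
  what gives the interpretation module a closed form to verify against
  ($\max$-impact of a binary feature = absolute weight-column magnitude
  times the domain range). Trained models use depth ≥ 1.
* **Impact aggregation.** "Maximum impact" is read as the max over records
  and alternative values per (feature, unit); the mean is emitted as a
  secondary summary since the reduction order is a genuine choice.
  Perturbations are applied to clean inputs. Numeric perturbation domains
  are capped at 25 quantile representatives.
* **Clustering and projection.** Feature clustering defaults to Euclidean
  distance with average linkage (neither is canonical; both exposed). The
  2-D projection of embeddings is by principal components or classical
  MDS, both deterministic.

## Known limitations

* The early-stopping monitor is small at rare-positive scales (10% of the
  training fold ≈ 50 records at $n = 500$, prevalence 0.1, i.e. ~5
  positives), so the chosen best epoch — and with it downstream geometric
  summaries such as the decoded-norm ratio — varies noticeably across
  seeds. Supplying an explicit `validation` cohort stabilizes this.
* Training is plain R matrix code: ideal for cohorts of hundreds to a few
  thousand records and tens of features, not for very wide data.
* Refusal imputation is mean-only by design; model-based imputation is out
  of scope.
* The interpretation module reports associations within the fitted model
  only; it makes no causal claims about risk factors.
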