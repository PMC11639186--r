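---
title: "Cross-modality imputation of missing omics samples: model and methods"
author: "CrossImpute maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality imputation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multi-omics cohorts are rarely complete. A tumour may have RNA-seq mRNA
expression but no miRNA profile because of cost, sample exhaustion, or
study design; the result is a *completely missing sample* in one modality
(the entire row absent), not element-wise missing values. Dropping those
samples discards statistical power in every downstream analysis that
needs both modalities. CrossImpute addresses this by learning a mapping
from the observed *source* modality ($X \in \mathbb{R}^{n \times p}$,
available for all $n$ samples) to the *target* modality
($Y \in \mathbb{R}^{m \times q}$, available for only $m \le n$ samples)
and imputing the $k = n - m$ missing target rows.

## The model

The imputer is a Wasserstein GAN. A fully connected generator $G$ with
two rectifier hidden layers (512 and 768 units by default) maps a source
profile to a target profile, $\hat{Y} = G(X)$; a rectified output layer
guarantees non-negative generated expression. A critic $C$ with hidden
layers of 256 and 128 units and a single linear output unit scores
profiles; it is trained to score measured profiles above generated ones,

$$L_C = \tfrac{1}{b}\textstyle\sum C(\hat{Y}) - \tfrac{1}{b}\sum C(Y),$$

with every critic parameter clipped to $[-0.01, 0.01]$ after each
optimizer step (the weight-clipping Lipschitz constraint of the original
Wasserstein formulation). The critic's output unit is linear, not
rectified: a rectified score cannot express negative values and collapses
the Wasserstein objective.

The generator minimizes a three-term objective,

$$L_G = -\tfrac{1}{b}\textstyle\sum C(G(X))
  \;+\; \alpha\, \lVert U - \hat{U}_\pi \rVert_2^2
  \;+\; \beta\, \mathrm{MSE}(Y_{\mathrm{obs}}, G(X)_{\mathrm{obs}}),$$

where the three terms are the adversarial score, the NMF
cluster-centroid consistency penalty, and the reconstruction error. The
reconstruction term is restricted to batch rows whose target profile is
observed; the adversarial and centroid terms use **every** row. This is
the point of the design: samples with no target-modality ground truth
still shape training through the distribution-level terms instead of
being held back for inference only.

### The centroid-consistency term

Non-negative matrix factorization writes $Y \approx VU$ with
$V \ge 0$ ($m \times c$ cluster memberships) and $U \ge 0$
($c \times q$ cluster centroids). If cluster structure is a stable
property of the target modality, centroids estimated from a generated
mini-batch should resemble centroids estimated from the measured data.
The reference $U$ is computed once, before training, from the
training-split target rows only (never the validation rows, to keep
validation honest). For each generated mini-batch the loss pipeline is:

1. decompose the batch with the package's multiplicative-update solver;
   the resulting memberships $\hat{V}$ are treated as constants;
2. refit $\hat{U} = \arg\min_{U \ge 0} \lVert \hat{Y} - \hat{V} U
   \rVert_F^2$ by per-column non-negative least squares (Lawson–Hanson);
3. align components: NMF rows carry no intrinsic order or scale, so each
   factorization is normalized (unit-maximum membership columns, scale
   absorbed into $U$) and the refit centroids are matched to the
   reference rows by an exact optimal assignment (Hungarian algorithm)
   before the squared Frobenius distance is taken.

Two choices here deserve explanation. First, differentiability: a
converged multiplicative-update factorization has no useful gradient
path, but the fixed-membership refit is a (piecewise) linear map from
the batch to $\hat{U}$, so the loss has an exact analytic gradient in
the generator output (treating the non-negativity active set as fixed at
the solution; the package's gradient is verified against finite
differences in the tests). Second, alignment: without normalization and
matching, the distance between two factorizations is dominated by
label-switching and scale noise rather than by genuine structural
disagreement. The reference centroids are themselves re-solved by the
same fixed-membership refit at the converged memberships, so the
pipeline applied to the reference data returns exactly zero.

One further detail makes the loss well behaved: the solver seeds only
the centroid initialization $U_0$ and derives the membership
initialization from the data as $V_0 \propto Y U_0^\top$. Every update
of $V$ is row-local and every update of $U$ aggregates rows
symmetrically, so the whole factorization — and therefore the loss — is
exactly invariant to permuting the rows of a batch.

## Training procedure

Mini-batches are drawn by a seeded shuffle from the union of
training-split and missing samples. Per batch, the critic takes 5
RMSprop updates on (real = observed target rows of the batch, fake =
generated counterparts of the *same* samples), each followed by weight
clipping; the generator then takes one RMSprop update on $L_G$. Pairing
real and fake scores on the same samples makes the critic a translation
critic rather than a marginal-distribution critic; generated rows of
missing samples never enter $L_C$ (they have no real counterpart) but do
enter the generator's adversarial term. The parameters of the epoch with
the lowest validation MSE are kept.

Two initialization details matter on non-negative expression data.
With a rectified output layer and symmetric Kaiming-style initial
weights, output units either start dead (zero for every input, hence
zero gradient, hence dead forever) or produce a large first-epoch
transient whose correction drives them dead. The trainer therefore warm
starts the output layer at the training-target column means with
down-scaled output weights, so training begins at the mean profile. This
is not an extra model assumption — it is the rectifier analogue of
centring the data.

### Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `alpha` | `1e-4` | weight of the centroid term. The term is a *sum* over $c \times q$ centroid entries and its gradient passes through an NNLS pseudo-inverse, so it is numerically much larger than the element-averaged MSE term; `1e-4` makes the two gradients commensurate. Selected by validation MSE over the grid {0, 1e-4, 1e-3, 1e-2}; larger values destabilize training, and smaller data fractions observed in the target argue for smaller `alpha` still. |
| `beta` | `1` | weight of the reconstruction term, the anchor that keeps generated profiles on the measured scale. MSE is averaged over elements so `beta` is batch-size independent. |
| `c` | `10` | NMF cluster count for the centroid term. |
| `epochs` | `50` | training length; the best-validation epoch is kept. |
| `batchSize` | `64` | must be at least `c` when the centroid term is active (a factorization needs at least `c` rows); trailing smaller batches are merged. |
| `criticSteps` | `5` | critic updates per generator update, the usual Wasserstein recipe. |
| `learningRate` | `5e-3` | RMSprop step for both networks. The classical Wasserstein value of 5e-5 is tuned for runs of $10^5$ steps; at desk scale (tens of epochs, a few hundred generator steps) it cannot move the parameters appreciably, so the default is scaled to the step budget. |
| `clipValue` | `0.01` | critic clip box half-width. |
| `mode` | `"full"` | `"nmf_only"` drops the reconstruction term (the ablation); `"mse_only"` drops the adversarial and centroid terms (the classical feed-forward MSE baseline). |

## The synthetic benchmark

`simulatePairedOmics()` generates the world the model assumes: $n = 400$
samples in $c_{\mathrm{true}} = 4$ equally likely latent clusters;
near-one-hot Dirichlet-jittered memberships $V_{\mathrm{true}}$;
non-negative uniform cluster centroids for both modalities (with a check
that centroid separation exceeds $4\times$ the noise level); source
$X = V_{\mathrm{true}} U_x + \varepsilon$ and target
$Y = \mathrm{map}(V_{\mathrm{true}} U_y) + \varepsilon$ with
truncated-at-zero Gaussian noise ($\sigma = 0.05$), where the map is the
identity or a fixed seeded softplus network with positive second-layer
weights (smooth, positive, non-linear); 25% of samples withheld from
the target as ground truth; binary labels splitting the clusters into
two halves; and exponential survival with rate
$0.01\,e^{\mathrm{risk}(z)}$, risk increasing linearly across clusters,
with 20% independent censoring. Noise is truncated rather than
log-normal so the non-negativity invariant is simple and exact.

What the simulator does **not** emulate: the marginal distributions of
real sequencing data (library-size effects, zero inflation,
heavy-tailed counts), batch effects, feature-feature correlation beyond
the cluster structure, and realistic feature dimensions (real panels
have $10^3$–$10^4$ features; the benchmark uses 60/40 so a full
training run takes well under a minute on one CPU). Passing the
benchmark therefore shows that the machinery is correct and that the
method works *when its structural assumptions hold*; it does not certify
performance on any particular cohort.

## Numerical choices and degenerate inputs

* NMF: Frobenius-objective multiplicative updates, $10^{-12}$ guards in
  the denominators, relative-objective tolerance $10^{-4}$, iteration cap
  1000 (500 within training batches); the objective is non-increasing at
  every iteration and this is asserted in the tests. All-zero sample rows
  stay exactly zero.
* NNLS refit: all-zero membership columns produce zero centroid rows
  with a warning; rank-deficient passive sets fall back to a
  ridge-stabilized inner solve.
* Split sizes use half-up rounding; sampling ties are broken by the
  seeded permutation order.
* Median risk split: ties at the median go to the low-risk group by
  stable sample order; all-equal scores split by stable order with a
  warning. Log-rank tables with zero variance (no discriminating
  information) return $p = 1$.
* Elastic-net Cox: penalty selected by 3-fold cross-validated partial
  likelihood when not supplied; constant features are excluded from the
  path and given zero coefficients; single-covariate inputs use an
  unpenalized (or ridge) `coxph` fit because a coordinate-descent path
  needs at least two covariates.
* All randomness flows from one seed through named sub-streams, and no
  package function disturbs the caller's RNG state.

## Scope and limitations

* Only whole-sample missingness is handled; element-wise NA imputation
  is out of scope.
* Sample matching is exact string equality of identifiers — no barcode
  truncation heuristics.
* One source modality maps to one target modality; multi-source fusion
  would need a different generator.
* Binary phenotypes only in the evaluation harness.
* The adversarial game is trained at desk scale. The test suite runs the
  benchmark at $n = 400$, $p = 60$, $q = 40$ with three seeds for the
  training-dependent properties (majority criteria), which keeps the
  whole suite in the minutes range; these sizes are a deliberate
  design point of the benchmark, chosen so the full pipeline is cheap to
  rerun while the cluster structure remains clearly recoverable.
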