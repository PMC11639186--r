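# CrossImpute

Adversarial cross-modality imputation of completely missing omics
samples, with an NMF cluster-centroid consistency loss that lets
samples lacking target-modality ground truth participate in training.

## The problem

Multi-omics cohorts are usually incomplete: some samples have, say,
mRNA expression but no miRNA profile at all. Given a source modality
`X (n x p)` observed for all samples and a target modality `Y (m x q)`
observed for a subset, CrossImpute trains a generator `G` so that
`Y_hat = G(X)` fills in the `k = n - m` missing target rows, and ships
the evaluation harness to judge whether the imputations are useful
downstream (phenotype classification, survival stratification).

The imputer is a weight-clipped Wasserstein GAN. The critic `C` is
trained on `L_C = mean C(Y_hat) - mean C(Y)`; the generator minimizes

```
L_G = -mean C(G(X)) + alpha * || U - U_hat ||_2^2 + beta * MSE(Y_obs, G(X)_obs)
```

where `U` and `U_hat` are NMF cluster-centroid matrices (`Y ~ V U`,
`V, U >= 0`) of the measured and generated data, aligned by optimal
assignment and refit by fixed-membership non-negative least squares so
the term is differentiable. The adversarial and centroid terms use every
sample — including those with no measured target row — while the MSE
term uses only observed rows. Baselines (k-nearest-neighbour,
per-feature regression, column means), ablation modes (`nmf_only`,
`mse_only`), and a synthetic paired-omics simulator with known ground
truth are included. See `vignettes/cross-modality-imputation.Rmd` for
the full model description.

## Worked example

```r
library(CrossImpute)

sim  <- simulatePairedOmics(syntheticSpec(seed = 1))   # 400 samples, 25% missing
ds   <- sim$dataset
plan <- makeSplit(ds, trainFraction = 0.8, seed = 1)

imp <- trainImputer(ds, plan, trainingConfig(seed = 1))  # ~25 s on one CPU
cm  <- imputeMissing(imp, ds)
cm
#> CompletedMatrix: 400 x 40 (300 observed, 100 imputed)

groundTruthMSE(cm, sim$truth)                        # withheld-row MSE
#> [1] 0.003952930
groundTruthMSE(baselineMeanImpute(ds), sim$truth)    # column-mean baseline
#> [1] 0.1107334

testSetAUC(cm, sim$truth$labels, plan, seed = 1)     # classifier trained on
#> [1] 1                                             # observed, tested on imputed

survivalEvaluation(cm, sim$truth$survival, seed = 1)$p   # log-rank p, risk groups
#> [1] 8.109484e-05                                      # from imputed profiles
```

The imputed rows sit ~28x below the column-mean baseline error (the
irreducible noise floor of this benchmark is `sigma^2 = 0.0025`), a
classifier that never saw the missing samples separates their phenotypes
perfectly, and the prognostic index fitted on the completed matrix
stratifies survival. Training with `mode = "nmf_only"` (no MSE anchor)
reproduces the expected ablation: reconstruction error blows up by two
orders of magnitude even though cluster structure is preserved.

A thin command-line front end over the same functions is in
`inst/scripts/crossimpute.R` (`simulate`, `prepare`, `train`, `impute`,
`evaluate` subcommands).

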