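# Shared benchmark runs, trained once per test session and cached so the
# training-property and acceptance tests do not repeat half-minute fits.

.bench_cache <- new.env(parent = emptyenv())

bench_run <- function(seed, mode = "full") {
  key <- paste0(mode, "_", seed)
  hit <- .bench_cache[[key]]
  if (!is.null(hit)) return(hit)
  sim <- simulatePairedOmics(syntheticSpec(seed = seed))
  ds <- sim$dataset
  plan <- makeSplit(ds, 0.8, seed = seed)
  imp <- trainImputer(ds, plan, trainingConfig(seed = seed, mode = mode))
  cm <- imputeMissing(imp, ds)
  out <- list(sim = sim, ds = ds, plan = plan, imp = imp, cm = cm,
              mse = groundTruthMSE(cm, sim$truth),
              mean_mse = groundTruthMSE(baselineMeanImpute(ds), sim$truth))
  .bench_cache[[key]] <- out
  out
}

# Tiny paired dataset for fast structural tests.
tiny_paired <- function(n = 12L, p = 4L, q = 3L, k = 3L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n))
  X <- matrix(runif(n * p, 0, 2), n, p,
              dimnames = list(ids, paste0("x", seq_len(p))))
  Y <- matrix(runif(n * q, 0, 2), n, q,
              dimnames = list(ids, paste0("y", seq_len(q))))
  alignSamples(omicsMatrix(X), omicsMatrix(Y[seq_len(n - k), , drop = FALSE]))
}
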