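# shared desk-scale experiment for the synthetic-benchmark tests:
# one 300-protein corpus (3 terms, label noise 0.05, 8:1:1 split) and, per
# training seed, a hierarchical-attention model and a max-pool ablation.
# Everything is trained lazily and cached so several tests can reuse it.

.expCache <- new.env(parent = emptyenv())

experimentCorpus <- function() {
  if (is.null(.expCache$ds))
    .expCache$ds <- generateDataset(syntheticSpec(
      nProteins = 300, lengthRange = c(40, 60), labelNoise = 0.05,
      motifProb = 0.5, seed = 20260921))
  .expCache$ds
}

# desk-scale training settings (tiny model D=32 K=4 H=2 N=4; see the
# methods vignette for the rationale behind the rate and epoch budget)
experimentTrain <- function(seed, pooling = "hgt") {
  key <- paste0(pooling, seed)
  if (!is.null(.expCache[[key]])) return(.expCache[[key]])
  ds <- experimentCorpus()
  tr <- ds$split == "train"; va <- ds$split == "valid"
  mdl <- funPredModel(21, ncol(ds$labels), hiddenDim = 32, nGcnLayers = 4,
                      nSuperNodes = 4, nHeads = 2, pooling = pooling,
                      termNames = colnames(ds$labels), seed = seed,
                      quiet = TRUE)
  fit <- trainModel(mdl, ds$graphs[tr], ds$labels[tr, ],
                    ds$graphs[va], ds$labels[va, ],
                    trainConfig(learningRate = 5e-3, batchSize = 64,
                                maxEpochs = 60, patience = 10,
                                seed = seed, contrastive = TRUE))
  te <- ds$split == "test"
  scores <- predictDataset(fit$model, ds$graphs[te])
  fmax <- suppressWarnings(computeFmax(ds$labels[te, ], scores))$fmax
  .expCache[[key]] <- list(model = fit$model, scores = scores, fmax = fmax)
  .expCache[[key]]
}

experimentSeeds <- 1:5
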