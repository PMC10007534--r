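# Shared fixtures. Heavy training runs are computed once per session and
# cached so several tests can assert on the same run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

tinyGraph <- function() {
  buildBodyGraph(strokegcn:::MarkerSet(c("a", "b", "c"), rep("seg", 3)),
                 rbind(c("a", "b"), c("b", "c")))
}

tinyModel <- function(seed = 3, ...) {
  g <- tinyGraph()
  set.seed(seed)
  initModel(g, modelConfig(F = 2L, Z = 2L, rnnWidth = 2L, attWidth = 2L,
                           headHidden = 2L, ...))
}

bodyGraph <- function() cached("bodyGraph",
  buildBodyGraph(loadMarkerSet("plug_in_gait_39")))

fullGraph <- function() cached("fullGraph", attachRacket(bodyGraph()))

# small model + training settings used by every training-based test
smallModelConfig <- function(...) {
  modelConfig(F = 8L, Z = 4L, rnnWidth = 16L, attWidth = 8L,
              headHidden = 8L, ...)
}

smallTrainConfig <- function(batchSize = 8L, ...) {
  trainConfig(lr = 1e-2, batchSize = batchSize, model = smallModelConfig(), ...)
}

# noise-free, jitter-free corpus: the linearly separable learnability case
learnabilityFit <- function() cached("learnability", {
  cfg <- synthConfig(counts = rep(12L, 4), noiseSd = 0,
                     durationRange = c(24L, 40L), amplitudeJitterSd = 0)
  ds <- generateDataset(cfg)
  sp <- stratifiedSplit(ds, splitSpec(seed = 7))
  hyper <- smallTrainConfig(epochs = 200L, patience = 25L, seed = 7L)
  fit <- trainModel(sp$train, sp$val, fullGraph(), hyper)
  list(fit = fit, split = sp)
})

# the with/without-racket ablation at moderate noise, 5 runs per condition
ablationResult <- function(mode) cached(paste0("ablation_", mode), {
  cfg <- synthConfig(counts = rep(12L, 4), noiseSd = 10,
                     durationRange = c(20L, 32L), racketInformative = mode,
                     seed = 99L)
  ds <- generateDataset(cfg)
  hyper <- smallTrainConfig(batchSize = 4L, epochs = 70L, patience = 70L)
  suppressWarnings(suppressMessages(
    runPipeline(outDir = NULL, dataset = ds, hyper = hyper, k = 5L,
                seed = 11L)))
})

randomTrialArray <- function(nf, M) array(rnorm(nf * M * 3), dim = c(nf, M, 3))
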