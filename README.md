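# strokegcn

Classify four basic tennis strokes — forehand, backhand, volley forehand,
volley backhand — from optical motion-capture marker trajectories, and
measure whether adding the tennis racket's markers to the player's
silhouette improves classification.

A trial is a tensor of frames × markers × 3 coordinates (mm, 100 Hz): the
39-marker Plug-in Gait body model, optionally extended by a 7-marker rigid
racket (46 markers in total). Markers form a graph G = (V, E); the
classifier is an attention temporal graph convolutional network:

1. per frame, a three-layer spatial graph convolution over the normalized
   adjacency `Âhat = T̃^(−1/2) (O + I) T̃^(−1/2)`:
   `f(X) = σ(Â ReLU(Â (Â X Ψ₀) Ψ₁) Ψ₂)`;
2. the flattened per-frame node embeddings are encoded by a bidirectional
   gated recurrent network (`uₜ = σ(W_u[xₜ, hₜ₋₁])`,
   `rₜ = σ(W_r[xₜ, hₜ₋₁])`, `mₜ = tanh(W_c[xₜ, rₜ⊙hₜ₋₁])`,
   `hₜ = uₜ⊙hₜ₋₁ + (1−uₜ)⊙mₜ`);
3. soft attention pools the hidden states into a context vector
   `C_v = Σᵢ αᵢ uᵢ` with `α = softmax(e)`,
   `eᵢ = ψ⁽²⁾(ψ⁽¹⁾uᵢ + b⁽¹⁾) + b⁽²⁾`;
4. a two-layer perceptron head emits four class probabilities, trained
   with sparse categorical cross-entropy `L = −log p_y`.

Training uses exact hand-derived analytic gradients (verified against
finite differences in the test suite) with Adam — no deep-learning
framework is required. The experiment harness provides stratified
60/20/20 splits, repeated independent runs with mean/max/min/SD
summaries, per-class precision/recall/F1, confusion matrices,
leave-one-out cross-validation (entry-wise RMSE), and a Welch t-test
comparing the with-racket (46-node) and without-racket (39-node)
conditions. A synthetic stroke generator with controllable class-signal
placement (`body_only` / `racket_only` / `both`) makes the whole pipeline
testable without any recorded data; C3D files can be read and written for
interoperability with capture software.

## Worked example

```r
library(strokegcn)

# a small synthetic corpus: 12 trials per class, racket follows the stroke
cfg <- synthConfig(counts = rep(12L, 4), noiseSd = 10,
                   durationRange = c(20L, 32L), seed = 99L)
ds  <- generateDataset(cfg)
ds
#> TrialSet: 48 trials x 46 markers, nf = 32
#>    forehand: 12, backhand: 12, volley_forehand: 12, volley_backhand: 12

body <- buildBodyGraph(loadMarkerSet("plug_in_gait_39"))
full <- attachRacket(body)      # 46 nodes: rigid K7 racket + grip edges

sp  <- stratifiedSplit(ds, splitSpec(seed = 7))
fit <- trainModel(sp$train, sp$val, full,
                  trainConfig(lr = 1e-2, batchSize = 4L, epochs = 60L,
                              patience = 60L, seed = 7L,
                              model = modelConfig(F = 8, Z = 4,
                                                  rnnWidth = 16,
                                                  attWidth = 8,
                                                  headHidden = 8)))
tail(fit$curves, 1)
#>    epoch  trainLoss    valLoss valAcc
#> 60    60 0.09117472 0.08604244      1

ev <- evaluateModel(fit, sp$test, full)
ev$accuracy
#> [1] 1
classMetrics(ev$confusion)$perClass[, c("class", "precision", "recall", "f1")]
#>             class precision recall f1
#> 1        forehand         1      1  1
#> 2        backhand         1      1  1
#> 3 volley_forehand         1      1  1
#> 4 volley_backhand         1      1  1
```

On this noise level the with-racket model separates the test set
perfectly; the interesting science is in the comparison. The one-call
pipeline runs both conditions and compares them:

```r
hyper <- trainConfig(lr = 1e-2, batchSize = 4L, epochs = 70L,
                     patience = 70L,
                     model = modelConfig(F = 8, Z = 4, rnnWidth = 16,
                                         attWidth = 8, headHidden = 8))
out <- runPipeline(outDir = "report", synth = cfg, hyper = hyper,
                   k = 5, seed = 11)
out$comparison   # Welch t-test on per-run accuracies, without - with
```

The drive/volley pairs share their swing shape and differ mainly in
amplitude — which per-trial amplitude jitter blurs — while the racket
orientation profiles differ strongly per class. Stripping the racket
(39-node condition) therefore costs accuracy, and `runPipeline` quantifies
how much.

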