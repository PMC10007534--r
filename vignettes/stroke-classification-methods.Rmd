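---
title: "Classifying tennis strokes from marker trajectories: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tennis strokes from marker trajectories: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Optical motion capture records a tennis player as a cloud of labelled
markers: 39 body markers placed according to the Plug-in Gait model, plus
(optionally) 7 markers on the racket, sampled at 100 Hz. Each trial is one
stroke belonging to one of four classes — forehand, backhand, volley
forehand, volley backhand — and the scientific question the package serves
is whether including the racket markers in the input improves
classification over the player's silhouette alone.

`strokegcn` implements the full chain: marker-graph construction, C3D
ingestion, the attention temporal graph convolutional classifier, and an
experiment harness (repeated stratified runs, per-class metrics, LOOCV,
and the with/without-racket comparison), together with a synthetic stroke
generator so the entire pipeline is testable without any recorded data.

# The model

A trial is a tensor of frames × markers × 3 coordinates. Markers form a
graph $G = (V, E)$ with $M = 39$ (body) or $M = 46$ (body + racket) nodes.

**Spatial stage.** Per frame, node coordinates pass through a three-layer
graph convolution over the symmetrically normalized adjacency
$\hat{O} = \tilde{T}^{-1/2}\,\tilde{O}\,\tilde{T}^{-1/2}$, where
$\tilde{O} = O + I$ adds self-connections and $\tilde{T}$ is the degree
diagonal of $\tilde{O}$:

$$ f(X) \;=\; \sigma\!\big(\hat{O}\,\mathrm{ReLU}\big(\hat{O}\,(\hat{O} X
\Psi_0)\,\Psi_1\big)\,\Psi_2\big). $$

In the published A3T-GCN formulation the two inner weight matrices are
both given the shape $F \times Z$, which does not compose; the package
uses $\Psi_0 \in \mathbb{R}^{3 \times F}$, $\Psi_1 \in \mathbb{R}^{F
\times F}$ and $\Psi_2 \in \mathbb{R}^{F \times Z}$, keeping the published
shape for $\Psi_2$. The output per frame is an $M \times Z$ embedding,
flattened to a frame vector (flattening rather than mean-pooling preserves
*which* node moved — essential for exploiting the racket channels;
mean-pooling is available via `modelConfig(meanPool = TRUE)`).

**Temporal stage.** Frame vectors are encoded by a bidirectional gated
recurrent network. Each direction applies, per frame,

$$ u_t = \sigma(W_u [x_t, h_{t-1}]), \quad
   r_t = \sigma(W_r [x_t, h_{t-1}]), $$
$$ m_t = \tanh(W_c [x_t, r_t \odot h_{t-1}]), \quad
   h_t = u_t \odot h_{t-1} + (1 - u_t) \odot m_t. $$

Note the gate convention: the update gate multiplies the *previous* state
and its complement the candidate memory. The common GRU convention swaps
the two; the package follows the published A3T-GCN convention (the two
parameterizations are equally expressive, but
checkpoints are not interchangeable). The two directions have independent
parameters and their states are concatenated, $u_t = [h^{\rightarrow}_t;
h^{\leftarrow}_t]$.

**Attention stage.** Each hidden state receives a scalar energy through
two affine layers, $e_t = \psi^{(2)}(\psi^{(1)} u_t + b^{(1)}) + b^{(2)}$
(the formulation places no nonlinearity between the two layers, so the
composition is affine), a softmax over time turns energies into weights
$\alpha_t$, and the context vector is the convex combination $C_v =
\sum_t \alpha_t u_t$. The softmax is computed with max-subtraction, which
is mathematically a no-op but overflow-safe.

**Head.** A two-layer perceptron maps $C_v$ to four class scores followed
by a terminal softmax, trained with sparse categorical cross-entropy
$L = -\log p_{y}$ (probabilities clamped at $10^{-12}$).

## Why the head deviates from the published wiring

The published head has *one* unit in its first layer with softmax
activation — but the softmax of a single unit is identically 1, so that
layer passes no information (this degenerate wiring is available as
`modelConfig(faithfulHead = TRUE)` for completeness). The natural
generalization — a wider hidden layer, still softmax-activated — turned
out to be untrainable in practice, for a reason worth recording: the
hidden activations live on the probability simplex, so the output logits
are confined to the convex hull of the second layer's columns, and
separating classes whose context vectors differ modestly requires very
large first-layer weights. Adam's per-parameter step caps weight growth
at roughly the learning rate per update, so convergence takes thousands
of updates at a stable learning rate — and at aggressive learning rates
the hidden softmax saturates to a vertex, its Jacobian vanishes, and all
gradient flow through the head (and hence to every upstream stage) dies.
Both failure modes were observed empirically on linearly separable
synthetic data. The default hidden activation is therefore `tanh`
(`modelConfig(headActivation = "softmax")` restores the softmax reading).

# Training

All gradients are computed by an exact analytic backward pass mirroring
the forward stages (verified in the test suite against central finite
differences to ~1e-11 relative on a small instance; the acceptance
criterion is 1e-4). Optimization details are not part of the published formulation, so
the package chooses: Adam (learning rate $10^{-3}$ by default; the
experiment harness uses $10^{-2}$ with the small architectures it
trains), minibatches of 16, up to 200 epochs with early stopping on
validation loss (patience 20), a global gradient-norm clip of 5 as a
divergence guard, and Glorot-uniform initialization. All randomness flows
from a single seed; two runs with the same configuration are
bit-identical.

Inputs are translated so the first frame's mid-pelvis (mean of LASI,
RASI, LPSI, RPSI) is at the origin and rescaled from millimetres to
metres — raw mm-scale inputs saturate the sigmoid stages. Left-handed
trials are mirrored into the right-handed convention before modelling
(about 1 player in 10 is left-handed; without this the minority hand acts
as label noise). Both steps are configurable in `trainConfig()`.

Trials are zero-padded at the end (after the movement) to the
corpus-wide maximum frame count `nf`; padded frames pass through the
network like any other (an all-zero frame maps to a constant embedding of
0.5), and attention learns to down-weight them. No masking is used.

# The marker graph

The published formulation defines the graph abstractly as G = (V, E);
no concrete adjacency accompanies it. The package ships an editable anatomical edge
table (`inst/extdata/plug_in_gait_edges.txt`) chaining markers along body
segments and joining segments at shared landmarks. The racket's 7 markers
form a complete subgraph — the racket is a rigid body, so every racket
marker's position constrains every other — and the handle-bottom marker
connects to the dominant hand's wrist and finger markers (`RWRA`,
`RWRB`, `RFIN`, flipped for a left-handed grip). All three choices are
the package's own constructions and can be overridden by user edge files.

# The synthetic generator

With no public corpus to download, the generator emulates the statistical
structure the classifier assumes, at the conditions of the study design
the package targets:
per-class counts 197/212/180/180 (forehand/backhand/volley
forehand/volley backhand), 100 Hz, trial durations uniform on 60–180
frames (forcing nontrivial padding), additive i.i.d. Gaussian marker
noise of 2 mm (typical optical-capture jitter), and a 10-subject pool
with one left-hander.

Each class is a deterministic template: a standing pose, a dominant-arm
displacement profile (drives sweep across the body, backhands mirror
forehands, volleys are the same shape scaled to 0.85 with a small lift —
deliberately similar, as the real strokes are), and a racket moved by a
single per-frame rigid transform whose orientation profile differs
strongly per class (drives roll through ~120°, volleys hold an open
face). Per-trial amplitude jitter (multiplicative, sd 0.12) overlaps the
drive/volley amplitude difference, so the body alone cannot separate a
drive from its volley reliably — while the racket orientation always
can. The `racketInformative` switch relocates the class signal: under
`"body_only"` the racket's rigid transform is drawn *independently* of
the class, making racket channels uninformative by construction; under
`"racket_only"` the body swing is drawn independently instead. This
turns the package's central ablation — does adding the racket help? —
into a controllable ground truth.

What the generator does **not** emulate: biomechanically valid joint
kinematics, soft-tissue artefact, marker occlusion and mislabelling,
inter-subject anthropometry, or ball contact. Passing tests on synthetic
data therefore demonstrate that the *method* behaves as designed
(learnability, the ablation ordering, metric arithmetic), not that any
particular accuracy level transfers to recorded data.

# Evaluation conventions

* **Splits**: stratified 60/20/20; per class, `floor` of the fraction for
  train and validation, remainder to test (the rounding rule is the
  package's choice).
* **Repeated runs**: 20 by default, each with its own split and training
  seed; summaries report mean/max/min/SD. Per-class "accuracy" is
  one-vs-rest accuracy; precision, recall and F1 follow the standard
  one-vs-rest definitions, with 0/0 reported as 0 plus a warning.
  Diverged runs are excluded and flagged rather than crashing the
  summary.
* **Condition comparison**: Welch's two-sample t-test on per-run
  accuracies (the published analysis does not name the variant; the group SDs
  differ, so the unequal-variance form is the defensible default).
* **LOOCV**: what "RMSE between true and predicted values" means for a
  classifier is left open in the published analysis; the package's convention is
  entry-wise RMSE between the one-hot truth and the predicted
  probability vector, reported with the SD of per-fold RMSEs. Folds
  train for a fixed epoch budget with no early stopping, and the
  final-epoch weights are used, so the held-out trial cannot leak into
  checkpoint selection. This convention is declared, not claimed to
  match the original analysis.

# Problem sizes used by the tests and acceptance script

The shipped experiments run on deliberately small instances chosen as
the smallest sizes at which each property is meaningful: learnability
uses 12 trials per class, durations 24–40 frames, no noise and no
amplitude jitter, with an 8/4/16/8/8 architecture (F/Z/RNN/attention/head
widths); the ablation uses 12 trials per class, durations 20–32, 10 mm
noise, default jitter, 5 runs per condition with a 70-epoch budget;
LOOCV runs on 8–12 trials. The full-scale defaults (769 trials, 60–180
frames, 64/16/64/16/16 architecture) are what a user reproducing the
original study design would run.

One property of the scaled ablation deserves a plain statement. The
racket-borne class signal (large orientation sweeps) is picked up within
tens of epochs, while the body-borne signal — which requires resolving
the drive/volley amplitude difference through the per-trial amplitude
jitter — takes this architecture much longer to find (often beyond 100
epochs on these small training sets; optimization sits on a long plateau
at the uniform-prediction loss before escaping). Within the shipped
70-epoch budget the without-racket condition therefore typically stays
near chance while the with-racket condition learns, which is exactly the
contrast the ablation measures: *what can be learned from this input at a
fixed budget*. The `body_only` control confirms the placement of the
signal: with the racket transform drawn independently of the class, the
two input conditions become statistically indistinguishable, and a
model-free check (nearest-neighbour classification on racket orientation
features) verifies that racket channels alone identify the stroke only
when the generator makes them informative.

# Known limitations

* Pure-R training: minutes per small run; the full 769-trial, 20-run
  protocol is a long computation best run overnight.
* The C3D reader supports Intel and big-endian IEEE files with float or
  scaled-integer point data; DEC-float files are rejected. Analog
  channels are ignored. Invalid samples (negative residuals) are
  linearly interpolated across interior gaps of at most 10 frames;
  trials with longer or boundary gaps are rejected rather than
  gap-filled.
* `RBAK` has no contralateral partner in Plug-in Gait, so mirroring
  reflects its coordinates without relabelling.
* The attention energies are affine in the hidden states, following the
  published formulation; a nonlinearity between the two attention layers
  may have been intended there, but is not assumed.
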