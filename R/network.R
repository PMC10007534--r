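## The attention temporal graph convolutional classifier, forward pass.
##
## Per frame, node coordinates pass through a three-layer spatial graph
## convolution over the normalized marker adjacency; the per-frame node
## embeddings are flattened to a frame vector, encoded forward and
## backward by gated recurrent cells (a BiRNN), pooled over time by soft
## attention into a context vector, and classified by a two-layer
## perceptron head. All weights live in a plain named list so the analytic
## backward pass (backprop.R) can mirror this file stage by stage.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmaxVec <- function(x) {
  # max-subtraction guard: mathematically unchanged, overflow-safe
  z <- exp(x - max(x))
  z / sum(z)
}

#' One spatial graph convolution layer
#'
#' Computes `activation(Ahat %*% X %*% W)`: symmetrically normalized
#' neighbourhood aggregation followed by a feature transform.
#'
#' @param X M x d node feature matrix
#' @param Ahat M x M normalized adjacency (see [normalizeAdjacency()])
#' @param W d x d2 weight matrix
#' @param activation `"none"`, `"relu"`, or `"sigmoid"`
#' @return M x d2 feature matrix
#' @export
gcnLayer <- function(X, Ahat, W, activation = c("none", "relu", "sigmoid")) {
  activation <- match.arg(activation)
  if (ncol(Ahat) != nrow(X) || ncol(X) != nrow(W))
    stop("shape mismatch in gcnLayer")
  Y <- Ahat %*% X %*% W
  switch(activation,
         none = Y,
         relu = pmax(Y, 0),
         sigmoid = sigmoid(Y))
}

#' Three-layer spatial graph convolution stack
#'
#' The per-frame spatial encoder: a linear aggregation layer, a ReLU
#' layer, and a sigmoid output layer, each preceded by multiplication with
#' the normalized adjacency. Output entries therefore lie in (0, 1), and
#' an all-zero frame maps to constant 0.5.
#'
#' @param X M x P node features for one frame (P = 3 coordinates)
#' @param Ahat normalized adjacency
#' @param gcn list with `W0` (P x F), `W1` (F x F), `W2` (F x Z)
#' @return M x Z node embeddings
#' @export
gcnStack <- function(X, Ahat, gcn) {
  L0 <- Ahat %*% X %*% gcn$W0
  L1 <- pmax(Ahat %*% L0 %*% gcn$W1, 0)
  sigmoid(Ahat %*% L1 %*% gcn$W2)
}

#' One gated recurrent cell step
#'
#' Update gate `u = sigmoid(Wu [x, h])`, reset gate `r = sigmoid(Wr [x, h])`,
#' candidate memory `mc = tanh(Wc [x, r*h])`, and output
#' `h_t = u * h_prev + (1 - u) * mc`. Note the gate convention: the update
#' gate multiplies the previous state (the complement multiplies the
#' candidate), which differs from the common GRU convention; see the
#' methods vignette.
#'
#' @param x input frame vector (length D)
#' @param hPrev previous hidden state (length R)
#' @param cell list with `Wu`, `Wr`, `Wc`, each R x (D + R)
#' @return list with `u`, `r`, `mc`, `h`
#' @export
gatedCell <- function(x, hPrev, cell) {
  if (ncol(cell$Wu) != length(x) + length(hPrev))
    stop("shape mismatch in gatedCell")
  xh <- c(x, hPrev)
  u <- sigmoid(drop(cell$Wu %*% xh))
  r <- sigmoid(drop(cell$Wr %*% xh))
  mc <- tanh(drop(cell$Wc %*% c(x, r * hPrev)))
  list(u = u, r = r, mc = mc, h = u * hPrev + (1 - u) * mc)
}

#' Bidirectional recurrent encoding of a frame sequence
#'
#' Runs one gated cell forward over t = 1..nf and an independently
#' parameterized cell backward over t = nf..1, starting from zero states,
#' and concatenates the two directions' hidden states per time step.
#'
#' @param seq nf x D matrix of frame vectors
#' @param fwd,bwd cell parameter lists (see [gatedCell()])
#' @return nf x 2R matrix of hidden states
#' @export
birnnEncode <- function(seq, fwd, bwd) {
  nf <- nrow(seq)
  if (is.null(nf) || nf < 1) stop("empty sequence")
  R <- nrow(fwd$Wu)
  H <- matrix(0, nf, 2 * R)
  h <- numeric(R)
  for (t in seq_len(nf)) {
    h <- gatedCell(seq[t, ], h, fwd)$h
    H[t, 1:R] <- h
  }
  h <- numeric(R)
  for (t in rev(seq_len(nf))) {
    h <- gatedCell(seq[t, ], h, bwd)$h
    H[t, R + 1:R] <- h
  }
  H
}

#' Per-time-step attention energies
#'
#' Two affine layers map each hidden state to a scalar energy:
#' `e_t = psi2 (psi1 u_t + b1) + b2`.
#'
#' @param H nf x 2R hidden state matrix
#' @param att list with `psi1` (A x 2R), `b1` (A), `psi2` (A), `b2` (scalar)
#' @return numeric vector of nf energies
#' @export
attentionEnergies <- function(H, att) {
  if (nrow(H) < 1) stop("empty hidden state matrix")
  if (ncol(att$psi1) != ncol(H)) stop("shape mismatch in attentionEnergies")
  Q <- H %*% t(att$psi1)                       # nf x A
  Q <- sweep(Q, 2, att$b1, `+`)
  drop(Q %*% att$psi2) + att$b2
}

#' Softmax attention weights over time
#'
#' `alpha_i = exp(e_i) / sum_k exp(e_k)`, computed with max-subtraction so
#' it is overflow-safe; shift-invariant and summing to one.
#'
#' @param e vector of attention energies
#' @return simplex vector of the same length
#' @export
attentionWeights <- function(e) {
  if (!all(is.finite(e))) stop("attention energies must be finite")
  softmaxVec(e)
}

#' Attention context vector
#'
#' The convex combination `Cv = sum_i alpha_i u_i` of hidden states.
#'
#' @param H nf x 2R hidden state matrix
#' @param alpha attention weights, length nf
#' @return list with `Cv` (length 2R) and `alpha`
#' @export
contextVector <- function(H, alpha) {
  if (length(alpha) != nrow(H)) stop("alpha length must match rows of H")
  list(Cv = drop(crossprod(H, alpha)), alpha = alpha)
}

#' Perceptron classification head
#'
#' A hidden layer, a linear layer to four class scores, and a terminal
#' softmax so the output is a probability distribution. The default hidden
#' activation is tanh; `activation = "softmax"` activates the hidden layer
#' by a softmax over its units (the original A3T-GCN formulation,
#' generalized to width > 1 — see the methods vignette for why it is not the default),
#' and `faithful = TRUE` reproduces that formulation's one-unit first layer,
#' whose softmax activation over a single unit is identically one (a
#' documented degenerate case).
#'
#' @param Cv context vector
#' @param head list with `V1` (Hw x 2R), `c1` (Hw), `V2` (4 x Hw), `c2` (4)
#' @param activation hidden activation: `"tanh"` or `"softmax"`
#' @param faithful use the degenerate one-unit softmax first layer
#' @return length-4 probability vector
#' @export
headForward <- function(Cv, head, activation = c("tanh", "softmax"),
                        faithful = FALSE) {
  activation <- match.arg(activation)
  if (faithful) {
    if (nrow(head$V1) != 1)
      stop("faithful mode requires a hidden width of 1")
    activation <- "softmax"     # softmax of a singleton: identically 1
  }
  z1 <- drop(head$V1 %*% Cv) + head$c1
  a1 <- if (activation == "softmax") softmaxVec(z1) else tanh(z1)
  z2 <- drop(head$V2 %*% a1) + head$c2
  softmaxVec(z2)
}

## ---- model container ----------------------------------------------------

#' Model hyperparameter configuration
#'
#' @param F GCN hidden width
#' @param Z GCN output embedding width per node
#' @param rnnWidth hidden width of each recurrent direction
#' @param attWidth hidden width of the attention energy map
#' @param headHidden hidden width of the classification head
#' @param headActivation hidden activation of the head, `"tanh"` (default)
#'   or `"softmax"` (see [headForward()])
#' @param meanPool pool node embeddings by mean instead of flattening
#'   (flattening preserves which node moved and is the default)
#' @param faithfulHead use the degenerate one-unit head wiring of the original formulation
#' @return named list
#' @export
modelConfig <- function(F = 64L, Z = 16L, rnnWidth = 64L, attWidth = 16L,
                        headHidden = 16L,
                        headActivation = c("tanh", "softmax"),
                        meanPool = FALSE, faithfulHead = FALSE) {
  headActivation <- match.arg(headActivation)
  stopifnot(F > 0, Z > 0, rnnWidth > 0, attWidth > 0, headHidden > 0)
  if (faithfulHead) { headHidden <- 1L; headActivation <- "softmax" }
  list(F = as.integer(F), Z = as.integer(Z), rnnWidth = as.integer(rnnWidth),
       attWidth = as.integer(attWidth), headHidden = as.integer(headHidden),
       headActivation = headActivation, meanPool = meanPool,
       faithfulHead = faithfulHead)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, drawn from the current RNG stream
#' (seed it for reproducibility).
#'
#' @param graph a [SkeletonGraph-class]; fixes the node count M
#' @param config a [modelConfig()]
#' @return named list of parameter arrays, plus `$config` and `$M`
#' @export
initModel <- function(graph, config = modelConfig()) {
  M <- nMarkers(graph)
  D <- if (config$meanPool) config$Z else M * config$Z
  R <- config$rnnWidth
  cell <- function() list(Wu = glorot(R, D + R), Wr = glorot(R, D + R),
                          Wc = glorot(R, D + R))
  list(
    gcn = list(W0 = glorot(3L, config$F), W1 = glorot(config$F, config$F),
               W2 = glorot(config$F, config$Z)),
    fwd = cell(), bwd = cell(),
    att = list(psi1 = glorot(config$attWidth, 2L * R),
               b1 = numeric(config$attWidth),
               psi2 = drop(glorot(config$attWidth, 1L)), b2 = 0),
    head = list(V1 = glorot(config$headHidden, 2L * R),
                c1 = numeric(config$headHidden),
                V2 = glorot(4L, config$headHidden), c2 = numeric(4L)),
    config = config, M = M)
}

frameVectors <- function(X, Ahat, model) {
  # X: nf x M x 3 -> nf x D matrix of flattened (or mean-pooled) embeddings
  nf <- dim(X)[1]
  M <- dim(X)[2]
  D <- if (model$config$meanPool) model$config$Z else M * model$config$Z
  out <- matrix(0, nf, D)
  emb <- vector("list", nf)
  for (t in seq_len(nf)) {
    E <- gcnStack(matrix(X[t, , ], M, 3), Ahat, model$gcn)
    emb[[t]] <- E
    out[t, ] <- if (model$config$meanPool) colMeans(E) else as.vector(E)
  }
  list(seq = out, emb = emb)
}

#' Full model forward pass for one trial
#'
#' GCN per frame, flatten node embeddings to frame vectors, bidirectional
#' recurrent encoding, soft attention pooling, perceptron head.
#'
#' @param X padded trial array, nf x M x 3
#' @param graph a [SkeletonGraph-class] with matching M
#' @param model parameters from [initModel()]
#' @return length-4 class probability vector
#' @export
modelForward <- function(X, graph, model) {
  if (dim(X)[2] != model$M || nMarkers(graph) != model$M)
    stop("marker count mismatch between input, graph and model")
  fv <- frameVectors(X, normalizedAdjacency(graph), model)
  H <- birnnEncode(fv$seq, model$fwd, model$bwd)
  alpha <- attentionWeights(attentionEnergies(H, model$att))
  cv <- contextVector(H, alpha)
  headForward(cv$Cv, model$head,
              activation = model$config$headActivation %||% "tanh",
              faithful = model$config$faithfulHead)
}

#' Sparse categorical cross-entropy loss
#'
#' Mean over the batch of `-log p[true class]`, with probabilities clamped
#' at 1e-12 before the log.
#'
#' @param pred matrix of class probabilities (rows = trials) or a single
#'   probability vector
#' @param labels integer class ids 0..3
#' @return scalar loss
#' @export
sparseCCELoss <- function(pred, labels) {
  if (is.vector(pred)) pred <- matrix(pred, nrow = 1)
  labels <- as.integer(labels)
  if (any(labels < 0 | labels >= ncol(pred)))
    stop("label out of range")
  p <- pmax(pred[cbind(seq_len(nrow(pred)), labels + 1L)], 1e-12)
  mean(-log(p))
}
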