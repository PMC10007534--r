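test_that("a GCN layer equals naive neighbour aggregation", {
  g <- tinyGraph()
  A <- normalizedAdjacency(g)
  set.seed(11)
  X <- matrix(rnorm(9), 3, 3)
  W <- matrix(rnorm(6), 3, 2)
  # identity graph, identity weights
  expect_equal(gcnLayer(X, diag(3), diag(3)), X)
  # naive double-loop aggregation oracle on a random 5-node graph
  set.seed(12)
  O5 <- matrix(0, 5, 5); O5[cbind(c(1,2,3,1), c(2,3,4,5))] <- 1
  O5 <- O5 + t(O5)
  A5 <- normalizeAdjacency(O5)
  X5 <- matrix(rnorm(15), 5, 3); W5 <- matrix(rnorm(12), 3, 4)
  naive <- matrix(0, 5, 4)
  for (i in 1:5) for (f in 1:4) {
    agg <- numeric(3)
    for (j in 1:5) agg <- agg + A5[i, j] * X5[j, ]
    naive[i, f] <- sum(agg * W5[, f])
  }
  expect_lt(max(abs(gcnLayer(X5, A5, W5) - naive)), 1e-10)
  # permutation equivariance
  perm <- c(3, 5, 1, 2, 4)
  P <- diag(5)[perm, ]
  lhs <- gcnLayer(P %*% X5, P %*% A5 %*% t(P), W5)
  expect_equal(lhs, P %*% gcnLayer(X5, A5, W5), tolerance = 1e-12)
  expect_error(gcnLayer(X5, A5, matrix(0, 5, 2)), "shape")
})

test_that("the three-layer GCN stack matches a hand-unrolled oracle", {
  g <- tinyGraph()
  A <- normalizedAdjacency(g)
  set.seed(13)
  gcn <- list(W0 = matrix(rnorm(3 * 2), 3, 2),
              W1 = matrix(rnorm(4), 2, 2),
              W2 = matrix(rnorm(4), 2, 2))
  X <- matrix(rnorm(9), 3, 3)
  manual <- 1 / (1 + exp(-(A %*% pmax(A %*% (A %*% X %*% gcn$W0) %*% gcn$W1, 0) %*% gcn$W2)))
  expect_equal(gcnStack(X, A, gcn), manual, tolerance = 1e-12)
  # all-zero frame -> sigmoid(0) = 0.5 everywhere
  expect_true(all(gcnStack(matrix(0, 3, 3), A, gcn) == 0.5))
  # bounded output
  out <- gcnStack(matrix(rnorm(9, sd = 10), 3, 3), A, gcn)
  expect_true(all(out > 0 & out < 1))
})

test_that("the gated cell follows the published gate equations", {
  D <- 3; R <- 2
  zeroCell <- list(Wu = matrix(0, R, D + R), Wr = matrix(0, R, D + R),
                   Wc = matrix(0, R, D + R))
  # zero weights, zero state: gates 0.5, memory 0, output 0
  st <- gatedCell(rnorm(D), numeric(R), zeroCell)
  expect_equal(st$u, rep(0.5, R))
  expect_equal(st$r, rep(0.5, R))
  expect_equal(st$mc, rep(0, R))
  expect_equal(st$h, rep(0, R))
  # zero weights, state v: h = u*v + (1-u)*0 = 0.5 v  (the update gate
  # multiplies the previous state in this formulation)
  v <- c(0.8, -1.2)
  expect_equal(gatedCell(rnorm(D), v, zeroCell)$h, 0.5 * v)
  # generic case vs direct arithmetic
  set.seed(21)
  cell <- list(Wu = matrix(rnorm(R * (D + R)), R), Wr = matrix(rnorm(R * (D + R)), R),
               Wc = matrix(rnorm(R * (D + R)), R))
  x <- rnorm(D); h0 <- rnorm(R)
  st <- gatedCell(x, h0, cell)
  u <- 1 / (1 + exp(-drop(cell$Wu %*% c(x, h0))))
  r <- 1 / (1 + exp(-drop(cell$Wr %*% c(x, h0))))
  mc <- tanh(drop(cell$Wc %*% c(x, r * h0)))
  expect_equal(st$h, u * h0 + (1 - u) * mc, tolerance = 1e-14)
  expect_true(all(st$u > 0 & st$u < 1 & st$r > 0 & st$r < 1))
  expect_error(gatedCell(rnorm(5), h0, cell), "shape")
})

test_that("bidirectional encoding equals a manual unroll and is time-symmetric", {
  D <- 3; R <- 2; nf <- 3
  set.seed(22)
  mk <- function() list(Wu = matrix(rnorm(R * (D + R)), R),
                        Wr = matrix(rnorm(R * (D + R)), R),
                        Wc = matrix(rnorm(R * (D + R)), R))
  fwd <- mk(); bwd <- mk()
  seqm <- matrix(rnorm(nf * D), nf, D)
  H <- birnnEncode(seqm, fwd, bwd)
  # manual unroll oracle
  h <- numeric(R)
  for (t in 1:nf) { h <- gatedCell(seqm[t, ], h, fwd)$h
                    expect_equal(H[t, 1:R], h, tolerance = 1e-14) }
  h <- numeric(R)
  for (t in nf:1) { h <- gatedCell(seqm[t, ], h, bwd)$h
                    expect_equal(H[t, R + 1:R], h, tolerance = 1e-14) }
  # reversing time and swapping directions reverses rows and swaps halves
  Hrev <- birnnEncode(seqm[nf:1, ], bwd, fwd)
  expect_equal(Hrev[nf:1, c(R + 1:R, 1:R)], H, tolerance = 1e-14)
  # single frame: both directions see the same input
  H1 <- birnnEncode(seqm[1, , drop = FALSE], fwd, fwd)
  expect_equal(H1[1, 1:R], H1[1, R + 1:R])
})

test_that("attention energies are the two-layer affine map", {
  nf <- 3; twoR <- 4; Aw <- 2
  set.seed(23)
  H <- matrix(rnorm(nf * twoR), nf, twoR)
  att <- list(psi1 = matrix(rnorm(Aw * twoR), Aw), b1 = rnorm(Aw),
              psi2 = rnorm(Aw), b2 = rnorm(1))
  e <- attentionEnergies(H, att)
  for (t in 1:nf)
    expect_equal(e[t],
                 sum(att$psi2 * (drop(att$psi1 %*% H[t, ]) + att$b1)) + att$b2,
                 tolerance = 1e-14)
  # zero weights, bias c: all energies equal c
  attZ <- list(psi1 = matrix(0, Aw, twoR), b1 = numeric(Aw),
               psi2 = numeric(Aw), b2 = 3.25)
  expect_equal(attentionEnergies(H, attZ), rep(3.25, nf))
  # shifting b2 shifts every energy by the same constant
  att2 <- att; att2$b2 <- att$b2 + 1.5
  expect_equal(attentionEnergies(H, att2), e + 1.5)
})

test_that("softmax weights match closed forms and are shift-invariant", {
  expect_equal(attentionWeights(c(0, 0)), c(0.5, 0.5))
  expect_equal(attentionWeights(c(log(2), 0)), c(2 / 3, 1 / 3),
               tolerance = 1e-14)
  set.seed(24)
  for (k in 1:20) {
    e <- rnorm(sample(2:30, 1), sd = 10)
    a <- attentionWeights(e)
    expect_lt(abs(sum(a) - 1), 1e-12)
    expect_true(all(a >= 0))
    expect_equal(attentionWeights(e + 123.4), a, tolerance = 1e-12)
  }
  # extreme energies must not overflow
  expect_equal(sum(attentionWeights(c(1e4, 0, -1e4))), 1)
  expect_error(attentionWeights(c(1, NA)), "finite")
})

test_that("the context vector is the attention-weighted state average", {
  nf <- 4; twoR <- 3
  set.seed(25)
  H <- matrix(rnorm(nf * twoR), nf, twoR)
  alpha <- attentionWeights(rnorm(nf))
  cv <- contextVector(H, alpha)
  oracle <- numeric(twoR)
  for (t in 1:nf) oracle <- oracle + alpha[t] * H[t, ]
  expect_equal(cv$Cv, oracle, tolerance = 1e-14)
  # identical states: convexity makes Cv that state, for any alpha
  Hsame <- matrix(rep(c(1, -2, 0.5), each = nf), nf, twoR)
  expect_equal(contextVector(Hsame, alpha)$Cv, c(1, -2, 0.5))
  # one-hot alpha selects a single state
  oneHot <- c(0, 0, 1, 0)
  expect_equal(contextVector(H, oneHot)$Cv, H[3, ])
  expect_error(contextVector(H, alpha[1:2]), "length")
})

test_that("the head always emits a probability distribution", {
  twoR <- 4; Hw <- 3
  set.seed(26)
  head <- list(V1 = matrix(rnorm(Hw * twoR), Hw), c1 = rnorm(Hw),
               V2 = matrix(rnorm(4 * Hw), 4), c2 = rnorm(4))
  for (act in c("tanh", "softmax")) {
    p <- headForward(rnorm(twoR), head, activation = act)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  # zero weights: uniform prediction in either mode
  headZ <- list(V1 = matrix(0, Hw, twoR), c1 = numeric(Hw),
                V2 = matrix(0, 4, Hw), c2 = numeric(4))
  expect_equal(headForward(rnorm(twoR), headZ), rep(0.25, 4))
  expect_equal(headForward(rnorm(twoR), headZ, activation = "softmax"),
               rep(0.25, 4))
  # faithful one-unit wiring: its softmax is identically 1, so the
  # prediction ignores the context vector
  head1 <- list(V1 = matrix(rnorm(twoR), 1), c1 = rnorm(1),
                V2 = matrix(rnorm(4), 4, 1), c2 = rnorm(4))
  p1 <- headForward(rnorm(twoR), head1, faithful = TRUE)
  p2 <- headForward(rnorm(twoR) * 100, head1, faithful = TRUE)
  expect_equal(p1, p2, tolerance = 1e-14)
  expect_error(headForward(rnorm(twoR), head, faithful = TRUE), "width")
})

test_that("the full forward pass composes the stage operations", {
  g <- tinyGraph()
  m <- tinyModel(seed = 31)
  X <- randomTrialArray(2, 3)
  p <- modelForward(X, g, m)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p > 0))
  # stagewise composition oracle (M = 3, nf = 2)
  A <- normalizedAdjacency(g)
  seqm <- t(vapply(1:2, function(t)
    as.vector(gcnStack(matrix(X[t, , ], 3, 3), A, m$gcn)), numeric(6)))
  H <- birnnEncode(seqm, m$fwd, m$bwd)
  alpha <- attentionWeights(attentionEnergies(H, m$att))
  Cv <- contextVector(H, alpha)$Cv
  expect_equal(p, headForward(Cv, m$head), tolerance = 1e-12)
  # determinism
  expect_identical(p, modelForward(X, g, m))
  expect_error(modelForward(randomTrialArray(2, 4), g, m), "mismatch")
})

test_that("sparse categorical cross-entropy matches its closed forms", {
  expect_equal(sparseCCELoss(c(0, 1, 0, 0), 1L), 0)
  expect_equal(sparseCCELoss(rep(0.25, 4), 2L), log(4), tolerance = 1e-12)
  set.seed(27)
  P <- t(vapply(1:50, function(i) attentionWeights(rnorm(4)), numeric(4)))
  labs <- sample(0:3, 50, replace = TRUE)
  expect_gte(sparseCCELoss(P, labs), 0)
  expect_equal(sparseCCELoss(P, labs),
               mean(-log(P[cbind(1:50, labs + 1)])), tolerance = 1e-12)
  expect_error(sparseCCELoss(P, c(labs[-1], 4L)), "range")
  # clamp keeps an exact zero probability finite
  expect_true(is.finite(sparseCCELoss(c(1, 0, 0, 0), 1L)))
})

test_that("analytic gradients agree with finite differences", {
  g <- tinyGraph()
  m <- tinyModel(seed = 3)
  set.seed(33)
  inputs <- list(randomTrialArray(2, 3), randomTrialArray(2, 3))
  expect_lt(gradientCheck(inputs, c(0L, 2L), g, m), 1e-6)
  m2 <- tinyModel(seed = 4, headActivation = "softmax")
  expect_lt(gradientCheck(inputs, c(1L, 3L), g, m2), 1e-6)
})

test_that("checkpoints round-trip to identical predictions", {
  g <- tinyGraph()
  m <- tinyModel(seed = 44)
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  X <- randomTrialArray(3, 3)
  expect_identical(modelForward(X, g, m), modelForward(X, g, m2))
})
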