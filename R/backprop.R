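## Analytic gradients for the full model, stage by stage mirroring the
## forward pass in network.R. Gradients are exact (verified against
## central finite differences in the test suite), so training needs no
## autodiff framework.
##
## For speed, the per-trial forward/backward below vectorize over frames:
## each GCN layer is one large matrix product over all frames, the
## recurrent cells precompute their input projections for the whole
## sequence, and weight-gradient accumulations collapse into single
## crossprod() calls. The per-frame stage functions in network.R are the
## readable reference; the test suite checks the two paths agree.

# layout helpers: "rows" form stacks frames as (M*nf) x d row blocks,
# "cat" form stacks frames as M x (d*nf) column blocks (for Ahat %*% .)
rows2cat <- function(Xr, M, nf, d)
  matrix(aperm(array(Xr, c(M, nf, d)), c(1, 3, 2)), M, d * nf)
cat2rows <- function(Xc, M, nf, d)
  matrix(aperm(array(Xc, c(M, d, nf)), c(1, 3, 2)), M * nf, d)

# forward pass retaining every intermediate the backward pass needs
forwardCache <- function(X, Ahat, model) {
  nf <- dim(X)[1]; M <- dim(X)[2]
  cfg <- model$config
  Fh <- cfg$F; Z <- cfg$Z
  D <- if (cfg$meanPool) Z else M * Z

  # --- GCN stack, all frames at once ---
  Xcat <- matrix(aperm(X, c(2, 3, 1)), M, 3 * nf)
  AXr <- cat2rows(Ahat %*% Xcat, M, nf, 3)         # (M*nf) x 3
  L0r <- AXr %*% model$gcn$W0
  AL0r <- cat2rows(Ahat %*% rows2cat(L0r, M, nf, Fh), M, nf, Fh)
  S1r <- AL0r %*% model$gcn$W1
  L1r <- pmax(S1r, 0)
  AL1r <- cat2rows(Ahat %*% rows2cat(L1r, M, nf, Fh), M, nf, Fh)
  L2r <- sigmoid(AL1r %*% model$gcn$W2)            # (M*nf) x Z
  emb <- aperm(array(L2r, c(M, nf, Z)), c(2, 1, 3))  # nf x M x Z
  seqMat <- if (cfg$meanPool) apply(emb, c(1, 3), mean)
            else matrix(emb, nf, M * Z)

  # --- bidirectional gated recurrence ---
  R <- cfg$rnnWidth
  runDir <- function(cell, order) {
    Wx <- lapply(cell, function(W) W[, seq_len(D), drop = FALSE])
    Wh <- lapply(cell, function(W) W[, D + seq_len(R), drop = FALSE])
    Px <- lapply(Wx, function(W) tcrossprod(W, seqMat))   # R x nf each
    U <- Rg <- Mc <- Hp <- Hd <- matrix(0, R, nf)
    h <- numeric(R)
    for (t in order) {
      u <- sigmoid(Px$Wu[, t] + drop(Wh$Wu %*% h))
      r <- sigmoid(Px$Wr[, t] + drop(Wh$Wr %*% h))
      mc <- tanh(Px$Wc[, t] + drop(Wh$Wc %*% (r * h)))
      U[, t] <- u; Rg[, t] <- r; Mc[, t] <- mc; Hp[, t] <- h
      h <- u * h + (1 - u) * mc
      Hd[, t] <- h
    }
    list(U = U, Rg = Rg, Mc = Mc, Hp = Hp, Hd = Hd, Wh = Wh)
  }
  fwdD <- runDir(model$fwd, seq_len(nf))
  bwdD <- runDir(model$bwd, rev(seq_len(nf)))
  H <- cbind(t(fwdD$Hd), t(bwdD$Hd))               # nf x 2R

  # --- attention, context, head ---
  Q <- sweep(H %*% t(model$att$psi1), 2, model$att$b1, `+`)   # nf x A
  e <- drop(Q %*% model$att$psi2) + model$att$b2
  alpha <- softmaxVec(e)
  Cv <- drop(crossprod(H, alpha))
  z1 <- drop(model$head$V1 %*% Cv) + model$head$c1
  a1 <- if ((model$config$headActivation %||% "tanh") == "softmax" ||
            model$config$faithfulHead) softmaxVec(z1) else tanh(z1)
  z2 <- drop(model$head$V2 %*% a1) + model$head$c2
  p <- softmaxVec(z2)
  list(AXr = AXr, AL0r = AL0r, S1r = S1r, AL1r = AL1r, L2r = L2r,
       seqMat = seqMat, fwdD = fwdD, bwdD = bwdD, H = H, Q = Q,
       alpha = alpha, Cv = Cv, a1 = a1, p = p, nf = nf, M = M, D = D)
}

zeroGrads <- function(model) {
  zl <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
                    else numeric(length(x))
  list(gcn = lapply(model$gcn, zl), fwd = lapply(model$fwd, zl),
       bwd = lapply(model$bwd, zl), att = lapply(model$att, zl),
       head = lapply(model$head, zl))
}

addGrads <- function(a, b, w = 1) {
  for (g in names(a)) for (p in names(a[[g]]))
    a[[g]][[p]] <- a[[g]][[p]] + w * b[[g]][[p]]
  a
}

# backward pass for one trial; returns gradient of -log p[label] w.r.t.
# every parameter
backwardTrial <- function(cache, label, Ahat, model) {
  g <- zeroGrads(model)
  cfg <- model$config
  R <- cfg$rnnWidth; Fh <- cfg$F; Z <- cfg$Z
  nf <- cache$nf; M <- cache$M; D <- cache$D

  dz2 <- cache$p
  dz2[label + 1L] <- dz2[label + 1L] - 1
  g$head$V2 <- outer(dz2, cache$a1)
  g$head$c2 <- dz2
  da1 <- drop(crossprod(model$head$V2, dz2))
  dz1 <- if ((cfg$headActivation %||% "tanh") == "softmax" || cfg$faithfulHead)
    cache$a1 * (da1 - sum(cache$a1 * da1))   # softmax Jacobian
  else da1 * (1 - cache$a1^2)                # tanh derivative
  g$head$V1 <- outer(dz1, cache$Cv)
  g$head$c1 <- dz1
  dCv <- drop(crossprod(model$head$V1, dz1))

  dalpha <- drop(cache$H %*% dCv)
  dH <- outer(cache$alpha, dCv)
  de <- cache$alpha * (dalpha - sum(cache$alpha * dalpha))
  dQ <- outer(de, model$att$psi2)                  # nf x A
  g$att$psi2 <- drop(crossprod(cache$Q, de))
  g$att$b2 <- sum(de)
  g$att$psi1 <- crossprod(dQ, cache$H)
  g$att$b1 <- colSums(dQ)
  dH <- dH + dQ %*% model$att$psi1

  bpttDir <- function(dd, cell, dHdir, order) {
    # order: reverse of the processing order; the carry flows into hPrev
    DAU <- DAR <- DAC <- matrix(0, R, nf)
    carry <- numeric(R)
    tWuh <- t(dd$Wh$Wu); tWrh <- t(dd$Wh$Wr); tWch <- t(dd$Wh$Wc)
    for (t in order) {
      u <- dd$U[, t]; r <- dd$Rg[, t]; mc <- dd$Mc[, t]; hp <- dd$Hp[, t]
      dh <- dHdir[t, ] + carry
      du <- dh * (hp - mc)
      dmc <- dh * (1 - u)
      dhPrev <- dh * u
      dac <- dmc * (1 - mc^2)
      drh <- drop(tWch %*% dac)
      dr <- drh * hp
      dhPrev <- dhPrev + drh * r
      dau <- du * u * (1 - u)
      dar <- dr * r * (1 - r)
      DAU[, t] <- dau; DAR[, t] <- dar; DAC[, t] <- dac
      carry <- dhPrev + drop(tWuh %*% dau) + drop(tWrh %*% dar)
    }
    XH <- cbind(cache$seqMat, t(dd$Hp))             # nf x (D+R)
    XRH <- cbind(cache$seqMat, t(dd$Rg * dd$Hp))
    Wx <- lapply(cell, function(W) W[, seq_len(D), drop = FALSE])
    dSeqDir <- crossprod(DAU, Wx$Wu) + crossprod(DAR, Wx$Wr) +
               crossprod(DAC, Wx$Wc)                # nf x D
    list(Wu = DAU %*% XH, Wr = DAR %*% XH, Wc = DAC %*% XRH,
         dSeq = dSeqDir)
  }
  bf <- bpttDir(cache$fwdD, model$fwd, dH[, 1:R, drop = FALSE],
                rev(seq_len(nf)))
  bb <- bpttDir(cache$bwdD, model$bwd, dH[, R + 1:R, drop = FALSE],
                seq_len(nf))
  g$fwd <- list(Wu = bf$Wu, Wr = bf$Wr, Wc = bf$Wc)
  g$bwd <- list(Wu = bb$Wu, Wr = bb$Wr, Wc = bb$Wc)
  dSeq <- bf$dSeq + bb$dSeq                         # nf x D

  # --- GCN backward, all frames at once ---
  dL2r <- if (cfg$meanPool)
    matrix(aperm(array(rep(dSeq / M, each = 1), c(nf, 1, Z))[, rep(1, M), ,
                 drop = FALSE], c(2, 1, 3)), M * nf, Z)
  else matrix(aperm(array(dSeq, c(nf, M, Z)), c(2, 1, 3)), M * nf, Z)
  dS2r <- dL2r * cache$L2r * (1 - cache$L2r)
  g$gcn$W2 <- crossprod(cache$AL1r, dS2r)
  dL1r <- cat2rows(Ahat %*% rows2cat(tcrossprod(dS2r, model$gcn$W2),
                                     M, nf, Fh), M, nf, Fh)
  dS1r <- dL1r * (cache$S1r > 0)
  g$gcn$W1 <- crossprod(cache$AL0r, dS1r)
  dL0r <- cat2rows(Ahat %*% rows2cat(tcrossprod(dS1r, model$gcn$W1),
                                     M, nf, Fh), M, nf, Fh)
  g$gcn$W0 <- crossprod(cache$AXr, dL0r)
  g
}

#' Loss and gradients for a batch of trials
#'
#' Mean sparse categorical cross-entropy over the batch and its exact
#' analytic gradient with respect to every model parameter.
#'
#' @param inputs list of padded trial arrays (nf x M x 3)
#' @param labels integer class ids 0..3
#' @param graph a [SkeletonGraph-class]
#' @param model parameters from [initModel()]
#' @return list with `loss`, `grads` (same structure as the parameters),
#'   and `probs` (batch x 4 matrix)
#' @export
modelGradients <- function(inputs, labels, graph, model) {
  Ahat <- normalizedAdjacency(graph)
  n <- length(inputs)
  grads <- zeroGrads(model)
  loss <- 0
  probs <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    cache <- forwardCache(inputs[[i]], Ahat, model)
    probs[i, ] <- cache$p
    loss <- loss + -log(max(cache$p[labels[i] + 1L], 1e-12))
    grads <- addGrads(grads, backwardTrial(cache, labels[i], Ahat, model),
                      w = 1 / n)
  }
  list(loss = loss / n, grads = grads, probs = probs)
}

## ---- parameter flattening (gradient checks, Adam state) -----------------

paramLeaves <- function(model) {
  out <- list()
  for (g in c("gcn", "fwd", "bwd", "att", "head"))
    for (p in names(model[[g]]))
      out[[paste(g, p, sep = ".")]] <- model[[g]][[p]]
  out
}

flattenParams <- function(model) {
  unlist(paramLeaves(model), use.names = FALSE)
}

unflattenParams <- function(vec, model) {
  pos <- 0L
  for (g in c("gcn", "fwd", "bwd", "att", "head"))
    for (p in names(model[[g]])) {
      x <- model[[g]][[p]]
      n <- length(x)
      val <- vec[pos + seq_len(n)]
      model[[g]][[p]] <- if (is.matrix(x)) matrix(val, nrow(x), ncol(x))
                         else val
      pos <- pos + n
    }
  model
}

#' Finite-difference check of the analytic gradients
#'
#' Compares the analytic gradient of the batch loss with central finite
#' differences over every parameter. Returns the worst relative
#' discrepancy, `max |ga - gn| / max(1, |gn|)`.
#'
#' @param inputs,labels,graph,model as in [modelGradients()]
#' @param h finite-difference step
#' @return scalar worst-case relative discrepancy
#' @export
gradientCheck <- function(inputs, labels, graph, model, h = 1e-5) {
  res <- modelGradients(inputs, labels, graph, model)
  ga <- flattenParams(res$grads)
  theta <- flattenParams(model)
  gn <- numeric(length(theta))
  Ahat <- normalizedAdjacency(graph)
  lossAt <- function(v) {
    m <- unflattenParams(v, model)
    tot <- 0
    for (i in seq_along(inputs)) {
      p <- forwardCache(inputs[[i]], Ahat, m)$p
      tot <- tot + -log(max(p[labels[i] + 1L], 1e-12))
    }
    tot / length(inputs)
  }
  for (k in seq_along(theta)) {
    vp <- theta; vp[k] <- vp[k] + h
    vm <- theta; vm[k] <- vm[k] - h
    gn[k] <- (lossAt(vp) - lossAt(vm)) / (2 * h)
  }
  max(abs(ga - gn) / pmax(1, abs(gn)))
}
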