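## Training loop (Adam, minibatches, early stopping on validation loss),
## evaluation, confusion matrices and the standard multiclass metrics.

#' Training hyperparameters
#'
#' @param lr Adam learning rate
#' @param batchSize minibatch size
#' @param epochs maximum number of epochs
#' @param patience early-stopping patience on validation loss; `Inf`
#'   disables early stopping
#' @param clipNorm global gradient-norm clip (numerical guard against
#'   divergence); `Inf` disables
#' @param seed RNG seed for initialization and shuffling
#' @param model a [modelConfig()]
#' @param nf pad target; defaults to the longest trial seen
#' @param center,scale,standardize input preprocessing switches (see
#'   [normalizeTrial()] and [standardizeHandedness()])
#' @return named list
#' @export
trainConfig <- function(lr = 1e-3, batchSize = 16L, epochs = 200L,
                        patience = 20L, clipNorm = 5, seed = 1L,
                        model = modelConfig(), nf = NULL, center = TRUE,
                        scale = TRUE, standardize = TRUE) {
  list(lr = lr, batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       patience = patience, clipNorm = clipNorm, seed = as.integer(seed),
       model = model, nf = nf, center = center, scale = scale,
       standardize = standardize)
}

adamInit <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamStep <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

batchLossAcc <- function(inputs, labels, graph, model) {
  Ahat <- normalizedAdjacency(graph)
  n <- length(inputs)
  probs <- matrix(0, n, 4)
  for (i in seq_len(n))
    probs[i, ] <- forwardCache(inputs[[i]], Ahat, model)$p
  pred <- max.col(probs, ties.method = "first") - 1L
  list(loss = sparseCCELoss(probs, labels), acc = mean(pred == labels),
       probs = probs, pred = pred)
}

#' Train the classifier
#'
#' Adam optimization of the sparse categorical cross-entropy with
#' minibatches, returning the checkpoint with the best validation loss and
#' the full per-epoch accuracy/loss curves. A non-finite training loss
#' aborts with an error naming the epoch (divergence).
#'
#' @param train,val [TrialSet-class] partitions
#' @param graph a [SkeletonGraph-class] matching the sets' marker count
#' @param hyper a [trainConfig()]
#' @return list with `model` (best checkpoint), `curves` (per-epoch
#'   data.frame), `nf` (pad length used), and `bestEpoch`
#' @export
trainModel <- function(train, val, graph, hyper = trainConfig()) {
  if (!length(train) || !length(val)) stop("empty train or validation set")
  nf <- hyper$nf
  if (is.null(nf)) nf <- max(nFrames(train), nFrames(val))
  prepTr <- prepareInputs(train, nf = nf, center = hyper$center,
                          scale = hyper$scale, standardize = hyper$standardize)
  prepVa <- prepareInputs(val, nf = nf, center = hyper$center,
                          scale = hyper$scale, standardize = hyper$standardize)
  withSeed(hyper$seed, {
    model <- initModel(graph, hyper$model)
    theta <- flattenParams(model)
    opt <- adamInit(length(theta))
    n <- length(prepTr$inputs)
    bestLoss <- Inf; bestTheta <- theta; bestEpoch <- 0L; wait <- 0L
    curves <- data.frame()
    for (epoch in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      nBatches <- 0L
      for (start in seq(1L, n, by = hyper$batchSize)) {
        idx <- ord[start:min(start + hyper$batchSize - 1L, n)]
        res <- modelGradients(prepTr$inputs[idx], prepTr$labels[idx],
                              graph, model)
        if (!is.finite(res$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        gvec <- flattenParams(res$grads)
        gn <- sqrt(sum(gvec^2))
        if (is.finite(hyper$clipNorm) && gn > hyper$clipNorm)
          gvec <- gvec * hyper$clipNorm / gn
        upd <- adamStep(theta, gvec, opt, hyper$lr)
        theta <- upd$theta; opt <- upd$state
        model <- unflattenParams(theta, model)
        epochLoss <- epochLoss + res$loss
        nBatches <- nBatches + 1L
      }
      va <- batchLossAcc(prepVa$inputs, prepVa$labels, graph, model)
      curves <- rbind(curves, data.frame(
        epoch = epoch, trainLoss = epochLoss / nBatches,
        valLoss = va$loss, valAcc = va$acc))
      if (va$loss < bestLoss) {
        bestLoss <- va$loss; bestTheta <- theta; bestEpoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= hyper$patience) break
      }
    }
    list(model = unflattenParams(bestTheta, model),
         final = unflattenParams(theta, model), curves = curves,
         nf = nf, bestEpoch = bestEpoch)
  })
}

#' Confusion matrix from true and predicted labels
#'
#' @param trueLabels,predLabels integer class ids 0..3
#' @return 4 x 4 integer matrix, rows = true class, columns = predicted
#' @export
confusionCounts <- function(trueLabels, predLabels) {
  cm <- matrix(0L, 4, 4, dimnames = list(true = CLASS_NAMES,
                                         predicted = CLASS_NAMES))
  for (i in seq_along(trueLabels))
    cm[trueLabels[i] + 1L, predLabels[i] + 1L] <-
      cm[trueLabels[i] + 1L, predLabels[i] + 1L] + 1L
  cm
}

#' Evaluate a trained model on a test set
#'
#' @param fit result of [trainModel()] (or a bare model list)
#' @param test a [TrialSet-class]
#' @param graph the matching [SkeletonGraph-class]
#' @param nf pad target; defaults to the fit's training pad length, grown
#'   if the test set has longer trials
#' @param hyper preprocessing switches (a [trainConfig()])
#' @return list with `confusion`, `accuracy`, `predictions` (data.frame
#'   with true, predicted and the four class probabilities)
#' @export
evaluateModel <- function(fit, test, graph, nf = NULL,
                          hyper = trainConfig()) {
  model <- if (!is.null(fit$model)) fit$model else fit
  if (is.null(nf)) nf <- max(nFrames(test), fit$nf %||% 0L)
  prep <- prepareInputs(test, nf = nf, center = hyper$center,
                        scale = hyper$scale, standardize = hyper$standardize)
  res <- batchLossAcc(prep$inputs, prep$labels, graph, model)
  cm <- confusionCounts(prep$labels, res$pred)
  preds <- data.frame(true = prep$labels, predicted = res$pred)
  preds <- cbind(preds, setNames(as.data.frame(res$probs),
                                 paste0("p_", CLASS_NAMES)))
  list(confusion = cm, accuracy = res$acc, predictions = preds,
       loss = res$loss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multiclass metrics from a confusion matrix
#'
#' Accuracy is the trace over the total. Per class c (one vs rest):
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 the harmonic mean, and
#' one-vs-rest accuracy `(TP+TN)/total`. An undefined ratio (0/0) is
#' reported as 0 with a warning.
#'
#' @param cm 4 x 4 confusion matrix, rows = true, columns = predicted
#' @return list with `accuracy` and a per-class data.frame `perClass`
#' @export
classMetrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safeDiv <- function(num, den, what) {
    out <- ifelse(den == 0, 0, num / den)
    if (any(den == 0))
      warning("undefined ", what, " (0/0) reported as 0 for: ",
              paste(CLASS_NAMES[den == 0], collapse = ", "))
    out
  }
  precision <- safeDiv(tp, tp + fp, "precision")
  recall <- safeDiv(tp, tp + fn, "recall")
  f1 <- safeDiv(2 * precision * recall, precision + recall, "F1")
  list(accuracy = sum(tp) / total,
       perClass = data.frame(class = CLASS_NAMES, precision = precision,
                             recall = recall, f1 = f1,
                             ovrAccuracy = (tp + tn) / total,
                             row.names = NULL))
}

#' Save or load a model checkpoint
#'
#' A checkpoint is a single RDS file holding every named weight array and
#' the model configuration; [loadCheckpoint()] validates that the stored
#' arrays match the configuration's shapes by rebuilding the parameter
#' skeleton.
#'
#' @param model parameters from [initModel()] or [trainModel()]`$model`
#' @param path file path
#' @return `path` invisibly; for [loadCheckpoint()], the model list
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(weights = paramLeaves(model), config = model$config,
               M = model$M), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  model <- list(gcn = list(), fwd = list(), bwd = list(), att = list(),
                head = list(), config = ck$config, M = ck$M)
  for (key in names(ck$weights)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    model[[parts[1]]][[parts[2]]] <- ck$weights[[key]]
  }
  model
}
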