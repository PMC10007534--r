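## Experiment harness: stratified splits, repeated independent runs,
## leave-one-out cross-validation, the with/without-racket comparison and
## the report bundle.

#' Stratified split specification
#'
#' @param fractions train/validation/test fractions; must sum to 1
#' @param seed RNG seed for the split
#' @return named list
#' @export
splitSpec <- function(fractions = c(train = 0.60, val = 0.20, test = 0.20),
                      seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  list(fractions = fractions, seed = as.integer(seed))
}

#' Stratified train/validation/test split
#'
#' Per class, `floor(fraction * n_c)` trials go to train and to validation
#' and the remainder to test, from a seeded shuffle within each class.
#' Partitions are disjoint and their union is the input.
#'
#' @param set a [TrialSet-class]; every class must have at least 3 trials
#' @param spec a [splitSpec()]
#' @return list of three [TrialSet-class]: `train`, `val`, `test`
#' @export
stratifiedSplit <- function(set, spec = splitSpec()) {
  labs <- vapply(trials(set), classId, integer(1))
  cnt <- classCounts(set)
  if (any(cnt < 3))
    stop("every class needs at least 3 trials; got ",
         paste(cnt, collapse = "/"))
  withSeed(spec$seed, {
    trIdx <- vaIdx <- teIdx <- integer(0)
    for (cls in 0:3) {
      idx <- sample(which(labs == cls))
      nc <- length(idx)
      nTr <- floor(spec$fractions[1] * nc)
      nVa <- floor(spec$fractions[2] * nc)
      trIdx <- c(trIdx, idx[seq_len(nTr)])
      vaIdx <- c(vaIdx, idx[nTr + seq_len(nVa)])
      teIdx <- c(teIdx, idx[(nTr + nVa + 1):nc])
    }
    list(train = set[trIdx], val = set[vaIdx], test = set[teIdx])
  })
}

#' Repeated independent split/train/evaluate runs
#'
#' Runs `k` independent cycles (each with its own split seed and training
#' seed derived from `seed`), evaluates on each test partition, and
#' summarizes accuracy overall and per class (one-vs-rest accuracy,
#' precision, recall, F1) as mean/max/min/SD over runs. Runs that diverge
#' are excluded from the summary and flagged.
#'
#' @param set a [TrialSet-class]
#' @param graph the matching [SkeletonGraph-class]
#' @param k number of runs (default 20)
#' @param hyper a [trainConfig()]
#' @param spec a [splitSpec()] (its seed is re-derived per run)
#' @param seed root seed; run i uses `seed + 1000 * i`
#' @return list with `summary` (data.frame metric/class x mean/max/min/sd),
#'   `accuracies`, `perRun` (list of run records), `failed` (indices of
#'   diverged runs)
#' @export
repeatedRuns <- function(set, graph, k = 20L, hyper = trainConfig(),
                         spec = splitSpec(), seed = 1L) {
  if (k < 2) stop("need at least 2 runs")
  nf <- nFrames(set)
  perRun <- list()
  failed <- integer(0)
  for (i in seq_len(k)) {
    runSeed <- seed + 1000L * i
    sp <- stratifiedSplit(set, splitSpec(spec$fractions, seed = runSeed))
    h <- hyper; h$seed <- runSeed; h$nf <- nf
    rec <- tryCatch({
      fit <- trainModel(sp$train, sp$val, graph, h)
      ev <- evaluateModel(fit, sp$test, graph, nf = nf, hyper = h)
      met <- classMetrics(ev$confusion)
      list(seed = runSeed, accuracy = ev$accuracy, confusion = ev$confusion,
           metrics = met, bestEpoch = fit$bestEpoch)
    }, error = function(e) {
      warning("run ", i, " failed and was excluded: ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) failed <- c(failed, i) else perRun[[length(perRun) + 1L]] <- rec
  }
  if (!length(perRun)) stop("all runs failed")
  acc <- vapply(perRun, `[[`, numeric(1), "accuracy")
  summarize <- function(vals, metric, class) {
    data.frame(metric = metric, class = class, mean = mean(vals),
               max = max(vals), min = min(vals), sd = sd(vals))
  }
  summary <- summarize(acc, "accuracy", "overall")
  for (m in c("ovrAccuracy", "precision", "recall", "f1"))
    for (ci in 1:4) {
      vals <- vapply(perRun, function(r) r$metrics$perClass[[m]][ci],
                     numeric(1))
      summary <- rbind(summary, summarize(vals, m, CLASS_NAMES[ci]))
    }
  list(summary = summary, accuracies = acc, perRun = perRun, failed = failed)
}

## ---- LOOCV --------------------------------------------------------------

#' Entry-wise RMSE between one-hot truth and predicted probabilities
#'
#' The squared error is averaged over every entry of every
#' (one-hot truth, probability vector) pair; RMSE is its square root.
#' Also returns the per-fold RMSE values and their SD.
#'
#' @param trueLabels integer class ids 0..3
#' @param probs matrix of predicted probability vectors (rows = folds)
#' @return list with `rmse`, `sdRmse`, `perFold`
#' @export
rmseFromRecords <- function(trueLabels, probs) {
  n <- length(trueLabels)
  Y <- matrix(0, n, ncol(probs))
  Y[cbind(seq_len(n), trueLabels + 1L)] <- 1
  sq <- (Y - probs)^2
  perFold <- sqrt(rowMeans(sq))
  list(rmse = sqrt(mean(sq)), sdRmse = sd(perFold), perFold = perFold)
}

#' Leave-one-out cross-validation
#'
#' For each trial, trains on all others (a fixed number of epochs, no
#' early stopping: there is no validation partition inside a fold) and
#' records the held-out trial's one-hot truth against its predicted
#' probability vector. Summarized by entry-wise RMSE; the convention for
#' applying a regression-style RMSE to a classifier output is the
#' package's own and is documented in the methods vignette.
#'
#' @param set a [TrialSet-class] with at least 4 trials
#' @param graph the matching [SkeletonGraph-class]
#' @param hyper a [trainConfig()]; `epochs` is the fixed per-fold budget
#' @return list with `rmse`, `sdRmse`, `n`, and `records` (per-fold truth
#'   and probabilities)
#' @export
loocv <- function(set, graph, hyper = trainConfig(epochs = 30L,
                                                  patience = Inf)) {
  n <- length(set)
  if (n < 4) stop("LOOCV needs at least 4 trials")
  nf <- nFrames(set)
  probs <- matrix(0, n, 4)
  labs <- vapply(trials(set), classId, integer(1))
  for (i in seq_len(n)) {
    rest <- set[setdiff(seq_len(n), i)]
    h <- hyper; h$seed <- hyper$seed + i; h$nf <- nf; h$patience <- Inf
    # the held-out trial serves only as the curve monitor: the final-epoch
    # weights are used, so no checkpoint selection can leak it
    fit <- trainModel(rest, set[i], graph, h)
    ev <- evaluateModel(list(model = fit$final, nf = nf), set[i], graph,
                        nf = nf, hyper = h)
    probs[i, ] <- as.matrix(ev$predictions[, paste0("p_", CLASS_NAMES)])
  }
  r <- rmseFromRecords(labs, probs)
  list(rmse = r$rmse, sdRmse = r$sdRmse, n = n,
       records = data.frame(true = labs,
                            setNames(as.data.frame(probs),
                                     paste0("p_", CLASS_NAMES))))
}

#' Welch comparison of per-run accuracies between two conditions
#'
#' Two-sample Welch t-test on the per-run accuracy samples of two
#' experimental conditions (sign convention `a - b`).
#'
#' @param accA,accB numeric vectors of per-run accuracies (>= 2 each)
#' @return list with `t`, `df`, `p`, `meanA`, `meanB`
#' @export
compareConditions <- function(accA, accB) {
  if (length(accA) < 2 || length(accB) < 2)
    stop("need at least 2 accuracies per condition")
  if (sd(accA) == 0 && sd(accB) == 0) {
    # degenerate limit of the Welch statistic: reported, not fatal
    d <- mean(accA) - mean(accB)
    return(list(t = if (d == 0) 0 else sign(d) * Inf, df = NA_real_,
                p = if (d == 0) 1 else 0, meanA = mean(accA),
                meanB = mean(accB), note = "zero variance in both samples"))
  }
  ht <- t.test(accA, accB)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, meanA = mean(accA), meanB = mean(accB))
}

## ---- pipeline -----------------------------------------------------------

#' End-to-end experiment pipeline
#'
#' Generates (or accepts) a 46-marker corpus, runs the repeated-runs
#' experiment for both input conditions (with the racket: 46 nodes;
#' without: racket channels stripped, 39 nodes), compares the two
#' accuracy samples with a Welch t-test, and writes the report bundle
#' (summary tables, confusion matrices in counts and percent, a JSONL run
#' log) to `outDir`. Fully regenerable from the configuration and seed.
#'
#' @param outDir output directory (created if needed); `NULL` skips writing
#' @param synth a [synthConfig()] used when `dataset` is `NULL`
#' @param dataset optional pre-assembled 46-marker [TrialSet-class]
#' @param hyper a [trainConfig()]
#' @param k runs per condition
#' @param seed root seed
#' @param conditions subset of `c("with_racket", "without_racket")`
#' @return list with per-condition results, the comparison, and the graphs
#' @export
runPipeline <- function(outDir = NULL, synth = synthConfig(),
                        dataset = NULL, hyper = trainConfig(), k = 20L,
                        seed = 1L,
                        conditions = c("with_racket", "without_racket")) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (is.null(dataset)) dataset <- generateDataset(synth)
  if (nMarkers(dataset) != 46)
    stop("pipeline expects a 46-marker corpus")
  body <- buildBodyGraph(loadMarkerSet("plug_in_gait_39"))
  graphs <- list(with_racket = attachRacket(body), without_racket = body)
  results <- list()
  for (cond in conditions) {
    set <- if (cond == "with_racket") dataset else stripRacket(dataset)
    message("condition ", cond, ": M = ", nMarkers(graphs[[cond]]))
    results[[cond]] <- repeatedRuns(set, graphs[[cond]], k = k,
                                    hyper = hyper, seed = seed)
  }
  comparison <- if (length(conditions) == 2)
    compareConditions(results$without_racket$accuracies,
                      results$with_racket$accuracies)
  else NULL
  out <- list(results = results, comparison = comparison, graphs = graphs,
              seed = seed, k = k)
  if (!is.null(outDir)) writeReportBundle(out, outDir, hyper, synth)
  out
}

writeReportBundle <- function(out, outDir, hyper, synth) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(out$results)) {
    res <- out$results[[cond]]
    write.csv(res$summary, file.path(outDir, paste0("summary_", cond, ".csv")),
              row.names = FALSE)
    # mean confusion over runs, counts and row-percent
    cms <- lapply(res$perRun, `[[`, "confusion")
    cm <- Reduce(`+`, cms) / length(cms)
    write.csv(cm, file.path(outDir, paste0("confusion_counts_", cond, ".csv")))
    pct <- sweep(cm, 1, pmax(rowSums(cm), 1), `/`) * 100
    write.csv(round(pct, 2),
              file.path(outDir, paste0("confusion_percent_", cond, ".csv")))
    log <- lapply(res$perRun, function(r)
      list(seed = r$seed, accuracy = r$accuracy, bestEpoch = r$bestEpoch))
    writeLines(vapply(log, jsonlite::toJSON, character(1), auto_unbox = TRUE),
               file.path(outDir, paste0("runs_", cond, ".jsonl")))
  }
  if (!is.null(out$comparison))
    jsonlite::write_json(out$comparison,
                         file.path(outDir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  meta <- list(seed = out$seed, k = out$k,
               hyper = hyper[setdiff(names(hyper), "model")],
               model = hyper$model, synth = synth)
  jsonlite::write_json(meta, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
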