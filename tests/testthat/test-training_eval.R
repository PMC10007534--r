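test_that("stratified splits follow the floor rule and conserve trials", {
  set.seed(41)
  cfg <- synthConfig(counts = c(10L, 7L, 5L, 12L), noiseSd = 0,
                     durationRange = c(10L, 12L))
  ds <- generateDataset(cfg)
  sp <- stratifiedSplit(ds, splitSpec(seed = 5))
  lab <- function(s) vapply(trials(s), classId, integer(1))
  # class with 10 trials -> (6, 2, 2); 7 -> (4, 1, 2); 5 -> (3, 1, 1)
  expect_equal(sum(lab(sp$train) == 0), 6)
  expect_equal(sum(lab(sp$val) == 0), 2)
  expect_equal(sum(lab(sp$test) == 0), 2)
  expect_equal(sum(lab(sp$train) == 1), 4)
  expect_equal(sum(lab(sp$val) == 1), 1)
  expect_equal(sum(lab(sp$test) == 1), 2)
  expect_equal(sum(lab(sp$train) == 2), 3)
  # disjoint and exhaustive: every source index appears exactly once
  src <- function(s) vapply(trials(s), function(t) paste(
    classId(t), t@subjectId, nFrames(t), sum(t@coords)), character(1))
  all3 <- c(src(sp$train), src(sp$val), src(sp$test))
  expect_equal(sort(all3), sort(src(ds)))
  # determinism
  sp2 <- stratifiedSplit(ds, splitSpec(seed = 5))
  expect_identical(src(sp2$train), src(sp$train))
  # too-small class
  tiny <- generateDataset(synthConfig(counts = c(2L, 3L, 3L, 3L),
                                      durationRange = c(10L, 10L)))
  expect_error(stratifiedSplit(tiny), "at least 3")
  expect_error(splitSpec(c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("confusion counts match a hand count on fixed predictions", {
  truth <- c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L)
  pred  <- c(0L, 1L, 1L, 1L, 2L, 3L, 3L, 0L)
  cm <- confusionCounts(truth, pred)
  expect_equal(sum(cm), 8)
  hand <- matrix(0L, 4, 4)
  hand[1, 1] <- 1L; hand[1, 2] <- 1L; hand[2, 2] <- 2L
  hand[3, 3] <- 1L; hand[3, 4] <- 1L; hand[4, 4] <- 1L; hand[4, 1] <- 1L
  expect_equal(unname(cm), hand)
})

test_that("metrics match the definitional arithmetic", {
  # perfect predictor
  perfect <- diag(c(5L, 7L, 3L, 4L))
  m <- classMetrics(perfect)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$perClass$precision == 1 & m$perClass$recall == 1 &
                  m$perClass$f1 == 1 & m$perClass$ovrAccuracy == 1))
  # TP = 9, FN = 1, FP = 1 for class 1 -> P = R = F1 = 0.9
  cm <- matrix(0L, 4, 4)
  cm[1, 1] <- 9L; cm[1, 2] <- 1L; cm[2, 1] <- 1L; cm[2, 2] <- 9L
  m <- suppressWarnings(classMetrics(cm))  # empty volley rows warn 0/0
  expect_equal(m$perClass$precision[1], 0.9)
  expect_equal(m$perClass$recall[1], 0.9)
  expect_equal(m$perClass$f1[1], 0.9)   # P == R implies F1 == P
  expect_error(classMetrics(matrix(0L, 4, 4)), "empty")
  # all mass in one predicted column: undefined precision elsewhere -> 0
  onecol <- matrix(0L, 4, 4); onecol[, 1] <- 3L
  w <- capture_warnings(m1 <- classMetrics(onecol))
  expect_true(any(grepl("undefined precision", w)))
  expect_equal(m1$perClass$precision[2:4], rep(0, 3))
})

test_that("metrics agree with an independent counting oracle on random matrices", {
  set.seed(42)
  for (rep in 1:1000) {
    truth <- sample(0:3, 30, replace = TRUE)
    pred <- sample(0:3, 30, replace = TRUE)
    cm <- confusionCounts(truth, pred)
    m <- suppressWarnings(classMetrics(cm))
    expect_identical(sum(cm), 30L)
    expect_equal(m$accuracy, mean(truth == pred))
    for (c in 0:3) {
      tp <- sum(truth == c & pred == c)
      fp <- sum(truth != c & pred == c)
      fn <- sum(truth == c & pred != c)
      P <- if (tp + fp == 0) 0 else tp / (tp + fp)
      R <- if (tp + fn == 0) 0 else tp / (tp + fn)
      expect_equal(m$perClass$precision[c + 1], P)
      expect_equal(m$perClass$recall[c + 1], R)
      expect_equal(m$perClass$f1[c + 1],
                   if (P + R == 0) 0 else 2 * P * R / (P + R))
      expect_equal(m$perClass$ovrAccuracy[c + 1],
                   mean((truth == c) == (pred == c)))
    }
  }
})

test_that("entry-wise RMSE matches its closed forms", {
  # a uniform predictor on 4 classes: MSE = (0.75^2 + 3 * 0.25^2) / 4
  n <- 12
  probs <- matrix(0.25, n, 4)
  labs <- rep(0:3, 3)
  r <- rmseFromRecords(labs, probs)
  expect_equal(r$rmse, sqrt(0.1875), tolerance = 1e-12)  # ~0.4330
  expect_equal(r$sdRmse, 0)
  # a perfect predictor
  P <- matrix(0, n, 4); P[cbind(1:n, labs + 1)] <- 1
  expect_equal(rmseFromRecords(labs, P)$rmse, 0)
  expect_gte(rmseFromRecords(labs, (P + 0.25) / 2)$rmse, 0)
})

test_that("the condition comparison is a signed Welch test", {
  a <- c(0.8, 0.82, 0.78, 0.81)
  expect_equal(compareConditions(a, a)$t, 0)
  b <- a + 0.05
  cab <- compareConditions(a, b)
  cba <- compareConditions(b, a)
  expect_equal(cab$t, -cba$t)
  expect_lt(cab$t, 0)                      # sign convention a - b
  expect_equal(cab$p, cba$p)
  # summary-matched samples reproducing the published group summaries
  # (means 82.60 / 88.95, sd 2.08 / 2.62, n = 20 each): Welch t ~ -8.489
  mkSample <- function(mu, s, n, seed) {
    set.seed(seed); z <- rnorm(n); z <- (z - mean(z)) / sd(z); mu + s * z
  }
  x <- mkSample(82.60, 2.08, 20, 1)
  y <- mkSample(88.95, 2.62, 20, 2)
  cw <- compareConditions(x, y)
  expect_equal(cw$t, -8.489, tolerance = 1e-3)
  # degenerate: zero variance in both samples is reported, not fatal
  z <- rep(0.9, 3)
  expect_equal(compareConditions(z, z)$p, 1)
  deg <- compareConditions(z, z + 0.1)
  expect_equal(deg$t, -Inf)
  expect_equal(deg$p, 0)
  expect_match(deg$note, "zero variance")
  expect_error(compareConditions(0.5, c(0.4, 0.6)), "at least 2")
})

test_that("training is reproducible and tracks the best checkpoint", {
  cfg <- synthConfig(counts = rep(5L, 4), noiseSd = 0,
                     durationRange = c(10L, 14L), amplitudeJitterSd = 0)
  ds <- generateDataset(cfg)
  sp <- stratifiedSplit(ds, splitSpec(seed = 3))
  h <- smallTrainConfig(epochs = 3L, patience = Inf, seed = 5L)
  f1 <- trainModel(sp$train, sp$val, fullGraph(), h)
  f2 <- trainModel(sp$train, sp$val, fullGraph(), h)
  expect_identical(strokegcn:::flattenParams(f1$model),
                   strokegcn:::flattenParams(f2$model))
  expect_identical(f1$curves, f2$curves)
  # checkpoint = epoch with minimal validation loss
  expect_equal(f1$bestEpoch, which.min(f1$curves$valLoss))
  # evaluation returns a complete confusion matrix
  ev <- evaluateModel(f1, sp$test, fullGraph(), hyper = h)
  expect_equal(sum(ev$confusion), length(sp$test))
  expect_equal(nrow(ev$predictions), length(sp$test))
  expect_equal(rowSums(as.matrix(ev$predictions[, 3:6])), rep(1, length(sp$test)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("repeated runs summarize metrics over independent cycles", {
  cfg <- synthConfig(counts = rep(5L, 4), noiseSd = 0,
                     durationRange = c(10L, 14L), amplitudeJitterSd = 0)
  ds <- generateDataset(cfg)
  h <- smallTrainConfig(epochs = 2L, patience = Inf)
  res <- suppressWarnings(repeatedRuns(ds, fullGraph(), k = 2L, hyper = h,
                                       seed = 17L))
  expect_equal(length(res$accuracies), 2)
  ov <- res$summary[res$summary$class == "overall", ]
  expect_true(ov$min <= ov$mean && ov$mean <= ov$max)
  expect_gte(ov$sd, 0)
  # bit-reproducible under the same seed list
  res2 <- suppressWarnings(repeatedRuns(ds, fullGraph(), k = 2L, hyper = h,
                                        seed = 17L))
  expect_identical(res$accuracies, res2$accuracies)
  expect_identical(res$summary, res2$summary)
  expect_error(repeatedRuns(ds, fullGraph(), k = 1L), "at least 2")
  # default number of repeated runs is 20
  expect_equal(eval(formals(repeatedRuns)$k), 20L)
})

test_that("leave-one-out cross-validation records one fold per trial", {
  cfg <- synthConfig(counts = rep(2L, 4), noiseSd = 0,
                     durationRange = c(8L, 10L), amplitudeJitterSd = 0)
  ds <- generateDataset(cfg)
  h <- smallTrainConfig(epochs = 2L)
  res <- loocv(ds, fullGraph(), h)
  expect_equal(res$n, 8)
  expect_equal(nrow(res$records), 8)
  expect_gte(res$rmse, 0)
  expect_lte(res$rmse, 1)
  expect_equal(rowSums(as.matrix(res$records[, -1])), rep(1, 8),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(loocv(ds[1:3], fullGraph(), h), "at least 4")
})
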