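test_that("cross-entropy loss matches closed forms and a per-sample loop oracle", {
  oneHot <- diag(3)[c(1, 2, 3, 1), ]
  expect_lt(crossEntropyLoss(oneHot, oneHot), 1e-10)

  yT <- matrix(c(1, 0), 1, 2)
  expect_equal(crossEntropyLoss(yT, matrix(0.5, 1, 2)), log(2),
               tolerance = 1e-9)

  set.seed(9)
  m <- 20; k <- 5
  yTrue <- diag(k)[sample(k, m, replace = TRUE), ]
  raw <- matrix(stats::runif(m * k), m, k)
  yPred <- raw / rowSums(raw)
  loop <- 0
  for (i in seq_len(m)) {
    for (c in seq_len(k))
      loop <- loop - yTrue[i, c] * log(min(max(yPred[i, c], 1e-12), 1))
  }
  expect_equal(crossEntropyLoss(yTrue, yPred), loop / m, tolerance = 1e-9)

  expect_error(crossEntropyLoss(yTrue, yPred[, 1:3]), "dimensions")
  expect_error(crossEntropyLoss(yTrue, raw), "sum to 1")
})

test_that("confusion counts match enumeration on canonical and random cases", {
  yt <- rep(1:3, each = 10)
  conf <- confusionCounts(yt, yt, 3)
  expect_equal(conf$TP, rep(10L, 3))
  expect_equal(conf$FP, rep(0L, 3))
  expect_equal(conf$FN, rep(0L, 3))
  expect_equal(conf$TN, rep(20L, 3))

  ytb <- rep(1:2, each = 10)
  confb <- confusionCounts(ytb, rep(1L, 20), 2)
  expect_equal(unlist(confb[1, 2:5]), c(TP = 10L, FP = 10L, TN = 0L, FN = 0L))

  set.seed(4)
  yt2 <- sample(4, 60, replace = TRUE)
  yp2 <- sample(4, 60, replace = TRUE)
  conf2 <- confusionCounts(yt2, yp2, 4)
  for (c in 1:4) {
    # exhaustive pairwise-count oracle
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_along(yt2)) {
      if (yt2[i] == c && yp2[i] == c) tp <- tp + 1
      else if (yt2[i] == c) fn <- fn + 1
      else if (yp2[i] == c) fp <- fp + 1
      else tn <- tn + 1
    }
    expect_equal(unlist(conf2[c, 2:5]), c(TP = tp, FP = fp, TN = tn, FN = fn))
  }
  expect_equal(rowSums(conf2[, 2:5]), rep(60, 4))
})

test_that("metric formulas give their textbook values", {
  conf <- data.frame(class = 1L, TP = 9L, FP = 3L, TN = 97L, FN = 1L)
  r <- evalMetrics(conf)
  expect_equal(perClassMetrics(r)$sensitivity, 0.9)
  expect_equal(perClassMetrics(r)$specificity, 0.97)

  confEq <- data.frame(class = 1L, TP = 9L, FP = 1L, TN = 89L, FN = 1L)
  rEq <- evalMetrics(confEq)
  expect_equal(perClassMetrics(rEq)$precision, 0.9)
  expect_equal(perClassMetrics(rEq)$f1, 0.9)   # harmonic mean of equal values

  degenerate <- data.frame(class = 1L, TP = 0L, FP = 0L, TN = 10L, FN = 0L)
  expect_warning(r0 <- evalMetrics(degenerate), "zero denominator")
  expect_equal(perClassMetrics(r0)$sensitivity, 0)
})

test_that("metric suite equals a brute-force enumeration oracle on random prediction sets", {
  set.seed(12)
  for (rep in 1:100) {
    k <- sample(2:5, 1)
    m <- sample(10:40, 1)
    yt <- sample(k, m, replace = TRUE)
    if (length(unique(yt)) < 2) next
    yp <- sample(k, m, replace = TRUE)
    r <- suppressWarnings(evalMetrics(confusionCounts(yt, yp, k)))
    sens <- spec <- numeric(k)
    for (c in seq_len(k)) {
      tp <- sum(yt == c & yp == c); fn <- sum(yt == c & yp != c)
      fp <- sum(yt != c & yp == c); tn <- m - tp - fn - fp
      sens[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
      spec[c] <- if (tn + fp > 0) tn / (tn + fp) else 0
    }
    expect_equal(unname(macroMetrics(r)["sensitivity"]), mean(sens))
    expect_equal(unname(macroMetrics(r)["specificity"]), mean(spec))
    expect_equal(unname(macroMetrics(r)["accuracy"]), mean(yt == yp))
  }
})

test_that("ROC AUC matches the Mann-Whitney pair-counting oracle", {
  # perfectly separated scores
  scores <- cbind(c(rep(0.9, 5), rep(0.1, 5)), c(rep(0.1, 5), rep(0.9, 5)))
  expect_equal(rocAUC(scores, rep(1:2, each = 5)), 1.0)

  # constant scores are chance
  expect_equal(rocAUC(matrix(0.5, 10, 2), rep(1:2, each = 5)), 0.5)

  set.seed(3)
  for (rep in 1:20) {
    m <- 20
    yt <- sample(2, m, replace = TRUE)
    if (length(unique(yt)) < 2) next
    s <- round(stats::runif(m), 1)   # coarse grid forces ties
    scores <- cbind(s, 1 - s)
    got <- rocAUC(scores, yt)
    pairAUC <- function(sPos, sNeg) {
      tot <- 0
      for (p in sPos) for (n in sNeg)
        tot <- tot + (p > n) + 0.5 * (p == n)
      tot / (length(sPos) * length(sNeg))
    }
    want <- mean(c(pairAUC(s[yt == 1], s[yt == 1 + 1]),
                   pairAUC(1 - s[yt == 2], 1 - s[yt == 1])))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  yt <- sample(2, 40, replace = TRUE)
  s <- stats::runif(40)
  ours <- rocAUC(cbind(s, 1 - s), yt)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(yt == 1), predictor = s, direction = "<",
    levels = c(FALSE, TRUE))))
  # class 2 uses the complementary score; both one-vs-rest AUCs are equal here
  expect_equal(ours, as.numeric(ref), tolerance = 1e-9)
})

test_that("grouped stratified folding partitions records without leakage", {
  subjects <- rep(c("a", "b"), each = 20)
  records <- paste0(subjects, rep(rep(1:5, each = 4), 2))
  fold <- ppgbioid:::groupedStratifiedFolds(subjects, records, 5, seed = 1)
  expect_equal(sort(unique(fold)), 1:5)
  # a record never straddles folds
  for (r in unique(records))
    expect_length(unique(fold[records == r]), 1)
  # stratified: each fold holds one record of each subject
  for (f in 1:5) for (s in c("a", "b"))
    expect_equal(length(unique(records[fold == f & subjects == s])), 1)
  # deterministic under the seed
  fold2 <- ppgbioid:::groupedStratifiedFolds(subjects, records, 5, seed = 1)
  expect_identical(fold, fold2)
  expect_error(ppgbioid:::groupedStratifiedFolds(subjects, records, 6),
               "stratification")
})
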