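# Synthetic image classification task for exercising the training loop:
# each class is a distinct fixed random pattern plus noise, trivially
# learnable by the tiny model.
patternSet <- function(n, nClasses = 3, side = 16, noise = 0.1, seed = 1) {
  withr_seed <- seed
  set.seed(withr_seed)
  protos <- lapply(seq_len(nClasses), function(c)
    matrix(stats::runif(side^2), side, side))
  labels <- factor(rep(seq_len(nClasses), length.out = n))
  imgs <- array(0, c(side, side, n))
  for (i in seq_len(n))
    imgs[, , i] <- pmin(pmax(protos[[as.integer(labels[i])]] +
                               matrix(stats::rnorm(side^2, 0, noise),
                                      side, side), 0), 1)
  list(images = imgs, labels = labels)
}

test_that("a zero learning rate leaves parameters untouched", {
  d <- patternSet(12)
  m <- buildModel(tinyModelConfig())
  before <- modelParameters(m)
  fit <- trainModel(m, d$images, d$labels,
                    cfg = trainConfig(learningRate = 0, maxEpochs = 2,
                                      batchSize = 6))
  expect_equal(modelParameters(fit$model), before, tolerance = 0)
})

test_that("training is deterministic in its seed and errors on empty input", {
  d <- patternSet(18)
  run <- function() {
    m <- buildModel(tinyModelConfig())
    trainModel(m, d$images, d$labels, d$images[, , 1:6], d$labels[1:6],
               trainConfig(maxEpochs = 3, batchSize = 6, seed = 11))
  }
  h1 <- run()$history
  h2 <- run()$history
  expect_identical(h1, h2)
  m <- buildModel(tinyModelConfig())
  expect_error(trainModel(m, array(0, c(16, 16, 0)), factor(character())),
               "empty")
})

test_that("one optimization step does not blow up the batch loss", {
  for (seed in 1:5) {
    d <- patternSet(8, seed = seed)
    m <- buildModel(tinyModelConfig(seed = as.integer(seed)))
    Y <- ppgbioid:::.onehot(d$labels, 3)
    l0 <- ppgbioid:::.datasetLoss(m, d$images, Y, "cross_entropy")
    fit <- trainModel(m, d$images, d$labels,
                      cfg = trainConfig(maxEpochs = 1, batchSize = 8,
                                        seed = seed))
    l1 <- ppgbioid:::.datasetLoss(fit$model, d$images, Y, "cross_entropy")
    expect_lt(l1, l0 * 1.1 + 1e-9)
  }
})

test_that("the tiny model learns a separable pattern task with both optimizers and losses", {
  d <- patternSet(36, noise = 0.05)
  acc <- function(model) {
    p <- predictProbs(model, d$images)
    mean(apply(p, 2, which.max) == as.integer(d$labels))
  }
  fitAdam <- trainModel(buildModel(tinyModelConfig()), d$images, d$labels,
                        cfg = trainConfig(maxEpochs = 12, batchSize = 12,
                                          learningRate = 3e-3, seed = 2))
  expect_gte(acc(fitAdam$model), 0.9)

  fitSgd <- trainModel(buildModel(tinyModelConfig()), d$images, d$labels,
                       cfg = trainConfig(optimizer = "sgdm", maxEpochs = 15,
                                         batchSize = 12, learningRate = 5e-3,
                                         seed = 2))
  expect_gte(acc(fitSgd$model), 2 / 3)   # slower optimizer, same trend

  fitMse <- trainModel(buildModel(tinyModelConfig()), d$images, d$labels,
                       cfg = trainConfig(loss = "mse", maxEpochs = 15,
                                         batchSize = 12, learningRate = 3e-3,
                                         seed = 2))
  expect_gte(acc(fitMse$model), 2 / 3)
})

test_that("early stopping never trains past the patience window and restores the best epoch", {
  d <- patternSet(24)
  m <- buildModel(tinyModelConfig())
  fit <- trainModel(m, d$images, d$labels, d$images[, , 1:8], d$labels[1:8],
                    trainConfig(maxEpochs = 30, batchSize = 8,
                                earlyStopPatience = 3, seed = 4))
  h <- fit$history
  best <- which.min(h$valLoss)
  expect_lte(nrow(h) - best, 3)
})

test_that("five-fold protocol arithmetic matches the 80/20 within 80/20 scheme", {
  subjects <- rep(c("a", "b"), each = 50)
  records <- paste0(subjects, rep(1:10, each = 5))
  fold <- ppgbioid:::groupedStratifiedFolds(subjects, records, 5, seed = 0)
  expect_equal(as.numeric(table(fold)), rep(20, 5))
  # union of test folds is the dataset, pairwise disjoint by construction
  expect_equal(sort(unlist(lapply(1:5, function(f) which(fold == f)))),
               seq_along(subjects))
  # the remaining 80 samples split 80/20 into train/validation at record
  # granularity (2 of each subject's 8 remaining records go to validation)
  part <- ppgbioid:::trainValTestSplit(subjects[fold != 1], records[fold != 1],
                                       testFraction = 0, valFraction = 0.2,
                                       seed = 1)
  expect_equal(sum(part == "train"), 60)
  expect_equal(sum(part == "val"), 20)
})

test_that("kfoldCV returns disjoint stratified folds with per-fold reports", {
  se <- deskCohortSE()
  sub <- SummarizedExperiment::colData(se)$subject
  keep <- sub %in% c("1", "2", "3")
  seSmall <- se[, keep]
  # shrink the images to the tiny model size by plain subsampling
  a <- SummarizedExperiment::assay(seSmall)
  side <- S4Vectors::metadata(seSmall)$imageSide
  pick <- as.vector(outer(seq(1, side, by = 4), (seq(1, side, by = 4) - 1) * side, "+"))
  seTiny <- SummarizedExperiment::SummarizedExperiment(
    assays = list(scalogram = a[pick, ]),
    colData = SummarizedExperiment::colData(seSmall))
  S4Vectors::metadata(seTiny)$imageSide <- 16L
  cv <- kfoldCV(seTiny, tinyModelConfig(),
                trainConfig(maxEpochs = 2, batchSize = 16, kFolds = 3,
                            seed = 3))
  expect_length(cv$reports, 3)
  expect_true(all(vapply(cv$reports, function(r)
    is(r, "EvalReport"), logical(1))))
  expect_equal(sort(unique(cv$folds)), 1:3)
  expect_true(all(c("accuracy", "auc") %in% cv$summary$metric))
})

test_that("rotating cross-source validation counts runs and enforces label compatibility", {
  mkSe <- function(seed, subjects = c("1", "2", "3")) {
    n <- 18
    set.seed(seed)
    labels <- rep(subjects, each = n / 3)
    imgs <- matrix(stats::runif(256 * n), 256, n)
    for (i in seq_len(n))
      imgs[, i] <- imgs[, i] / 3 +
        rep(as.integer(labels[i]) / 3, 256) * 0.5
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(scalogram = imgs),
      colData = S4Vectors::DataFrame(
        subject = labels, record = paste0(labels, "-", rep(1:6, 3)),
        startTime = 0, snrDb = 10, source = paste0("s", seed)))
    S4Vectors::metadata(se)$imageSide <- 16L
    se
  }
  sources <- list(A = mkSe(1), B = mkSe(2), C = mkSe(3))
  res <- crossDatasetValidation(
    sources, tinyModelConfig(),
    trainConfig(maxEpochs = 1, batchSize = 9, kFolds = 3, seed = 5))
  expect_equal(dim(res$matrix), c(3, 3))
  offDiag <- res$matrix[row(res$matrix) != col(res$matrix)]
  expect_length(offDiag, 6)
  expect_true(all(vapply(offDiag, function(r) is(r, "EvalReport"),
                         logical(1))))

  bad <- list(A = mkSe(1), B = mkSe(2, subjects = c("7", "8", "9")))
  expect_error(crossDatasetValidation(bad, tinyModelConfig(),
                                      trainConfig(maxEpochs = 1)),
               "label mismatch")
})
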