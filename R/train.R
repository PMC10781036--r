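#' Training configuration
#'
#' Defaults correspond to the common training setup: Adam at learning rate
#' 1e-3 with categorical cross-entropy, early stopping on validation loss
#' with a no-improvement patience, and stratified five-fold evaluation with
#' an 80/20 inner train/validation split. The desk-scale default caps
#' training at 15 epochs.
#'
#' @param optimizer `"adam"` or `"sgdm"` (momentum 0.9).
#' @param learningRate positive learning rate.
#' @param batchSize minibatch size (>= 1).
#' @param maxEpochs maximum training epochs.
#' @param earlyStopPatience epochs without validation-loss improvement before
#'   stopping.
#' @param loss `"cross_entropy"` or `"mse"` (MSE between the softmax output
#'   and the one-hot target).
#' @param kFolds folds for cross-validation.
#' @param innerValFraction fraction of the training portion held out for
#'   validation, in (0, 1).
#' @param seed integer seed controlling shuffling and dropout.
#' @return a list with class `TrainConfig`.
#' @export
trainConfig <- function(optimizer = c("adam", "sgdm"), learningRate = 1e-3,
                        batchSize = 32L, maxEpochs = 15L,
                        earlyStopPatience = 50L,
                        loss = c("cross_entropy", "mse"), kFolds = 5L,
                        innerValFraction = 0.2, seed = 0L) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  stopifnot(learningRate >= 0, batchSize >= 1,
            innerValFraction > 0, innerValFraction < 1)
  structure(list(optimizer = optimizer, learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 earlyStopPatience = as.integer(earlyStopPatience),
                 loss = loss, kFolds = as.integer(kFolds),
                 innerValFraction = innerValFraction,
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Categorical cross-entropy loss
#'
#' `mean over samples of -sum_c y_true * log(clip(y_pred, 1e-12, 1))` with
#' rows indexing samples and columns classes; `yPred` rows must sum to 1
#' within 1e-6.
#'
#' @param yTrue one-hot matrix, samples x classes.
#' @param yPred predicted probability matrix of the same shape.
#' @return scalar mean loss.
#' @export
crossEntropyLoss <- function(yTrue, yPred) {
  if (!all(dim(yTrue) == dim(yPred)))
    stop("'yTrue' and 'yPred' must have identical dimensions")
  if (any(abs(rowSums(yPred) - 1) > 1e-6))
    stop("'yPred' rows must sum to 1")
  mean(-rowSums(yTrue * log(pmin(pmax(yPred, 1e-12), 1))))
}

# One-hot matrix (classes x m) from an integer/factor label vector.
.onehot <- function(labels, nClasses) {
  li <- as.integer(labels)
  Y <- matrix(0, nClasses, length(li))
  Y[cbind(li, seq_along(li))] <- 1
  Y
}

.optimInit <- function(params, optimizer) {
  list(optimizer = optimizer, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

.optimStep <- function(model, grads, cfg) {
  st <- model@env$opt
  p <- model@env$params
  lr <- cfg$learningRate
  st$t <- st$t + 1L
  if (st$optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (k in names(p)) {
      g <- grads[[k]]
      if (is.null(g)) next
      st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g
      st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g * g
      mh <- st$m[[k]] / (1 - b1^st$t)
      vh <- st$v[[k]] / (1 - b2^st$t)
      p[[k]] <- p[[k]] - lr * mh / (sqrt(vh) + eps)
    }
  } else {  # sgd with momentum 0.9
    for (k in names(p)) {
      g <- grads[[k]]
      if (is.null(g)) next
      st$m[[k]] <- 0.9 * st$m[[k]] + g
      p[[k]] <- p[[k]] - lr * st$m[[k]]
    }
  }
  model@env$params <- p
  model@env$opt <- st
  invisible(model)
}

.batchLossNode <- function(model, images, Y, lossMode, training) {
  fw <- .forward(model, images, training = training)
  loss <- if (lossMode == "cross_entropy")
    ndSoftmaxCrossEntropy(fw$logits, Y)
  else ndMSE(ndSoftmax(fw$logits), Y)
  list(fw = fw, loss = loss)
}

.datasetLoss <- function(model, images, Y, lossMode, chunk = 64L) {
  N <- dim(images)[3]
  tot <- 0
  for (s in seq(1L, N, by = chunk)) {
    e <- min(N, s + chunk - 1L)
    bl <- .batchLossNode(model, images[, , s:e, drop = FALSE],
                         Y[, s:e, drop = FALSE], lossMode, training = FALSE)
    tot <- tot + ndValue(bl$loss) * (e - s + 1L)
  }
  tot / N
}

#' Train the hybrid model
#'
#' Minibatch optimization of the configured loss with Adam or SGD-momentum.
#' After every epoch the validation loss is recorded; training stops at
#' `maxEpochs` or once the validation loss has not improved for
#' `earlyStopPatience` epochs, and the parameters of the best validation
#' epoch are restored. Fully deterministic in `cfg$seed`.
#'
#' @param model a [HybridModel-class] (modified in place and returned).
#' @param trainImages `(side, side, N)` array of training images.
#' @param trainLabels factor of training labels (levels = classes).
#' @param valImages,valLabels optional validation set (NULL disables early
#'   stopping).
#' @param cfg a [trainConfig()].
#' @return list with `model` and `history` (data.frame of epoch, train and
#'   validation loss, validation accuracy).
#' @export
trainModel <- function(model, trainImages, trainLabels,
                       valImages = NULL, valLabels = NULL,
                       cfg = trainConfig()) {
  N <- dim(trainImages)[3]
  if (is.null(N) || N < 1) stop("empty training set")
  if (N != length(trainLabels))
    stop("label count does not match the image count")
  nC <- model@config$nClasses
  if (nlevels(factor(trainLabels)) > nC)
    stop("more classes in the labels than the model was built for")
  trainLabels <- factor(trainLabels)
  Ytr <- .onehot(trainLabels, nC)
  hasVal <- !is.null(valImages)
  if (hasVal) {
    valLabels <- factor(valLabels, levels = levels(trainLabels))
    Yval <- .onehot(valLabels, nC)
  }
  if (is.null(model@env$opt))
    model@env$opt <- .optimInit(model@env$params, cfg$optimizer)
  best <- list(loss = Inf, params = NULL, bn = NULL, epoch = 0L)
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric(), valAccuracy = numeric())
  for (epoch in seq_len(cfg$maxEpochs)) {
    epochLoss <- 0; seen <- 0L
    withSeed(childSeed(cfg$seed, "epoch", epoch), {
      ord <- sample.int(N)
      for (s in seq(1L, N, by = cfg$batchSize)) {
        sel <- ord[s:min(N, s + cfg$batchSize - 1L)]
        bl <- .batchLossNode(model, trainImages[, , sel, drop = FALSE],
                             Ytr[, sel, drop = FALSE], cfg$loss,
                             training = TRUE)
        ndBackward(bl$loss)
        grads <- lapply(bl$fw$params, function(n) n$grad)
        if (!isTRUE(model@config$alphaLearnable)) grads$fuse_alpha <- NULL
        .optimStep(model, grads, cfg)
        epochLoss <- epochLoss + ndValue(bl$loss) * length(sel)
        seen <- seen + length(sel)
      }
    })
    trLoss <- epochLoss / seen
    if (hasVal) {
      vLoss <- .datasetLoss(model, valImages, Yval, cfg$loss)
      probs <- predictProbs(model, valImages)
      vAcc <- mean(apply(probs, 2, which.max) == as.integer(valLabels))
    } else { vLoss <- NA_real_; vAcc <- NA_real_ }
    hist <- rbind(hist, data.frame(epoch = epoch, trainLoss = trLoss,
                                   valLoss = vLoss, valAccuracy = vAcc))
    if (hasVal) {
      if (vLoss < best$loss - 1e-12) {
        best <- list(loss = vLoss, params = model@env$params,
                     bn = .copyBn(model@env$bn), epoch = epoch)
      } else if (epoch - best$epoch >= cfg$earlyStopPatience) break
    }
  }
  if (hasVal && !is.null(best$params)) {
    model@env$params <- best$params
    model@env$bn <- best$bn
  }
  list(model = model, history = hist)
}

.copyBn <- function(bn) {
  out <- new.env(parent = emptyenv())
  for (k in ls(bn)) {
    e <- new.env(parent = emptyenv())
    e$mean <- bn[[k]]$mean; e$var <- bn[[k]]$var
    out[[k]] <- e
  }
  out
}

#' Per-class one-vs-rest confusion counts
#'
#' For each class `c`: `TP` = samples of class `c` predicted `c`; `FN` =
#' samples of class `c` predicted otherwise; `FP` = other samples predicted
#' `c`; `TN` = the remainder. `TP + FP + TN + FN = m` for every class.
#'
#' @param yTrue,yPred integer or factor label vectors of equal length.
#' @param nClasses number of classes (defaults to the maximum label).
#' @return data.frame with columns class, TP, FP, TN, FN.
#' @export
confusionCounts <- function(yTrue, yPred, nClasses = max(as.integer(yTrue))) {
  yt <- as.integer(yTrue); yp <- as.integer(yPred)
  stopifnot(length(yt) == length(yp))
  m <- length(yt)
  out <- data.frame(class = seq_len(nClasses), TP = 0L, FP = 0L,
                    TN = 0L, FN = 0L)
  for (c in seq_len(nClasses)) {
    tp <- sum(yt == c & yp == c)
    fn <- sum(yt == c & yp != c)
    fp <- sum(yt != c & yp == c)
    out[c, 2:5] <- c(tp, fp, m - tp - fn - fp, fn)
  }
  out
}

.safeRatio <- function(num, den, what) {
  bad <- den == 0
  if (any(bad))
    warning(sprintf("zero denominator in %s for %d class(es); reporting 0",
                    what, sum(bad)), call. = FALSE)
  ifelse(bad, 0, num / den)
}

#' Metric suite from confusion counts
#'
#' Sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, F1 (harmonic mean of precision and recall), and per-class
#' accuracy `(TP+TN)/m`, plus unweighted macro averages. Zero denominators
#' yield 0 with a warning.
#'
#' @param conf data.frame from [confusionCounts()].
#' @param auc optional macro AUC to embed in the report.
#' @param loss optional mean loss to embed in the report.
#' @return an [EvalReport-class].
#' @export
evalMetrics <- function(conf, auc = NA_real_, loss = NA_real_) {
  m <- conf$TP + conf$FP + conf$TN + conf$FN
  sens <- .safeRatio(conf$TP, conf$TP + conf$FN, "sensitivity")
  spec <- .safeRatio(conf$TN, conf$TN + conf$FP, "specificity")
  prec <- .safeRatio(conf$TP, conf$TP + conf$FP, "precision")
  f1 <- .safeRatio(2 * prec * sens, prec + sens, "F1")
  acc <- (conf$TP + conf$TN) / m
  perClass <- data.frame(class = conf$class, sensitivity = sens,
                         specificity = spec, precision = prec, recall = sens,
                         f1 = f1, accuracy = acc)
  overallAcc <- sum(conf$TP) / m[1]
  macro <- c(sensitivity = mean(sens), specificity = mean(spec),
             precision = mean(prec), recall = mean(sens), f1 = mean(f1),
             accuracy = overallAcc)
  new("EvalReport", confusion = conf, perClass = perClass, macro = macro,
      auc = auc, loss = loss)
}

#' Macro one-vs-rest ROC AUC
#'
#' For each class the ROC curve is traced by sweeping a threshold over the
#' unique predicted scores (samples with tied scores enter together, which
#' averages over tied orderings) and integrated by the trapezoidal rule;
#' classes lacking both positives and negatives are skipped. The macro AUC is
#' the unweighted mean.
#'
#' @param scores samples x classes matrix of class scores/probabilities.
#' @param yTrue integer or factor label vector (values index the columns).
#' @return macro-averaged AUC in \[0, 1\].
#' @export
rocAUC <- function(scores, yTrue) {
  yt <- as.integer(yTrue)
  scores <- as.matrix(scores)
  aucs <- c()
  for (c in seq_len(ncol(scores))) {
    pos <- yt == c
    if (!any(pos) || all(pos)) next
    s <- scores[, c]
    th <- c(Inf, sort(unique(s), decreasing = TRUE))
    tpr <- vapply(th, function(t) mean(s[pos] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(s[!pos] >= t), numeric(1))
    aucs <- c(aucs, sum(diff(fpr) *
                          (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2))
  }
  if (!length(aucs)) return(NA_real_)
  mean(aucs)
}

#' Evaluate a trained model on labeled images
#'
#' @param model a [HybridModel-class].
#' @param images `(side, side, N)` image array.
#' @param labels factor of true labels (its levels define the class order).
#' @param lossMode `"cross_entropy"` or `"mse"`.
#' @return an [EvalReport-class] with confusion counts, metric suite, macro
#'   AUC and mean loss.
#' @export
evaluateModel <- function(model, images, labels,
                          lossMode = "cross_entropy") {
  labels <- factor(labels)
  nC <- model@config$nClasses
  probs <- predictProbs(model, images)
  pred <- apply(probs, 2, which.max)   # ties resolve to the lowest index
  conf <- confusionCounts(as.integer(labels), pred, nC)
  auc <- rocAUC(t(probs), as.integer(labels))
  Y <- .onehot(labels, nC)
  loss <- if (lossMode == "cross_entropy") crossEntropyLoss(t(Y), t(probs))
  else mean((probs - Y)^2)
  evalMetrics(conf, auc = auc, loss = loss)
}

# ---- splitting protocols ----

# Deal the records (grouping units) of every class round-robin into k folds,
# in seeded shuffled order: stratified by class, grouped by record.
groupedStratifiedFolds <- function(subjects, records, k, seed = 0L) {
  stopifnot(length(subjects) == length(records))
  recTab <- unique(data.frame(subject = subjects, record = records,
                              stringsAsFactors = FALSE))
  if (any(table(recTab$subject) < k))
    stop(sprintf(
      "stratification error: some class has fewer than %d records", k))
  fold <- integer(length(records))
  withSeed(childSeed(seed, "folds"), {
    for (s in unique(recTab$subject)) {
      recs <- sample(recTab$record[recTab$subject == s])
      for (i in seq_along(recs))
        fold[records == recs[i]] <- ((i - 1L) %% k) + 1L
    }
  })
  fold
}

# Group-stratified train/validation/test split (fractions of records).
trainValTestSplit <- function(subjects, records, testFraction = 0.2,
                              valFraction = 0.2, seed = 0L) {
  part <- character(length(records))
  withSeed(childSeed(seed, "split"), {
    recTab <- unique(data.frame(subject = subjects, record = records,
                                stringsAsFactors = FALSE))
    for (s in unique(recTab$subject)) {
      recs <- sample(recTab$record[recTab$subject == s])
      nR <- length(recs)
      nTest <- if (testFraction <= 0) 0L else max(1L, round(testFraction * nR))
      nVal <- if (valFraction <= 0) 0L else
        max(1L, round(valFraction * (nR - nTest)))
      grp <- c(rep("test", nTest), rep("val", nVal),
               rep("train", nR - nTest - nVal))
      for (i in seq_along(recs)) part[records == recs[i]] <- grp[i]
    }
  })
  part
}

.seImages <- function(se) {
  side <- S4Vectors::metadata(se)$imageSide
  a <- SummarizedExperiment::assay(se, "scalogram")
  array(as.numeric(a), c(side, side, ncol(a)))
}

#' Stratified, subject-grouped k-fold cross-validation
#'
#' Each cycle holds out one fold as the test set; the remainder is split
#' (by record) into training and validation using `innerValFraction`. Records
#' are the grouping unit, so segments cut from the same record never straddle
#' training and test. Folds are stratified by subject. A class with fewer
#' records than `k` raises a stratification error.
#'
#' @param se a [scalogramExperiment()] SummarizedExperiment.
#' @param modelCfg a [modelConfig()].
#' @param trainCfg a [trainConfig()].
#' @return list with per-fold `reports` (EvalReport), `folds` assignment,
#'   and `summary` (mean and sd of the macro metrics and AUC across folds).
#' @export
kfoldCV <- function(se, modelCfg = modelConfig(), trainCfg = trainConfig()) {
  cd <- SummarizedExperiment::colData(se)
  labels <- factor(cd$subject)
  imgs <- .seImages(se)
  k <- trainCfg$kFolds
  fold <- groupedStratifiedFolds(as.character(labels), cd$record, k,
                                 seed = trainCfg$seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- which(fold == f)
    restIdx <- which(fold != f)
    part <- trainValTestSplit(as.character(labels)[restIdx],
                              cd$record[restIdx], testFraction = 0,
                              valFraction = trainCfg$innerValFraction,
                              seed = childSeed(trainCfg$seed, "inner", f))
    trIdx <- restIdx[part == "train"]
    vaIdx <- restIdx[part == "val"]
    mcfg <- modelCfg
    mcfg$nClasses <- nlevels(labels)
    mcfg$seed <- childSeed(trainCfg$seed, "model", f)
    model <- buildModel(mcfg)
    fit <- trainModel(model, imgs[, , trIdx, drop = FALSE], labels[trIdx],
                      imgs[, , vaIdx, drop = FALSE], labels[vaIdx],
                      trainCfg)
    reports[[f]] <- evaluateModel(fit$model, imgs[, , testIdx, drop = FALSE],
                                  labels[testIdx], trainCfg$loss)
  }
  mm <- t(vapply(reports, function(r) c(r@macro, auc = r@auc),
                 numeric(length(reports[[1]]@macro) + 1L)))
  list(reports = reports, folds = fold,
       summary = data.frame(metric = colnames(mm), mean = colMeans(mm),
                            sd = apply(mm, 2, stats::sd)))
}

#' Rotating cross-source validation
#'
#' For each source, a model is trained on that source (with an inner
#' validation split) and evaluated on every other source; the diagonal holds
#' the within-source k-fold summary. All sources must share the same label
#' set for identification; disjoint label sets raise an error unless
#' `verificationMode = TRUE`, in which case each evaluation reports the
#' one-vs-rest genuine/imposter AUC over the trained identities instead.
#'
#' @param seBySource named list of [scalogramExperiment()] objects.
#' @param modelCfg a [modelConfig()].
#' @param trainCfg a [trainConfig()].
#' @param verificationMode evaluate genuine/imposter verification instead of
#'   closed-set identification.
#' @return list with the report `matrix` (lists indexed
#'   `[train source][test source]`) and the trained `models`.
#' @export
crossDatasetValidation <- function(seBySource, modelCfg = modelConfig(),
                                   trainCfg = trainConfig(),
                                   verificationMode = FALSE) {
  srcs <- names(seBySource)
  stopifnot(length(srcs) >= 2L)
  labelSets <- lapply(seBySource, function(se)
    sort(unique(SummarizedExperiment::colData(se)$subject)))
  if (!verificationMode) {
    for (i in seq_along(srcs)) for (j in seq_along(srcs))
      if (!setequal(labelSets[[i]], labelSets[[j]]))
        stop("label mismatch between sources '", srcs[i], "' and '", srcs[j],
             "': identification requires a shared identity set ",
             "(use verificationMode for open-set evaluation)")
  }
  levelsAll <- sort(unique(unlist(labelSets)))
  out <- matrix(list(), length(srcs), length(srcs),
                dimnames = list(train = srcs, test = srcs))
  models <- list()
  for (i in seq_along(srcs)) {
    se <- seBySource[[i]]
    cd <- SummarizedExperiment::colData(se)
    labels <- factor(cd$subject, levels = levelsAll)
    imgs <- .seImages(se)
    part <- trainValTestSplit(as.character(labels), cd$record,
                              testFraction = 0,
                              valFraction = trainCfg$innerValFraction,
                              seed = childSeed(trainCfg$seed, "xsrc", i))
    mcfg <- modelCfg
    mcfg$nClasses <- length(levelsAll)
    mcfg$seed <- childSeed(trainCfg$seed, "xsrc-model", i)
    model <- buildModel(mcfg)
    fit <- trainModel(model, imgs[, , part == "train", drop = FALSE],
                      labels[part == "train"],
                      imgs[, , part == "val", drop = FALSE],
                      labels[part == "val"], trainCfg)
    models[[srcs[i]]] <- fit$model
    out[[i, i]] <- kfoldCV(se, modelCfg, trainCfg)$summary
    for (j in seq_along(srcs)) {
      if (j == i) next
      seT <- seBySource[[j]]
      imgsT <- .seImages(seT)
      labT <- factor(SummarizedExperiment::colData(seT)$subject,
                     levels = levelsAll)
      if (verificationMode) {
        probs <- predictProbs(fit$model, imgsT)
        aucs <- c()
        for (cls in which(levelsAll %in% labelSets[[i]])) {
          genuine <- as.integer(labT) == cls
          if (!any(genuine) || all(genuine)) next
          aucs <- c(aucs, rocAUC(cbind(probs[cls, ], 1 - probs[cls, ]),
                                 ifelse(genuine, 1L, 2L)))
        }
        out[[i, j]] <- list(verificationAUC = mean(aucs))
      } else {
        out[[i, j]] <- evaluateModel(fit$model, imgsT, labT, trainCfg$loss)
      }
    }
  }
  list(matrix = out, models = models)
}
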