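#' Run the full identification pipeline
#'
#' Simulate a labeled cohort, preprocess every record, build scalogram
#' images, split record-grouped and subject-stratified into
#' train/validation/test, train the hybrid classifier and evaluate on the
#' held-out test records. All randomness derives from `cfg$seed`, so two
#' runs with the same configuration produce byte-identical reports.
#'
#' @param cfg a `RunConfig` (see [defaultRunConfig()]).
#' @param outDir output directory (NULL to skip writing files). When set,
#'   the evaluation report (JSON), the training history, the segment
#'   manifest and sample scalogram PNGs are written there.
#' @param verbose print stage progress with timings.
#' @return list with `report` (named metric list), `evalReport`
#'   ([EvalReport-class]), `history`, `model` and `se` (the scalogram
#'   SummarizedExperiment).
#' @export
runPipeline <- function(cfg = defaultRunConfig(), outDir = NULL,
                        verbose = TRUE) {
  problems <- validateRunConfig(cfg)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  say <- function(...) if (verbose)
    message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...))
  t0 <- proc.time()[3]

  sim <- cfg$simulate
  noise <- do.call(noiseConfig, sim$noise)
  say("simulate: %d identities x %d records (%g s @ %g Hz)",
      sim$nIdentities, sim$recordsPerIdentity, sim$durationS, sim$fs)
  cohort <- synthCohort(sim$nIdentities, sim$recordsPerIdentity,
                        sim$durationS, sim$fs, noise, seed = cfg$seed)

  ppCfg <- structure(cfg$preprocess, class = "PreprocessConfig")
  say("preprocess: %d records", length(cohort))
  segs <- list(); recIds <- character()
  for (i in seq_along(cohort)) {
    s <- preprocessRecord(cohort[[i]], ppCfg)
    segs <- c(segs, s)
    recIds <- c(recIds, rep(sprintf("rec%03d", i), length(s)))
  }
  say("preprocess: %d segments survived screening", length(segs))
  if (!length(segs)) stop("no segments survived quality screening")

  scCfg <- structure(cfg$scalogram, class = "ScalogramConfig")
  say("scalogram: %d images (%d x %d)", length(segs), scCfg$imageSide,
      scCfg$imageSide)
  se <- scalogramExperiment(segs, recIds, source = "synthetic", cfg = scCfg)

  cd <- SummarizedExperiment::colData(se)
  labels <- factor(cd$subject)
  part <- trainValTestSplit(as.character(labels), cd$record,
                            testFraction = 0.2,
                            valFraction = cfg$train$innerValFraction,
                            seed = cfg$seed)
  imgs <- .seImages(se)
  mCfg <- structure(cfg$model, class = "ModelConfig")
  mCfg$nClasses <- nlevels(labels)
  mCfg$seed <- childSeed(cfg$seed, "model")
  tCfg <- structure(cfg$train, class = "TrainConfig")
  tCfg$seed <- childSeed(cfg$seed, "train")
  model <- buildModel(mCfg)
  say("train: %s parameters, %d train / %d val / %d test segments",
      format(parameterCount(model), big.mark = ","),
      sum(part == "train"), sum(part == "val"), sum(part == "test"))
  fit <- trainModel(model, imgs[, , part == "train", drop = FALSE],
                    labels[part == "train"],
                    imgs[, , part == "val", drop = FALSE],
                    labels[part == "val"], tCfg)
  say("evaluate: held-out test records")
  ev <- evaluateModel(fit$model, imgs[, , part == "test", drop = FALSE],
                      labels[part == "test"], tCfg$loss)
  report <- list(
    profile = cfg$profile, seed = cfg$seed,
    nIdentities = sim$nIdentities, nSegments = length(segs),
    nTrain = sum(part == "train"), nVal = sum(part == "val"),
    nTest = sum(part == "test"),
    accuracy = unname(ev@macro["accuracy"]),
    sensitivity = unname(ev@macro["sensitivity"]),
    specificity = unname(ev@macro["specificity"]),
    f1 = unname(ev@macro["f1"]),
    auc = ev@auc, loss = ev@loss,
    epochsRun = nrow(fit$history))
  say("done in %.1f s: accuracy %.3f, AUC %.3f", proc.time()[3] - t0,
      report$accuracy, report$auc)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(fit$history, file.path(outDir, "history.csv"),
                     row.names = FALSE)
    manifest <- data.frame(record = cd$record, subject = cd$subject,
                           startTime = cd$startTime, snrDb = cd$snrDb,
                           partition = part)
    utils::write.csv(manifest, file.path(outDir, "segments.csv"),
                     row.names = FALSE)
    for (i in seq_len(min(3L, dim(imgs)[3])))
      writeImagePNG(imgs[, , i],
                    file.path(outDir, sprintf("scalogram%02d.png", i)))
  }
  list(report = report, evalReport = ev, history = fit$history,
       model = fit$model, se = se)
}
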