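#' Default run configuration
#'
#' Nested configuration covering every pipeline stage. The `"desk"` profile
#' is sized for single-CPU experiments (8 identities, 64x64 scalograms);
#' `"paper-full"` carries the published-scale architecture settings.
#'
#' @param profile `"desk"` or `"paper-full"`.
#' @param seed global seed.
#' @return nested list with class `RunConfig`.
#' @export
defaultRunConfig <- function(profile = c("desk", "paper-full"), seed = 0L) {
  profile <- match.arg(profile)
  desk <- profile == "desk"
  structure(list(
    profile = profile,
    seed = as.integer(seed),
    simulate = list(nIdentities = 8L, recordsPerIdentity = 12L,
                    durationS = 15, fs = 250,
                    noise = unclass(noiseConfig())),
    preprocess = unclass(preprocessConfig()),
    scalogram = if (desk)
      unclass(scalogramConfig(nFreqBins = 64L, freqMinHz = 0.5,
                              freqMaxHz = 20, imageSide = 64L))
    else unclass(scalogramConfig()),
    model = unclass(modelConfig(profile)),
    train = if (desk) unclass(trainConfig(maxEpochs = 15L))
    else unclass(trainConfig(maxEpochs = 100L, earlyStopPatience = 50L)),
    output = list(dir = "ppgbioid-out")),
    class = "RunConfig")
}

# Recursively overlay user values onto defaults, rejecting unknown keys.
.mergeConfig <- function(base, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, "$", k) else k
    if (!k %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], user[[k]], full)
    else base[[k]] <- user[[k]]
  }
  base
}

#' Load a run configuration from YAML
#'
#' Missing fields take their documented defaults (an empty file yields the
#' full desk-profile default); unknown keys are rejected.
#'
#' @param path YAML file path (NULL for pure defaults).
#' @param profile base profile for the defaults.
#' @return a `RunConfig`.
#' @export
loadRunConfig <- function(path = NULL, profile = "desk") {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.null(user$profile)) profile <- user$profile
  base <- defaultRunConfig(profile)
  structure(.mergeConfig(unclass(base), user), class = "RunConfig")
}

#' Save a run configuration as YAML
#' @param cfg a `RunConfig`.
#' @param path output path.
#' @export
saveRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks cross-field constraints (Nyquist limits, pooling/patch geometry,
#' overlap and fraction ranges) and returns a character vector of problems;
#' an empty vector means the configuration is runnable.
#'
#' @param cfg a `RunConfig`.
#' @return character vector of problem descriptions.
#' @export
validateRunConfig <- function(cfg) {
  problems <- character()
  note <- function(...) problems <<- c(problems, sprintf(...))
  pp <- cfg$preprocess
  if (pp$bandHighHz >= pp$targetFs / 2)
    note("preprocess$bandHighHz %g is at or above Nyquist %g of targetFs",
         pp$bandHighHz, pp$targetFs / 2)
  if (pp$overlap < 0 || pp$overlap >= 1)
    note("preprocess$overlap must lie in [0, 1)")
  sc <- cfg$scalogram
  if (sc$freqMaxHz > pp$targetFs / 2)
    note("scalogram$freqMaxHz %g exceeds Nyquist %g of the resampled rate",
         sc$freqMaxHz, pp$targetFs / 2)
  mc <- cfg$model
  ok <- tryCatch({
    .validateModelConfig(structure(mc, class = "ModelConfig")); TRUE
  }, error = function(e) { note("%s", conditionMessage(e)); FALSE })
  if (ok && mc$imageSide != sc$imageSide)
    note("model$imageSide %d does not match scalogram$imageSide %d",
         mc$imageSide, sc$imageSide)
  if (cfg$simulate$nIdentities < 2)
    note("simulate$nIdentities must be >= 2")
  tr <- cfg$train
  if (tr$learningRate < 0) note("train$learningRate must be >= 0")
  problems
}
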