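#' @include AllClasses.R dataset.R train.R baselines.R metrics.R io.R
NULL

#' End-to-end pipeline configuration
#'
#' @param psf a \linkS4class{PSFSpec}, or \code{NULL} to estimate it from
#'   \code{testImage} + \code{wireRois}.
#' @param testImage optional linear-amplitude matrix with wire targets for
#'   PSF estimation.
#' @param wireRois list of wire ROI boxes for \code{\link{estimatePsfSize}}.
#' @param size image side in pixels.
#' @param pairsPerCombo pairs per level combination.
#' @param trainFraction training fraction.
#' @param normalization \code{"max"} or \code{"theoretical"}.
#' @param netConfig a \code{\link{networkConfig}}.
#' @param trainConfig a \code{\link{trainingConfig}}.
#' @param baselineParams optional list of per-method baseline parameter
#'   lists (\code{nlm}, \code{adf}, \code{blf}).
#' @param nEval held-out evaluation images simulated after training.
#' @param outputDir run directory.
#' @param masterSeed master seed; every random draw in the run derives
#'   from it.
#' @param saveDatasetDir logical; persist the full dataset under the run
#'   directory (off by default, datasets can be large).
#' @return A validated configuration list.
#' @export
pipelineConfig <- function(psf = NULL, testImage = NULL, wireRois = NULL,
                           size = 256, pairsPerCombo = 350,
                           trainFraction = 0.7,
                           normalization = c("max", "theoretical"),
                           netConfig = networkConfig(),
                           trainConfig = trainingConfig(),
                           baselineParams = list(), nEval = 10,
                           outputDir = tempfile("echomap_run_"),
                           masterSeed = 1, saveDatasetDir = FALSE) {
  normalization <- match.arg(normalization)
  if (is.null(psf) && (is.null(testImage) || is.null(wireRois)))
    stopCond("echomapConfigError",
             "either psf or testImage + wireRois must be given")
  list(psf = psf, testImage = testImage, wireRois = wireRois, size = size,
       pairsPerCombo = pairsPerCombo, trainFraction = trainFraction,
       normalization = normalization, netConfig = netConfig,
       trainConfig = trainConfig, baselineParams = baselineParams,
       nEval = nEval, outputDir = outputDir,
       masterSeed = as.integer(masterSeed),
       saveDatasetDir = isTRUE(saveDatasetDir))
}

#' Simulate held-out evaluation pairs
#'
#' Fresh phantom/speckle pairs from seeds disjoint from any dataset built
#' with the same master seed (a distinct seed stream offset is used).
#'
#' @param psf \linkS4class{PSFSpec}.
#' @param n number of pairs.
#' @param size image side.
#' @param method normalization method.
#' @param combo level combo used for every pair (default +6 dB cyst,
#'   +6 dB edge/point: a positive-contrast target that makes CNR
#'   improvement directionally unambiguous).
#' @param masterSeed integer.
#' @return List of per-pair lists: \code{map}, \code{bmode} (normalized
#'   matrix), \code{truth} (normalized matrix), \code{rois}.
#' @export
simulateEvalPairs <- function(psf, n = 10, size = 64, method = "max",
                              combo = list(cyst = 6, edgePoint = 6),
                              masterSeed = 1) {
  seeds <- deriveSeeds(masterSeed + 104729L, 2L * n)  # offset stream
  out <- vector("list", n)
  for (i in seq_len(n)) {
    map <- NULL
    for (retry in 0:9) {
      map <- tryCatch(
        generateEchogenicityMap(size, combo,
                                seed = (seeds[i] + retry) %% .Machine$integer.max),
        echomapPlacementError = function(e) NULL)
      if (!is.null(map)) break
    }
    bm <- simulateBmode(map, psf, seed = seeds[n + i])
    pair <- normalizePair(bm, map, method = method)
    out[[i]] <- list(map = map, bmode = pair$bmode@pixels,
                     truth = pair$truth, rois = autoRois(map))
  }
  out
}

#' Compare the CNN with the classical baselines on one image
#'
#' @param bmode a normalized linear-amplitude \linkS4class{BModeImage} or
#'   matrix (the network input domain).
#' @param model a trained \linkS4class{UNetModel}.
#' @param baselineParams optional list of per-method parameter lists.
#' @param rois named ROI list (see \code{\link{evaluateReconstruction}}).
#' @param groundTruth optional normalized linear ground-truth matrix.
#' @param dynamicRange display dynamic range for the metric domain.
#' @return A data.frame with one row per method (original, nlm, adf, blf,
#'   cnn): the metric suite plus an informational \code{seconds} column.
#' @export
compareMethods <- function(bmode, model, baselineParams = list(), rois,
                           groundTruth = NULL, dynamicRange = 60) {
  lin <- if (is(bmode, "BModeImage")) bmode@pixels else bmode
  disp <- logCompress(lin, dynamicRange)
  truthDisp <- if (is.null(groundTruth)) NULL
               else logCompress(clamp01(groundTruth), dynamicRange)
  recons <- list(original = list(img = disp, secs = 0))
  t0 <- proc.time()[["elapsed"]]
  recons$nlm <- list(img = do.call(nlmFilter,
                       c(list(disp), baselineParams$nlm)))
  recons$nlm$secs <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  recons$adf <- list(img = do.call(adfFilter,
                       c(list(disp), baselineParams$adf)))
  recons$adf$secs <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  recons$blf <- list(img = do.call(blfFilter,
                       c(list(disp), baselineParams$blf)))
  recons$blf$secs <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  cnnLin <- despeckle(model, lin, clip = TRUE)
  recons$cnn <- list(img = logCompress(cnnLin, dynamicRange),
                     secs = proc.time()[["elapsed"]] - t0)
  rows <- lapply(names(recons), function(nm) {
    rep <- evaluateReconstruction(disp, recons[[nm]]$img, truthDisp, rois)
    cbind(data.frame(method = nm), reportAsDataFrame(rep),
          data.frame(seconds = recons[[nm]]$secs))
  })
  do.call(rbind, rows)
}

#' Run the full three-step recipe
#'
#' Estimate (or take) the PSF, build the matched simulation dataset, train
#' the network, reconstruct held-out simulated images, compare with the
#' classical baselines, and persist every artifact plus a JSON manifest to
#' the run directory.
#'
#' @param config list from \code{\link{pipelineConfig}}.
#' @param verbose print stage progress.
#' @return Invisibly, a list with \code{psf}, \code{dataset}, \code{model},
#'   \code{evalPairs}, \code{comparison} (data.frame) and \code{outputDir}.
#' @export
runFullPipeline <- function(config, verbose = FALSE) {
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(nm, expr) {
    if (verbose) message("[", nm, "]")
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)),
           call. = FALSE)
    })
  }
  psf <- stage("estimate-psf", {
    if (!is.null(config$psf)) config$psf
    else estimatePsfSize(config$testImage, config$wireRois)
  })
  dataset <- stage("simulate-dataset",
    buildDataset(psf, pairsPerCombo = config$pairsPerCombo,
                 trainFraction = config$trainFraction,
                 method = config$normalization, size = config$size,
                 masterSeed = config$masterSeed))
  if (config$saveDatasetDir)
    stage("save-dataset", saveDataset(dataset,
                                      file.path(config$outputDir, "dataset")))
  model <- stage("train", trainUnet(dataset, config$netConfig,
                                    config$trainConfig, verbose = verbose))
  stage("save-model", {
    saveModel(model, file.path(config$outputDir, "model.rds"))
    utils::write.csv(model@history,
                     file.path(config$outputDir, "loss_history.csv"),
                     row.names = FALSE)
  })
  evalPairs <- stage("simulate-eval",
    simulateEvalPairs(psf, n = config$nEval, size = config$size,
                      method = config$normalization,
                      masterSeed = config$masterSeed))
  comparison <- stage("compare", {
    rows <- lapply(seq_along(evalPairs), function(i) {
      p <- evalPairs[[i]]
      cbind(data.frame(image = i),
            compareMethods(p$bmode, model, config$baselineParams, p$rois,
                           groundTruth = p$truth))
    })
    do.call(rbind, rows)
  })
  stage("write-reports", {
    utils::write.csv(comparison,
                     file.path(config$outputDir, "comparison.csv"),
                     row.names = FALSE)
    for (i in seq_along(evalPairs)) {
      p <- evalPairs[[i]]
      writeImageTiff(p$bmode, file.path(config$outputDir,
                                        sprintf("eval_bmode_%02d.tiff", i)))
      rec <- despeckle(model, p$bmode, clip = TRUE)
      writeImageTiff(rec, file.path(config$outputDir,
                                    sprintf("eval_cnn_%02d.tiff", i)))
    }
    manifest <- list(
      version = as.character(utils::packageVersion("EchoMap")),
      psf = list(lateral = psf@lateral, axial = psf@axial),
      size = config$size, pairsPerCombo = config$pairsPerCombo,
      normalization = config$normalization,
      netConfig = unclass(config$netConfig),
      trainConfig = unclass(config$trainConfig),
      masterSeed = config$masterSeed,
      artifacts = list.files(config$outputDir, recursive = TRUE))
    jsonlite::write_json(manifest,
                         file.path(config$outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(list(psf = psf, dataset = dataset, model = model,
                 evalPairs = evalPairs, comparison = comparison,
                 outputDir = config$outputDir))
}
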