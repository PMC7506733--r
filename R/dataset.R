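#' @include AllClasses.R simulator.R phantom.R
NULL

#' Build a paired simulation dataset
#'
#' Generates \code{pairsPerCombo} normalized (B-mode, ground truth) pairs
#' for every echogenicity level combination (28 by default), with per-pair
#' seeds derived deterministically from the master seed and a shuffled
#' train/validation split.
#'
#' @param psf \linkS4class{PSFSpec} used to simulate every pair.
#' @param pairsPerCombo pairs per level combination (350 gives the full
#'   9800-pair set).
#' @param trainFraction fraction of all pairs assigned to the training
#'   split (default 0.7).
#' @param method normalization method, \code{"max"} or \code{"theoretical"}.
#' @param size image side in pixels.
#' @param masterSeed integer; every random draw derives from it.
#' @param combos level grid (default \code{\link{levelCombinations}}).
#' @param ... passed to \code{\link{generateEchogenicityMap}} (structure
#'   counts, size ranges).
#' @return A \linkS4class{SpeckleDataset} with
#'   \code{nrow(combos) * pairsPerCombo} pairs.
#' @examples
#' ds <- buildDataset(PSFSpec(4, 4), pairsPerCombo = 1, size = 64,
#'                    masterSeed = 7)
#' dim(ds@bmode)
#' @export
buildDataset <- function(psf, pairsPerCombo = 350, trainFraction = 0.7,
                         method = c("max", "theoretical"), size = 256,
                         masterSeed = 1, combos = levelCombinations(), ...) {
  method <- match.arg(method)
  stopifnot(is(psf, "PSFSpec"), pairsPerCombo >= 1)
  n <- nrow(combos) * pairsPerCombo
  seeds <- deriveSeeds(masterSeed, 2L * n)
  mapSeeds <- seeds[seq_len(n)]
  fieldSeeds <- seeds[n + seq_len(n)]
  bmode <- array(0, c(size, size, n))
  truth <- array(0, c(size, size, n))
  info <- data.frame(comboCyst = rep(combos$cyst, each = pairsPerCombo),
                     comboEdgePoint = rep(combos$edgePoint, each = pairsPerCombo),
                     seed = as.integer(mapSeeds),
                     split = "validation", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    combo <- list(cyst = info$comboCyst[i], edgePoint = info$comboEdgePoint[i])
    map <- NULL
    for (retry in 0:9) {   # placement is rejection-sampled; reseed on failure
      map <- tryCatch(
        generateEchogenicityMap(size, combo, seed = (mapSeeds[i] + retry) %%
                                  .Machine$integer.max, ...),
        echomapPlacementError = function(e) NULL)
      if (!is.null(map)) break
    }
    if (is.null(map))
      stopCond("echomapPlacementError", "pair %d: repeated placement failure", i)
    bm <- simulateBmode(map, psf, seed = fieldSeeds[i])
    pair <- normalizePair(bm, map, method = method)
    bmode[, , i] <- pair$bmode@pixels
    truth[, , i] <- pair$truth
  }
  nTrain <- round(trainFraction * n)
  perm <- withSeed(masterSeed, sample.int(n))
  info$split[perm[seq_len(nTrain)]] <- "train"
  new("SpeckleDataset", bmode = bmode, truth = truth, info = info, psf = psf,
      normalization = method, masterSeed = as.integer(masterSeed))
}

#' Subset of a dataset by split
#'
#' @param dataset a \linkS4class{SpeckleDataset}.
#' @param split \code{"train"} or \code{"validation"}.
#' @return Integer indices of the pairs in that split.
#' @export
splitIndices <- function(dataset, split = c("train", "validation")) {
  split <- match.arg(split)
  which(dataset@info$split == split)
}
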