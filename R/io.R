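#' @include AllClasses.R
NULL

#' Read and write images
#'
#' Single images are persisted as 32-bit float TIFF (linear amplitude) or
#' 8-bit PNG (display domain). \code{readImageAny} auto-detects by file
#' extension; pixel values from PNG are rescaled to [0, 255].
#'
#' @param pixels numeric matrix.
#' @param path file path.
#' @name image-io
NULL

#' @rdname image-io
#' @export
writeImageTiff <- function(pixels, path) {
  # float TIFF stores raw values without [0,1] clamping
  tiff::writeTIFF(pixels, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname image-io
#' @export
writeImagePng <- function(pixels, path) {
  png::writePNG(pmin(pmax(pixels / 255, 0), 1), path)
  invisible(path)
}

#' @rdname image-io
#' @export
readImageAny <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path, as.is = FALSE),
    "png" = png::readPNG(path) * 255,
    stopCond("echomapUsageError", "unsupported image format: %s", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Persist a dataset as a directory of float TIFFs plus a JSON manifest
#'
#' Each pair i is written as \code{bmode_i.tiff} and \code{truth_i.tiff};
#' \code{manifest.json} records PSF sizes, seeds, combo labels, split and
#' normalization method.
#'
#' @param dataset a \linkS4class{SpeckleDataset}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
saveDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(dataset@bmode)[3]
  for (i in seq_len(n)) {
    writeImageTiff(dataset@bmode[, , i], file.path(dir, sprintf("bmode_%05d.tiff", i)))
    writeImageTiff(dataset@truth[, , i], file.path(dir, sprintf("truth_%05d.tiff", i)))
  }
  info <- dataset@info
  info$comboCyst <- ifelse(is.infinite(info$comboCyst), "anechoic",
                           as.character(info$comboCyst))
  manifest <- list(
    psf = list(lateral = dataset@psf@lateral, axial = dataset@psf@axial),
    normalization = dataset@normalization,
    masterSeed = dataset@masterSeed,
    size = dim(dataset@bmode)[1], nPairs = n, pairs = info)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a dataset saved by \code{\link{saveDataset}}
#'
#' @param dir dataset directory.
#' @return A \linkS4class{SpeckleDataset}.
#' @export
loadDataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  n <- manifest$nPairs
  size <- manifest$size
  bmode <- array(0, c(size, size, n))
  truth <- array(0, c(size, size, n))
  for (i in seq_len(n)) {
    bmode[, , i] <- readImageAny(file.path(dir, sprintf("bmode_%05d.tiff", i)))
    truth[, , i] <- readImageAny(file.path(dir, sprintf("truth_%05d.tiff", i)))
  }
  info <- as.data.frame(manifest$pairs)
  cyst <- suppressWarnings(as.numeric(info$comboCyst))
  cyst[info$comboCyst == "anechoic"] <- -Inf
  info$comboCyst <- cyst
  info$seed <- as.integer(info$seed)
  new("SpeckleDataset", bmode = bmode, truth = truth, info = info,
      psf = PSFSpec(manifest$psf$lateral, manifest$psf$axial),
      normalization = manifest$normalization,
      masterSeed = as.integer(manifest$masterSeed))
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS file of the weight arrays plus a JSON sidecar
#' with the network/training configuration and the PSF of the training data.
#'
#' @param model a \linkS4class{UNetModel}.
#' @param path checkpoint path (\code{.rds}); the sidecar gets
#'   \code{.json} appended.
#' @return \code{path}, invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(netConfig = model@netConfig,
                  trainConfig = model@trainConfig,
                  psf = list(lateral = model@psf@lateral,
                             axial = model@psf@axial),
                  normalization = model@normalization,
                  epochsTrained = nrow(model@history))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)

#' Write an echogenicity map with its structure annotations
#'
#' @param map an \linkS4class{EchogenicityMap}.
#' @param path TIFF path; a JSON sidecar with the structure table and combo
#'   label is written next to it.
#' @return \code{path}, invisibly.
#' @export
saveEchogenicityMap <- function(map, path) {
  writeImageTiff(map@pixels, path)
  side <- list(comboCyst = if (is.infinite(map@comboCyst)) "anechoic"
                           else map@comboCyst,
               comboEdgePoint = map@comboEdgePoint, seed = map@seed,
               structures = map@structures)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
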