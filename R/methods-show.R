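#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn pixelData method for EchogenicityMap
#' @export
setMethod("pixelData", "EchogenicityMap", function(object) object@pixels)

#' @describeIn pixelData method for BModeImage
#' @export
setMethod("pixelData", "BModeImage", function(object) object@pixels)

#' @describeIn structures method for EchogenicityMap
#' @export
setMethod("structures", "EchogenicityMap", function(object) object@structures)

#' @describeIn psfLateral method for PSFSpec
#' @export
setMethod("psfLateral", "PSFSpec", function(object) object@lateral)

#' @describeIn psfLateral axial size of a PSFSpec
#' @export
setMethod("psfAxial", "PSFSpec", function(object) object@axial)

#' @describeIn psfLateral lateral PSF size of a BModeImage
#' @export
setMethod("psfLateral", "BModeImage", function(object) object@psf@lateral)

#' @describeIn psfLateral axial PSF size of a BModeImage
#' @export
setMethod("psfAxial", "BModeImage", function(object) object@psf@axial)

#' @describeIn lossHistory method for UNetModel
#' @export
setMethod("lossHistory", "UNetModel", function(object) object@history)

setMethod("show", "PSFSpec", function(object) {
  cat(sprintf("PSFSpec: lateral %.3g px, axial %.3g px (-6 dB full width)\n",
              object@lateral, object@axial))
})

setMethod("show", "EchogenicityMap", function(object) {
  d <- dim(object@pixels)
  lev <- if (is.infinite(object@comboCyst)) "anechoic"
         else sprintf("%+g dB", object@comboCyst)
  cat(sprintf("EchogenicityMap %dx%d | cyst %s, edge/point %+g dB | %d structures | seed %d\n",
              d[1], d[2], lev, object@comboEdgePoint,
              nrow(object@structures), object@seed))
})

setMethod("show", "BModeImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BModeImage %dx%d | normalized: %s | log-compressed: %s | PSF %.3g/%.3g px\n",
              d[1], d[2], object@normalized,
              ifelse(object@logCompressed, "yes", "no"),
              object@psf@lateral, object@psf@axial))
})

setMethod("show", "SpeckleDataset", function(object) {
  d <- dim(object@bmode)
  cat(sprintf("SpeckleDataset: %d pairs of %dx%d images (%d train / %d validation)\n",
              d[3], d[1], d[2], sum(object@info$split == "train"),
              sum(object@info$split == "validation")))
  cat(sprintf("  PSF %.3g/%.3g px | normalization: %s | master seed %d\n",
              object@psf@lateral, object@psf@axial, object@normalization,
              object@masterSeed))
})

setMethod("show", "UNetModel", function(object) {
  nc <- object@netConfig
  cat(sprintf("UNetModel: minFilters %d, filterSize %d, %s loss | %d epochs trained\n",
              nc$minFilters, nc$filterSize, object@trainConfig$loss,
              nrow(object@history)))
  if (nrow(object@history) > 0) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  final train loss %.5g, validation loss %.5g\n",
                last$train, last$val))
  }
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  df <- reportAsDataFrame(object)
  for (nm in names(df))
    if (!is.na(df[[nm]])) cat(sprintf("  %-12s %.5g\n", nm, df[[nm]]))
})
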