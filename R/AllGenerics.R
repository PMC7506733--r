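#' @include AllClasses.R
NULL

#' Pixel data of an image object
#'
#' Returns the underlying numeric matrix of an \linkS4class{EchogenicityMap}
#' or \linkS4class{BModeImage}, with axis 1 (rows) axial and axis 2 (columns)
#' lateral.
#'
#' @param object an image object.
#' @return A numeric matrix.
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))

#' Structure annotations of an echogenicity map
#'
#' @param object an \linkS4class{EchogenicityMap}.
#' @return A data.frame with one row per placed structure (kind, level in dB
#'   with \code{-Inf} meaning anechoic, and the geometry columns that apply
#'   to the kind).
#' @export
setGeneric("structures", function(object) standardGeneric("structures"))

#' Lateral and axial PSF size accessors
#'
#' PSF sizes are full widths at -6 dB of the amplitude point spread
#' function, in pixels.
#'
#' @param object a \linkS4class{PSFSpec} (or an object carrying one).
#' @return Numeric scalar size in pixels.
#' @export
setGeneric("psfLateral", function(object) standardGeneric("psfLateral"))

#' @rdname psfLateral
#' @export
setGeneric("psfAxial", function(object) standardGeneric("psfAxial"))

#' Per-epoch loss history of a trained model
#'
#' @param object a \linkS4class{UNetModel}.
#' @return A data.frame with columns \code{epoch}, \code{train}, \code{val}.
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' Reconstruct an echogenicity map from a speckled B-mode image
#'
#' Applies the trained residual U-net: the network predicts a residual
#' \eqn{r(x)} which is added to the input, \eqn{f(x) = r(x) + x}.
#'
#' @param model a \linkS4class{UNetModel}.
#' @param image a normalized \linkS4class{BModeImage} or a numeric matrix in
#'   the same normalization the model was trained with.
#' @param clip logical; clip the output to [0, 1] for display.
#' @return A numeric matrix of the same shape as the input.
#' @export
setGeneric("despeckle", function(model, image, clip = FALSE)
  standardGeneric("despeckle"))
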