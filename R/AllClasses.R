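# Central S4 containers. Axis convention everywhere: matrix rows = axial
# (depth), columns = lateral.

#' Point spread function size specification
#'
#' The PSF of the imaging system is modeled as a separable 2-D Gaussian.
#' Its "size" per axis is the full width at -6 dB of the amplitude PSF in
#' pixels; the Gaussian standard deviation follows as
#' \eqn{\sigma = size / (2\sqrt{2\ln 2}) \approx size / 2.3548}.
#'
#' @slot lateral full width at -6 dB along the lateral axis, pixels.
#' @slot axial full width at -6 dB along the axial axis, pixels.
#' @export
setClass("PSFSpec", representation(lateral = "numeric", axial = "numeric"))

setValidity("PSFSpec", function(object) {
  if (length(object@lateral) != 1L || length(object@axial) != 1L)
    return("lateral and axial must be scalars")
  if (!is.finite(object@lateral) || !is.finite(object@axial))
    return("PSF sizes must be finite")
  if (object@lateral <= 0 || object@axial <= 0)
    return("PSF sizes must be positive")
  TRUE
})

#' Construct a PSFSpec
#'
#' @param lateral,axial full widths at -6 dB of the amplitude PSF, pixels.
#' @return A \linkS4class{PSFSpec}.
#' @examples
#' psf <- PSFSpec(6.2, 2.8)
#' psfSigma(psf)
#' @export
PSFSpec <- function(lateral, axial) {
  new("PSFSpec", lateral = as.numeric(lateral), axial = as.numeric(axial))
}

#' Gaussian standard deviations implied by a PSFSpec
#'
#' @param psf a \linkS4class{PSFSpec}.
#' @return Named numeric vector \code{c(lateral = , axial = )} of standard
#'   deviations in pixels.
#' @export
psfSigma <- function(psf) {
  k <- 2 * sqrt(2 * log(2))
  c(lateral = psf@lateral / k, axial = psf@axial / k)
}

#' Ground-truth echogenicity map
#'
#' Linear-amplitude tissue reflectivity image. Background pixels are exactly
#' 1.0; pixels inside a structure are \eqn{10^{level/20}} (0 for anechoic).
#'
#' @slot pixels numeric matrix of non-negative linear amplitudes.
#' @slot structures data.frame of placed structures (see
#'   \code{\link{structures}}).
#' @slot comboCyst cyst echogenicity level in dB relative to background;
#'   \code{-Inf} encodes anechoic.
#' @slot comboEdgePoint shared edge/point level in dB.
#' @slot seed integer seed the map was generated from.
#' @export
setClass("EchogenicityMap",
  representation(pixels = "matrix", structures = "data.frame",
                 comboCyst = "numeric", comboEdgePoint = "numeric",
                 seed = "integer"))

setValidity("EchogenicityMap", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (any(p < 0)) return("pixels must be non-negative")
  if (nrow(p) != ncol(p)) return("map must be square")
  TRUE
})

#' Speckled B-mode image
#'
#' Envelope-amplitude image produced by the forward simulator (or loaded
#' from disk). Carries its normalization and log-compression state so that
#' downstream operations can check preconditions.
#'
#' @slot pixels numeric matrix of non-negative envelope amplitudes (or 8-bit
#'   display values once log-compressed).
#' @slot psf the \linkS4class{PSFSpec} used to simulate (or estimated).
#' @slot normalized one of \code{"none"}, \code{"max"}, \code{"theoretical"}.
#' @slot logCompressed logical.
#' @slot dynamicRange display dynamic range in dB (used when log-compressed).
#' @slot seed integer seed of the scatterer field.
#' @export
setClass("BModeImage",
  representation(pixels = "matrix", psf = "PSFSpec", normalized = "character",
                 logCompressed = "logical", dynamicRange = "numeric",
                 seed = "integer"))

setValidity("BModeImage", function(object) {
  if (any(object@pixels < 0)) return("envelope pixels must be non-negative")
  if (!object@normalized %in% c("none", "max", "theoretical"))
    return("normalized must be 'none', 'max' or 'theoretical'")
  TRUE
})

#' Paired simulation dataset
#'
#' In-memory container for normalized (B-mode, ground truth) training pairs.
#' Images are stored as (H, W, N) arrays; \code{info} holds one row per pair
#' (combo levels, per-pair seed, train/validation split).
#'
#' @slot bmode numeric array (H, W, N) of normalized B-mode inputs.
#' @slot truth numeric array (H, W, N) of normalized ground-truth maps.
#' @slot info data.frame with columns \code{comboCyst}, \code{comboEdgePoint},
#'   \code{seed}, \code{split}.
#' @slot psf \linkS4class{PSFSpec} used for simulation.
#' @slot normalization \code{"max"} or \code{"theoretical"}.
#' @slot masterSeed integer master seed.
#' @export
setClass("SpeckleDataset",
  representation(bmode = "array", truth = "array", info = "data.frame",
                 psf = "PSFSpec", normalization = "character",
                 masterSeed = "integer"))

setValidity("SpeckleDataset", function(object) {
  if (!identical(dim(object@bmode), dim(object@truth)))
    return("bmode and truth arrays must share dimensions")
  if (length(dim(object@bmode)) != 3L) return("arrays must be (H, W, N)")
  if (dim(object@bmode)[3] != nrow(object@info))
    return("info must have one row per pair")
  if (!all(object@info$split %in% c("train", "validation")))
    return("split must be 'train' or 'validation'")
  TRUE
})

#' Trained residual U-net artifact
#'
#' @slot params named list of weight arrays (conv kernels, biases, batch-norm
#'   scale/shift and running statistics).
#' @slot netConfig list from \code{\link{networkConfig}}.
#' @slot trainConfig list from \code{\link{trainingConfig}}.
#' @slot psf \linkS4class{PSFSpec} of the training data.
#' @slot normalization normalization method of the training data.
#' @slot history data.frame of per-epoch train/validation losses.
#' @export
setClass("UNetModel",
  representation(params = "list", netConfig = "list", trainConfig = "list",
                 psf = "PSFSpec", normalization = "character",
                 history = "data.frame"))

#' Image-quality metrics report
#'
#' One reconstruction's metric suite. Fields that require a ground truth
#' (mse, psnr, ssim, msSsim, mi) are \code{NA} when none was supplied.
#'
#' @slot cr contrast ratio (difference of ROI means, display domain).
#' @slot cnr contrast-to-noise ratio.
#' @slot fwhmLateral,fwhmAxial full width at half maximum of the wire
#'   target, pixels.
#' @slot mse,psnr,ssim,msSsim,mi full-reference metrics on 8-bit display
#'   images.
#' @slot metadata list (image identifiers, ROIs, pixel domain).
#' @export
setClass("MetricsReport",
  representation(cr = "numeric", cnr = "numeric", fwhmLateral = "numeric",
                 fwhmAxial = "numeric", mse = "numeric", psnr = "numeric",
                 ssim = "numeric", msSsim = "numeric", mi = "numeric",
                 metadata = "list"),
  prototype(cr = NA_real_, cnr = NA_real_, fwhmLateral = NA_real_,
            fwhmAxial = NA_real_, mse = NA_real_, psnr = NA_real_,
            ssim = NA_real_, msSsim = NA_real_, mi = NA_real_,
            metadata = list()))

setValidity("MetricsReport", function(object) {
  if (!is.na(object@fwhmLateral) && object@fwhmLateral <= 0)
    return("fwhmLateral must be positive")
  if (!is.na(object@fwhmAxial) && object@fwhmAxial <= 0)
    return("fwhmAxial must be positive")
  TRUE
})

#' Coerce a MetricsReport to a one-row data.frame
#'
#' @param report a \linkS4class{MetricsReport}.
#' @return A one-row data.frame.
#' @export
reportAsDataFrame <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  data.frame(cr = report@cr, cnr = report@cnr,
             fwhmLateral = report@fwhmLateral, fwhmAxial = report@fwhmAxial,
             mse = report@mse, psnr = report@psnr, ssim = report@ssim,
             msSsim = report@msSsim, mi = report@mi)
}
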