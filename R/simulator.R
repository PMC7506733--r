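#' @include AllClasses.R utils.R phantom.R
NULL

#' Sample a complex white-Gaussian scatterer field
#'
#' Fully developed speckle arises from the coherent sum of many
#' sub-resolution scatterers; its complex echo amplitude has i.i.d. standard
#' normal real and imaginary parts, so the envelope is Rayleigh.
#'
#' @param shape integer vector \code{c(rows, cols)}.
#' @param seed integer seed.
#' @return A complex matrix with unit-variance components.
#' @export
sampleScattererField <- function(shape, seed) {
  withSeed(seed, {
    re <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    im <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    re + 1i * im
  })
}

#' Separable Gaussian PSF kernel
#'
#' Builds the 2-D Gaussian amplitude PSF with peak 1 at the center and odd
#' support covering +/- 3 sigma per axis. The -6 dB (half-amplitude) full
#' widths of the continuous Gaussian equal the requested sizes.
#'
#' @param psf a \linkS4class{PSFSpec} (rows of the kernel are axial, columns
#'   lateral).
#' @return A numeric matrix kernel.
#' @examples
#' k <- gaussianPsfKernel(PSFSpec(6.2, 2.8))
#' dim(k)
#' @export
gaussianPsfKernel <- function(psf) {
  if (!is(psf, "PSFSpec")) stopCond("echomapInvalidPsf", "psf must be a PSFSpec")
  sig <- psfSigma(psf)
  g1 <- function(sigma) {
    half <- max(1L, as.integer(ceiling(3 * sigma)))
    t <- (-half):half
    exp(-t^2 / (2 * sigma^2))
  }
  outer(g1(sig["axial"]), g1(sig["lateral"]))
}

#' Simulate a speckled B-mode image from an echogenicity map
#'
#' Forward model: the echogenicity map multiplies a complex white-Gaussian
#' scatterer field to give the complex reflectivity; convolution with the
#' Gaussian PSF kernel (zero-padded, same-size output) models the imaging
#' system; the envelope (modulus) is the unnormalized B-mode image.
#'
#' @param map an \linkS4class{EchogenicityMap}.
#' @param psf a \linkS4class{PSFSpec}.
#' @param seed integer seed for the scatterer field.
#' @param envelopeFirst logical; if \code{TRUE}, take the modulus of the
#'   reflectivity before PSF convolution (literal amplitude-domain variant).
#'   Default \code{FALSE}: convolve the complex reflectivity, then take the
#'   modulus, which yields fully developed Rayleigh speckle.
#' @return An unnormalized \linkS4class{BModeImage}.
#' @export
simulateBmode <- function(map, psf, seed, envelopeFirst = FALSE) {
  stopifnot(is(map, "EchogenicityMap"), is(psf, "PSFSpec"))
  field <- sampleScattererField(dim(map@pixels), seed)
  k <- gaussianPsfKernel(psf)
  refl <- map@pixels * field
  env <- if (envelopeFirst) Re(convolveSame(Mod(refl) + 0i, k))
         else Mod(convolveSame(refl, k))
  env[env < 0] <- 0
  new("BModeImage", pixels = env, psf = psf, normalized = "none",
      logCompressed = FALSE, dynamicRange = NA_real_,
      seed = as.integer(seed))
}

#' Normalize a simulated (B-mode, ground truth) pair for training
#'
#' Two conventions are supported. \code{"max"}: each image is divided by its
#' own maximum, which leaves an amplitude gap between the normalized B-mode
#' background and the normalized ground-truth background (the speckle
#' maximum overshoots the Rayleigh mean). \code{"theoretical"}: the ground
#' truth is divided by its maximum amplitude \eqn{A_{max}} while the B-mode
#' image is divided by the theoretical envelope reference
#' \eqn{R = A_{max}\,\|k\|_2\sqrt{\pi/2}} (the expected Rayleigh envelope
#' mean for a region at peak echogenicity) and clipped to [0, 1], which
#' closes the gap.
#'
#' @param bmode an unnormalized \linkS4class{BModeImage}.
#' @param truth an \linkS4class{EchogenicityMap} or raw linear-amplitude
#'   matrix.
#' @param method \code{"max"} or \code{"theoretical"}.
#' @return A list with elements \code{bmode} (normalized
#'   \linkS4class{BModeImage}), \code{truth} (matrix with max 1) and
#'   \code{method}.
#' @export
normalizePair <- function(bmode, truth, method = c("max", "theoretical")) {
  method <- match.arg(method)
  stopifnot(is(bmode, "BModeImage"))
  if (bmode@normalized != "none")
    stopCond("echomapUsageError", "bmode is already normalized")
  tp <- if (is(truth, "EchogenicityMap")) truth@pixels else truth
  amax <- max(tp)
  bmax <- max(bmode@pixels)
  if (amax <= 0 || bmax <= 0)
    stopCond("echomapDegenerateNormalization", "all-zero image cannot be normalized")
  if (method == "max") {
    bpix <- bmode@pixels / bmax
  } else {
    k <- gaussianPsfKernel(bmode@psf)
    ref <- amax * sqrt(sum(k^2)) * sqrt(pi / 2)
    bpix <- clamp01(bmode@pixels / ref)
  }
  nb <- bmode
  nb@pixels <- bpix
  nb@normalized <- method
  list(bmode = nb, truth = tp / amax, method = method)
}

#' Log-compress a normalized image for display
#'
#' Maps amplitude to decibels and linearly rescales the interval
#' [-dynamicRange, 0] dB to 8-bit display values [0, 255], clipping outside.
#'
#' @param bmode a normalized \linkS4class{BModeImage}, or a numeric matrix
#'   with maximum 1.
#' @param dynamicRange display dynamic range in dB (default 60).
#' @return An integer-valued matrix in [0, 255].
#' @export
logCompress <- function(bmode, dynamicRange = 60) {
  if (is(bmode, "BModeImage")) {
    if (bmode@normalized == "none")
      stopCond("echomapUsageError", "log compression requires a normalized image")
    p <- bmode@pixels
  } else {
    p <- bmode
    if (max(p) > 1 + 1e-9)
      stopCond("echomapUsageError", "log compression requires max <= 1")
  }
  db <- 20 * log10(pmax(p, 10^(-(dynamicRange + 40) / 20)))
  out <- (db + dynamicRange) / dynamicRange * 255
  matrix(as.numeric(round(pmin(pmax(out, 0), 255))), nrow(p), ncol(p))
}

#' Invert the display mapping of \code{logCompress}
#'
#' @param display matrix of 8-bit display values in [0, 255].
#' @param dynamicRange display dynamic range in dB used for compression.
#' @return Linear-amplitude matrix with maximum about 1.
#' @export
displayToLinear <- function(display, dynamicRange = 60) {
  10^((display / 255 * dynamicRange - dynamicRange) / 20)
}

#' Theoretical speckle signal-to-noise ratio of the Rayleigh envelope
#'
#' @return \eqn{\sqrt{\pi / (4 - \pi)} \approx 1.9131}, the mean/sd ratio of
#'   any Rayleigh-distributed envelope.
#' @export
speckleSnrTheoretical <- function() sqrt(pi / (4 - pi))

#' Kolmogorov-Smirnov test of envelope pixels against a Rayleigh fit
#'
#' Fits the Rayleigh scale by maximum likelihood
#' (\eqn{\hat\sigma = \sqrt{\sum x_i^2 / (2n)}}) and runs a one-sample KS
#' test against the fitted distribution.
#'
#' @param x numeric vector of envelope amplitudes (background pixels).
#' @return The \code{htest} object from \code{\link[stats]{ks.test}}.
#' @export
rayleighKsTest <- function(x) {
  x <- as.numeric(x)
  sigma <- sqrt(mean(x^2) / 2)
  stats::ks.test(x, function(q) 1 - exp(-q^2 / (2 * sigma^2)))
}
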