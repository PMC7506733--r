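#' @include AllClasses.R utils.R psf.R loss.R
NULL

roiPixels <- function(image, box) {
  box <- as.numeric(box)
  rows <- box[1] + seq_len(box[3]) - 1
  cols <- box[2] + seq_len(box[4]) - 1
  if (length(rows) == 0 || length(cols) == 0)
    stopCond("echomapUsageError", "empty ROI")
  if (min(rows) < 1 || min(cols) < 1 || max(rows) > nrow(image) ||
      max(cols) > ncol(image))
    stopCond("echomapUsageError", "ROI outside image")
  image[rows, cols]
}

#' ROI mean and population standard deviation
#'
#' @param image numeric matrix.
#' @param roi box \code{c(top, left, height, width)}, 1-based pixels.
#' @return Named numeric vector \code{c(mean = , sd = )}; the standard
#'   deviation is the population form (divisor n).
#' @examples
#' roiStats(matrix(c(9, 11), 1), c(1, 1, 1, 2))  # mean 10, sd 1
#' @export
roiStats <- function(image, roi) {
  v <- as.numeric(roiPixels(image, roi))
  c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
}

#' Contrast ratio between a target and a background ROI
#'
#' Signed difference of ROI mean magnitudes, computed directly on the
#' display (log-compressed) image.
#'
#' @param image display-domain matrix.
#' @param cystRoi,bgRoi boxes \code{c(top, left, height, width)}.
#' @return \eqn{CR = \mu_{cyst} - \mu_{background}}.
#' @export
contrastRatio <- function(image, cystRoi, bgRoi) {
  roiStats(image, cystRoi)["mean"][[1]] - roiStats(image, bgRoi)["mean"][[1]]
}

#' Contrast-to-noise ratio
#'
#' \deqn{CNR = (\mu_{cyst} - \mu_{background}) /
#'   \sqrt{\sigma_{cyst}^2 + \sigma_{background}^2}}
#' The sign follows the contrast ratio (no absolute value).
#'
#' @inheritParams contrastRatio
#' @return Signed CNR.
#' @export
cnr <- function(image, cystRoi, bgRoi) {
  a <- roiStats(image, cystRoi)
  b <- roiStats(image, bgRoi)
  denom <- sqrt(a["sd"]^2 + b["sd"]^2)[[1]]
  if (denom == 0)
    stopCond("echomapUndefinedCnr", "both ROI standard deviations are zero")
  (a["mean"][[1]] - b["mean"][[1]]) / denom
}

#' Full width at half maximum of a wire target
#'
#' Takes the profile through the ROI's peak along the requested axis,
#' subtracts the profile-endpoint baseline, and measures the distance
#' between the linear-interpolated half-maximum crossings.
#'
#' @param image numeric matrix (linear amplitude by default; any monotone
#'   domain works since only the profile shape matters).
#' @param wireRoi box \code{c(top, left, height, width)} containing one
#'   dominant peak.
#' @param axis \code{"lateral"} (profile across columns) or \code{"axial"}
#'   (across rows).
#' @param interp crossing-location convention: \code{"spline"} (default)
#'   upsamples the profile 16x with a cubic spline before locating the
#'   crossings, giving widths accurate to well under 1 percent for
#'   Gaussian-like peaks down to sigma of 1 px; \code{"linear"} interpolates
#'   the raw samples piecewise-linearly (the classic convention, under
#'   which a single-pixel impulse has width exactly 1).
#' @return Width in pixels.
#' @export
fwhm <- function(image, wireRoi, axis = c("lateral", "axial"),
                 interp = c("spline", "linear")) {
  axis <- match.arg(axis)
  interp <- match.arg(interp)
  box <- as.numeric(wireRoi)
  sub <- matrix(roiPixels(image, wireRoi), box[3], box[4])
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  prof <- if (axis == "axial") sub[, pk[2]] else sub[pk[1], ]
  ip <- if (axis == "axial") pk[1] else pk[2]
  baseline <- (prof[1] + prof[length(prof)]) / 2
  if (prof[ip] <= baseline)
    stopCond("echomapNoCrossingError", "flat profile: no half-maximum crossing")
  profileWidth(prof, ip, 0.5, baseline = baseline,
               refine = if (interp == "spline") 16L else 1L)
}

#' Mean squared error between two images
#'
#' @param X,Y same-shape matrices (conventionally 8-bit display images).
#' @return Mean of squared pixel differences.
#' @export
mseMetric <- function(X, Y) {
  if (!identical(dim(X), dim(Y)))
    stopCond("echomapUsageError", "images must share dimensions")
  mean((X - Y)^2)
}

#' Peak signal-to-noise ratio
#'
#' \deqn{PSNR = 10 \log_{10}(MAX_I^2 / MSE)} with \eqn{MAX_I = 255} for
#' 8-bit images. Identical images give \code{Inf}.
#'
#' @inheritParams mseMetric
#' @param maxValue peak representable value (default 255).
#' @return PSNR in dB (\code{Inf} when MSE is 0).
#' @export
psnrMetric <- function(X, Y, maxValue = 255) {
  m <- mseMetric(X, Y)
  if (m == 0) return(Inf)
  10 * log10(maxValue^2 / m)
}

#' Diagonal-joint mutual information of two 8-bit images
#'
#' Histogram formulation over pixel value k = 0..255 with marginals
#' \eqn{P_X(k)}, \eqn{P_Y(k)} and the diagonal joint \eqn{P_{XY}(k)} = the
#' fraction of pixel positions where both images equal k:
#' \deqn{MI = \sum_k P_{XY}(k) \log \frac{P_{XY}(k)}{P_X(k) P_Y(k)}}
#' Terms with \eqn{P_{XY}(k) = 0} contribute 0. When \code{Y = X} this
#' equals the histogram entropy of X. \code{full = TRUE} computes the
#' conventional full-joint mutual information over all (j, k) pairs for
#' reference.
#'
#' @param X,Y same-shape matrices of integer display values in [0, 255].
#' @param logBase logarithm base (default 2).
#' @param full use the full 256x256 joint histogram instead of its
#'   diagonal.
#' @return Mutual information value.
#' @export
mutualInformationDiagonal <- function(X, Y, logBase = 2, full = FALSE) {
  if (!identical(dim(X), dim(Y)))
    stopCond("echomapUsageError", "images must share dimensions")
  xi <- as.integer(round(X)); yi <- as.integer(round(Y))
  n <- length(xi)
  px <- tabulate(xi + 1L, 256L) / n
  py <- tabulate(yi + 1L, 256L) / n
  if (full) {
    joint <- table(factor(xi, levels = 0:255), factor(yi, levels = 0:255)) / n
    pxy <- as.numeric(joint)
    pij <- outer(px, py)
    keep <- pxy > 0
    return(sum(pxy[keep] * log(pxy[keep] / pij[keep], base = logBase)))
  }
  pxy <- tabulate(ifelse(xi == yi, xi + 1L, 0L), 256L) / n
  keep <- pxy > 0
  sum(pxy[keep] * log(pxy[keep] / (px[keep] * py[keep]), base = logBase))
}

#' Assemble the full metric suite for one reconstruction
#'
#' Computes CR and CNR from the cyst/background ROIs, lateral and axial
#' FWHM from the wire ROI, and (when a ground truth is supplied) MSE, PSNR,
#' SSIM, MS-SSIM and mutual information on the 8-bit display images.
#'
#' @param inputBmode display-domain input image (kept in the metadata).
#' @param reconstruction display-domain reconstructed image.
#' @param groundTruth optional display-domain ground truth; full-reference
#'   fields are \code{NA} without it.
#' @param rois named list with boxes \code{cyst}, \code{background} and
#'   optionally \code{wire} (each \code{c(top, left, height, width)}).
#' @return A \linkS4class{MetricsReport}.
#' @export
evaluateReconstruction <- function(inputBmode, reconstruction,
                                   groundTruth = NULL, rois) {
  if (is.null(rois$cyst) || is.null(rois$background))
    stopCond("echomapConfigError", "rois must include 'cyst' and 'background'")
  crv <- contrastRatio(reconstruction, rois$cyst, rois$background)
  cnrv <- cnr(reconstruction, rois$cyst, rois$background)
  fl <- fa <- NA_real_
  if (!is.null(rois$wire)) {
    # batch evaluation should survive a washed-out wire; NA marks it
    fl <- tryCatch(fwhm(reconstruction, rois$wire, "lateral"),
                   echomapNoCrossingError = function(e) NA_real_)
    fa <- tryCatch(fwhm(reconstruction, rois$wire, "axial"),
                   echomapNoCrossingError = function(e) NA_real_)
  }
  msev <- psnrv <- ssimv <- msv <- miv <- NA_real_
  if (!is.null(groundTruth)) {
    msev <- mseMetric(groundTruth, reconstruction)
    psnrv <- psnrMetric(groundTruth, reconstruction)
    ssimv <- ssimMetric(groundTruth, reconstruction)
    msv <- tryCatch(msSsimMetric(groundTruth, reconstruction),
                    echomapError = function(e) NA_real_)
    miv <- mutualInformationDiagonal(groundTruth, reconstruction)
  }
  new("MetricsReport", cr = crv, cnr = cnrv, fwhmLateral = fl,
      fwhmAxial = fa, mse = msev, psnr = psnrv, ssim = ssimv, msSsim = msv,
      mi = miv,
      metadata = list(rois = rois, domain = "display",
                      hasGroundTruth = !is.null(groundTruth)))
}

#' Derive evaluation ROIs from a map's structure annotations
#'
#' Picks the largest cyst and returns an inscribed square ROI, a
#' same-sized background ROI found by scanning for a structure-free area,
#' and (when present) a box around the first wire point.
#'
#' @param map an \linkS4class{EchogenicityMap}.
#' @param margin border clearance used in the background scan.
#' @return Named list of boxes \code{cyst}, \code{background}, and possibly
#'   \code{wire}.
#' @export
autoRois <- function(map, margin = 8) {
  st <- map@structures
  cysts <- st[st$kind == "cyst", , drop = FALSE]
  if (nrow(cysts) == 0)
    stopCond("echomapConfigError", "map has no cyst to evaluate")
  cy <- cysts[which.max(cysts$radius), ]
  side <- max(3L, floor(2 * cy$radius / sqrt(2)) - 2L)
  cystBox <- c(round(cy$row - side / 2), round(cy$col - side / 2), side, side)
  # scan for a free background patch of the same size
  size <- nrow(map@pixels)
  occ <- map@pixels != 1
  bgBox <- NULL
  step <- max(2L, side %/% 2L)
  for (top in seq(margin + 1, size - margin - side, by = step)) {
    for (left in seq(margin + 1, size - margin - side, by = step)) {
      if (!any(occ[top:(top + side - 1), left:(left + side - 1)])) {
        bgBox <- c(top, left, side, side)
        break
      }
    }
    if (!is.null(bgBox)) break
  }
  if (is.null(bgBox))
    stopCond("echomapConfigError", "no structure-free background patch found")
  out <- list(cyst = cystBox, background = bgBox)
  pts <- st[st$kind == "point", , drop = FALSE]
  if (nrow(pts) > 0) {
    half <- 8L
    top <- min(max(1, pts$row[1] - half), size - 2 * half)
    left <- min(max(1, pts$col[1] - half), size - 2 * half)
    out$wire <- c(top, left, 2 * half + 1, 2 * half + 1)
  }
  out
}
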