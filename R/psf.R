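#' @include AllClasses.R utils.R simulator.R
NULL

# Sub-pixel width of a 1-D profile at `frac` times its peak: the profile is
# upsampled 16x with a cubic spline (plain linear interpolation of a
# sampled Gaussian biases the width by several percent at sigma ~ 1 px),
# then the left/right threshold crossings around the peak are located by
# linear interpolation on the dense grid.
profileWidth <- function(prof, ip, frac, baseline = 0, refine = 16L) {
  prof <- prof - baseline
  pos <- seq_along(prof)
  if (refine > 1L) {
    ss <- stats::spline(pos, prof, n = (length(prof) - 1L) * refine + 1L)
    # track the peak on the dense grid near the coarse peak
    nearby <- which(abs(ss$x - ip) <= 1)
    ipd <- nearby[which.max(ss$y[nearby])]
    pos <- ss$x; prof <- ss$y; ip <- ipd
  }
  thr <- prof[ip] * frac
  n <- length(prof)
  if (ip <= 1L || ip >= n)
    stopCond("echomapNoCrossingError",
             "profile peak lies on the ROI border; widen the ROI")
  left <- NA_real_
  for (i in seq(ip, 2)) {
    if (prof[i - 1] < thr && prof[i] >= thr) {
      left <- pos[i - 1] + (thr - prof[i - 1]) / (prof[i] - prof[i - 1]) *
        (pos[i] - pos[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(ip, n - 1)) {
    if (prof[i] >= thr && prof[i + 1] < thr) {
      right <- pos[i] + (prof[i] - thr) / (prof[i] - prof[i + 1]) *
        (pos[i + 1] - pos[i])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stopCond("echomapNoCrossingError",
             "profile never falls below the threshold inside the ROI")
  right - left
}

#' Estimate the PSF size of an image from wire-target regions
#'
#' For each wire ROI the dominant peak is located, axial and lateral
#' profiles are taken through it, and the left/right crossings of the
#' \code{-threshold_dB} level (relative to the peak) are found by linear
#' interpolation; the crossing distance is the per-axis width. Widths are
#' averaged across ROIs.
#'
#' @param image 2-D amplitude matrix (rows axial, columns lateral). If
#'   \code{domain = "display"} the image is first linearized with
#'   \code{\link{displayToLinear}}.
#' @param rois list of ROI boxes, each \code{c(top, left, height, width)} in
#'   pixels (1-based).
#' @param thresholdDb width measurement level below the peak, in dB
#'   (default 6).
#' @param domain \code{"linear"} (default) or \code{"display"}.
#' @param dynamicRange display dynamic range used when
#'   \code{domain = "display"}.
#' @param smooth logical; locate each ROI's peak on a 3x3-mean-filtered
#'   copy for robustness to speckle spikes (widths are still measured on
#'   the raw profiles; off by default).
#' @return A \linkS4class{PSFSpec} with the across-ROI mean widths.
#' @examples
#' psf <- PSFSpec(6.2, 2.8)
#' k <- gaussianPsfKernel(psf)
#' img <- matrix(0, 64, 64); img[33 - nrow(k) %/% 2 + seq_len(nrow(k)) - 1,
#'   33 - ncol(k) %/% 2 + seq_len(ncol(k)) - 1] <- k
#' estimatePsfSize(img, list(c(17, 17, 32, 32)))
#' @export
estimatePsfSize <- function(image, rois, thresholdDb = 6,
                            domain = c("linear", "display"),
                            dynamicRange = 60, smooth = FALSE) {
  domain <- match.arg(domain)
  if (length(rois) == 0)
    stopCond("echomapUsageError", "at least one wire ROI is required")
  if (domain == "display") image <- displayToLinear(image, dynamicRange)
  peakImage <- image
  if (smooth) {
    km <- matrix(1 / 9, 3, 3)
    peakImage <- Re(convolveSame(image + 0i, km))
  }
  frac <- 10^(-thresholdDb / 20)
  lat <- ax <- numeric(0)
  for (roi in rois) {
    roi <- as.numeric(roi)
    rows <- roi[1] + seq_len(roi[3]) - 1
    cols <- roi[2] + seq_len(roi[4]) - 1
    if (min(rows) < 1 || min(cols) < 1 || max(rows) > nrow(image) ||
        max(cols) > ncol(image))
      stopCond("echomapUsageError", "ROI outside image")
    sub <- image[rows, cols, drop = FALSE]
    subPeak <- peakImage[rows, cols, drop = FALSE]
    if (max(sub) <= 0)
      stopCond("echomapNoWirePeak", "ROI contains no wire peak")
    pk <- which(subPeak == max(subPeak), arr.ind = TRUE)[1, ]
    if (pk[1] %in% c(1, nrow(sub)) || pk[2] %in% c(1, ncol(sub)))
      stopCond("echomapEdgePeakError", "wire peak lies on the ROI border")
    ax <- c(ax, profileWidth(sub[, pk[2]], pk[1], frac))
    lat <- c(lat, profileWidth(sub[pk[1], ], pk[2], frac))
  }
  PSFSpec(lateral = mean(lat), axial = mean(ax))
}

#' Simulate an isolated wire target for PSF estimation checks
#'
#' Places a single point reflector on an anechoic background and runs the
#' speckle forward model; the envelope of an isolated point is the
#' scatterer magnitude times the Gaussian kernel, so the -6 dB widths equal
#' the programmed PSF sizes up to interpolation error.
#'
#' @param size image side, px.
#' @param psf \linkS4class{PSFSpec} to program.
#' @param seed integer seed.
#' @param amplitude wire reflectivity amplitude.
#' @return A list with \code{image} (envelope matrix) and \code{roi}
#'   (a box centered on the wire).
#' @export
simulateWireImage <- function(size = 64, psf, seed, amplitude = 1) {
  pix <- matrix(0, size, size)
  ctr <- as.integer(size / 2)
  pix[ctr, ctr] <- amplitude
  map <- new("EchogenicityMap", pixels = pix,
             structures = data.frame(kind = "point", level_dB = 0,
                                     row = ctr, col = ctr, radius = NA_real_,
                                     top = NA_real_, left = NA_real_,
                                     height = NA_real_, width = NA_real_),
             comboCyst = 0, comboEdgePoint = 0, seed = as.integer(seed))
  bm <- simulateBmode(map, psf, seed = seed)
  half <- as.integer(min(size / 4, 16))
  list(image = bm@pixels,
       roi = c(ctr - half, ctr - half, 2 * half + 1, 2 * half + 1))
}
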