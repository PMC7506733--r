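#' @include utils.R
NULL

#' Classical despeckling baselines
#'
#' Reference post-processing filters for comparison with the network:
#' non-local means (NLM), Perona-Malik anisotropic diffusion (ADF) and the
#' bilateral filter (BLF). All operate on a 2-D display-domain image (the
#' conventional setting for despeckling log-compressed B-mode images), are
#' exact fixed points on constant images, and never produce values outside
#' the input range.
#'
#' @param image numeric matrix.
#' @name baselines
NULL

# Noise-std estimate for speckled images: the median population std over
# non-overlapping 8x8 blocks. Speckle grain is correlated over the PSF
# scale, so derivative-based estimators underestimate it badly; block stds
# in (mostly homogeneous) B-mode images track the speckle std while the
# median rejects blocks straddling structure boundaries.
estimateNoiseSd <- function(image, block = 8L) {
  H <- nrow(image); W <- ncol(image)
  nr <- H %/% block; nc <- W %/% block
  if (nr < 2 || nc < 2) return(stats::sd(image))
  stats::median(vapply(seq_len(nr * nc), function(k) {
    i <- (k - 1) %% nr; j <- (k - 1) %/% nr
    v <- image[i * block + seq_len(block), j * block + seq_len(block)]
    sqrt(mean((v - mean(v))^2))
  }, numeric(1)))
}

#' @rdname baselines
#' @param patchSize odd patch edge for NLM (default 7).
#' @param searchWindow odd search-window edge for NLM (default 21).
#' @param h NLM filtering strength. When \code{NULL} (default), h is 0.8
#'   times a block-median noise standard-deviation estimate of the image
#'   and the patch distance is offset by the expected noise contribution
#'   \eqn{2\sigma^2} (the standard correction that makes such mid-strength
#'   h effective on correlated speckle); an explicitly supplied h selects
#'   the classic uncorrected weights \eqn{\exp(-\bar d^2 / h^2)}, under
#'   which \eqn{h \to 0} recovers the identity.
#' @return The filtered matrix.
#' @export
nlmFilter <- function(image, patchSize = 7, searchWindow = 21, h = NULL) {
  stopifnot(patchSize %% 2 == 1, searchWindow %% 2 == 1)
  if (searchWindow > min(dim(image)))
    stopCond("echomapUsageError", "search window larger than the image")
  sigma <- 0
  if (is.null(h)) {
    sigma <- estimateNoiseSd(image)
    h <- 0.8 * sigma
  }
  if (h <= 0) h <- .Machine$double.eps
  nlm_cpp(image, as.integer(patchSize), as.integer(searchWindow), h, sigma)
}

#' @rdname baselines
#' @param iterations diffusion iterations (default 30).
#' @param dt explicit time step, must be <= 0.25 for 2-D stability
#'   (default 0.2).
#' @param kappa conduction threshold on the image's value scale (default 30
#'   for 8-bit display images).
#' @param conduction \code{"exponential"} \eqn{g = \exp(-(\nabla/\kappa)^2)}
#'   or \code{"quotient"} \eqn{g = 1/(1+(\nabla/\kappa)^2)}.
#' @export
adfFilter <- function(image, iterations = 30, dt = 0.2, kappa = 30,
                      conduction = c("exponential", "quotient")) {
  conduction <- match.arg(conduction)
  if (dt > 0.25)
    stopCond("echomapStabilityError", "time step must be <= 0.25")
  g <- if (conduction == "exponential") function(d) exp(-(d / kappa)^2)
       else function(d) 1 / (1 + (d / kappa)^2)
  u <- image
  H <- nrow(u); W <- ncol(u)
  for (it in seq_len(iterations)) {
    # 4-neighbour differences with Neumann (replicated) boundaries
    dN <- rbind(u[1, , drop = FALSE], u[-H, , drop = FALSE]) - u
    dS <- rbind(u[-1, , drop = FALSE], u[H, , drop = FALSE]) - u
    dW <- cbind(u[, 1, drop = FALSE], u[, -W, drop = FALSE]) - u
    dE <- cbind(u[, -1, drop = FALSE], u[, W, drop = FALSE]) - u
    u <- u + dt * (g(dN) * dN + g(dS) * dS + g(dW) * dW + g(dE) * dE)
  }
  u
}

#' @rdname baselines
#' @param sigmaSpatial spatial Gaussian sigma in pixels (default 3).
#' @param sigmaRange range Gaussian sigma on the image's value scale
#'   (default 25 for 8-bit display images).
#' @export
blfFilter <- function(image, sigmaSpatial = 3, sigmaRange = 25) {
  if (sigmaSpatial <= 0 || sigmaRange <= 0)
    stopCond("echomapUsageError", "sigmas must be positive")
  bilateral_cpp(image, sigmaSpatial, sigmaRange)
}
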