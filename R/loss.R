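#' @include AllClasses.R utils.R
NULL

ssimWindow <- function(size = 11, sigma = 1.5) {
  t <- seq_len(size) - (size + 1) / 2
  g <- exp(-t^2 / (2 * sigma^2))
  g / sum(g)
}

msSsimWeights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)

# Number of dyadic scales the image size supports with an 11-px window.
msSsimScales <- function(H, W, windowSize = 11, maxScales = 5) {
  m <- 1
  while (m < maxScales && floor(min(H, W) / 2^m) >= windowSize) m <- m + 1
  m
}

# Per-scale SSIM statistics via 'valid' Gaussian windows.
ssimStats <- function(X, Y, g, C1, C2) {
  mx <- sep_corr_valid(X, g); my <- sep_corr_valid(Y, g)
  sxx <- sep_corr_valid(X * X, g) - mx * mx
  syy <- sep_corr_valid(Y * Y, g) - my * my
  sxy <- sep_corr_valid(X * Y, g) - mx * my
  D1 <- mx^2 + my^2 + C1
  D2 <- sxx + syy + C2
  l <- (2 * mx * my + C1) / D1
  cs <- (2 * sxy + C2) / D2
  list(mx = mx, my = my, l = l, cs = cs, D1 = D1, D2 = D2)
}

#' Multi-scale structural similarity (MS-SSIM), optionally with gradient
#'
#' Standard dyadic construction: the contrast/structure term is averaged at
#' every scale, the luminance term only at the coarsest; the index is the
#' weighted product with the standard five-scale weights (0.0448, 0.2856,
#' 0.3001, 0.2363, 0.1333), truncated and renormalized when the image size
#' supports fewer scales (an 11x11 Gaussian window, sigma 1.5, 'valid'
#' support; 2x2 average pooling between scales). When \code{gradient} is
#' requested, the analytic derivative with respect to \code{X} is returned,
#' backpropagated through the windows and the scale pyramid.
#'
#' @param X,Y numeric matrices on the same scale (prediction first).
#' @param dataRange value range L for the stability constants
#'   \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2}; 1 for normalized
#'   images, 255 for 8-bit.
#' @param gradient logical; also return \code{d msSsim / dX}.
#' @return The MS-SSIM value, or (with gradient) a list
#'   \code{list(value, grad)}.
#' @export
msSsim <- function(X, Y, dataRange = 1, gradient = FALSE) {
  if (!identical(dim(X), dim(Y)))
    stopCond("echomapUsageError", "images must share dimensions")
  g <- ssimWindow()
  if (min(dim(X)) < length(g))
    stopCond("echomapUsageError", "image smaller than the 11x11 SSIM window")
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  M <- msSsimScales(nrow(X), ncol(X))
  w <- msSsimWeights[seq_len(M)]
  w <- w / sum(w)
  Xs <- list(X); Ys <- list(Y)
  for (j in seq_len(M - 1)) {
    Xs[[j + 1]] <- avgpool2_m(Xs[[j]])
    Ys[[j + 1]] <- avgpool2_m(Ys[[j]])
  }
  stats <- vector("list", M)
  tbar <- numeric(M)
  for (j in seq_len(M)) {
    st <- ssimStats(Xs[[j]], Ys[[j]], g, C1, C2)
    stats[[j]] <- st
    tbar[j] <- if (j < M) mean(st$cs) else mean(st$l * st$cs)
  }
  tcl <- pmax(tbar, 1e-4)   # guard the power for rare non-positive means
  value <- prod(tcl^w)
  if (!gradient) return(value)

  grad <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(M)) {
    st <- stats[[j]]
    npix <- length(st$cs)
    dt <- if (tbar[j] > 1e-4) value * w[j] / tcl[j] / npix else 0
    if (identical(dt, 0)) next
    if (j < M) {
      a <- matrix(0, nrow(st$cs), ncol(st$cs))
      bcoef <- (-st$cs / st$D2) * dt
      ccoef <- (2 / st$D2) * dt
    } else {
      a <- (st$cs * 2 * (st$my - st$l * st$mx) / st$D1) * dt
      bcoef <- (st$l * (-st$cs) / st$D2) * dt
      ccoef <- (st$l * 2 / st$D2) * dt
    }
    Xj <- Xs[[j]]; Yj <- Ys[[j]]
    dXj <- sep_conv_full(a, g) +
      2 * Xj * sep_conv_full(bcoef, g) -
      2 * sep_conv_full(bcoef * st$mx, g) +
      Yj * sep_conv_full(ccoef, g) -
      sep_conv_full(ccoef * st$my, g)
    # chain back up the scale pyramid
    if (j > 1)
      for (s in seq(j - 1, 1))
        dXj <- avgpool2_adj(dXj, nrow(Xs[[s]]), ncol(Xs[[s]]))
    grad <- grad + dXj
  }
  list(value = value, grad = grad)
}

#' Single-scale structural similarity (SSIM)
#'
#' Standard SSIM index with an 11x11 Gaussian window (sigma 1.5), stability
#' constants K1 = 0.01, K2 = 0.03, averaged over the valid window support.
#'
#' @inheritParams msSsim
#' @return SSIM value in [-1, 1].
#' @export
ssimMetric <- function(X, Y, dataRange = 255) {
  if (!identical(dim(X), dim(Y)))
    stopCond("echomapUsageError", "images must share dimensions")
  g <- ssimWindow()
  if (min(dim(X)) < length(g))
    stopCond("echomapUsageError", "image smaller than the 11x11 SSIM window")
  st <- ssimStats(X, Y, g, (0.01 * dataRange)^2, (0.03 * dataRange)^2)
  mean(st$l * st$cs)
}

#' @rdname ssimMetric
#' @export
msSsimMetric <- function(X, Y, dataRange = 255) msSsim(X, Y, dataRange)

#' Mixed L1 + MS-SSIM training loss
#'
#' \deqn{L_{mixed} = L_{\ell 1} + \beta \, L_{MS\textrm{-}SSIM}} with
#' \eqn{L_{\ell 1}} the mean absolute error and
#' \eqn{L_{MS\textrm{-}SSIM} = 1 - \mathrm{MSSSIM}(prediction, target)}.
#'
#' @param prediction,target same-shape matrices in [0, 1].
#' @param beta MS-SSIM weight (default 300).
#' @return Scalar loss (>= 0; 0 iff the images are identical).
#' @examples
#' x <- matrix(runif(64 * 64), 64)
#' mixedLoss(x, x)       # 0
#' @export
mixedLoss <- function(prediction, target, beta = 300) {
  if (!identical(dim(prediction), dim(target)))
    stopCond("echomapUsageError", "images must share dimensions")
  l1 <- mean(abs(prediction - target))
  if (beta == 0) return(l1)
  l1 + beta * (1 - msSsim(prediction, target, dataRange = 1))
}

# Loss + gradient for a batch array (H, W, 1, N); used by the trainer.
batchLossGrad <- function(pred, target, loss, beta) {
  N <- dim(pred)[4]
  npx <- length(pred)
  if (loss == "mse") {
    diff <- pred - target
    list(value = mean(diff^2), grad = 2 * diff / npx)
  } else {
    diff <- pred - target
    l1 <- mean(abs(diff))
    grad <- sign(diff) / npx
    msTotal <- 0
    for (n in seq_len(N)) {
      ms <- msSsim(pred[, , 1, n], target[, , 1, n], dataRange = 1,
                   gradient = TRUE)
      msTotal <- msTotal + ms$value
      grad[, , 1, n] <- grad[, , 1, n] - beta * ms$grad / N
    }
    list(value = l1 + beta * (1 - msTotal / N), grad = grad)
  }
}
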