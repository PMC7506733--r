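#' @include AllClasses.R utils.R
NULL

#' Network architecture configuration
#'
#' The residual U-net has a fixed depth of five encoder blocks; the feature
#' counts are \code{minFilters * 2^k} for k = 0..4 (so 32 min filters gives
#' the channel sequence 32, 64, 128, 256, 512). All conv layers use square
#' kernels of \code{filterSize} except the fixed 2x2 transpose convolutions
#' and the final 1x1 residual head.
#'
#' @param minFilters filters in the first encoder block (16 or 32 for
#'   parity with the reference settings; any positive integer is allowed).
#' @param filterSize odd conv kernel edge (3, 5 or 7 for parity).
#' @return A list with class \code{"echomapNetworkConfig"}.
#' @export
networkConfig <- function(minFilters = 32, filterSize = 3) {
  stopifnot(minFilters >= 1, filterSize %% 2 == 1)
  structure(list(minFilters = as.integer(minFilters),
                 filterSize = as.integer(filterSize),
                 depth = 5L, inChannels = 1L, outChannels = 1L),
            class = "echomapNetworkConfig")
}

#' Training configuration
#'
#' @param loss \code{"mixed"} (L1 + beta * MS-SSIM loss, Adam at a constant
#'   learning rate) or \code{"mse"} (Adam with a step-decay schedule, x0.5
#'   every 10 epochs).
#' @param beta weight of the MS-SSIM term in the mixed loss (default 300).
#' @param initialLr initial learning rate.
#' @param batchSize minibatch size (default 8).
#' @param epochs training epochs (default 30).
#' @param seed integer seed controlling weight init and batch shuffling.
#' @return A list with class \code{"echomapTrainingConfig"}.
#' @export
trainingConfig <- function(loss = c("mixed", "mse"), beta = 300,
                           initialLr = 0.00035, batchSize = 8, epochs = 30,
                           seed = 1) {
  loss <- match.arg(loss)
  stopifnot(beta > 0, initialLr > 0, batchSize >= 1, epochs >= 1)
  structure(list(loss = loss, beta = beta, initialLr = initialLr,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "echomapTrainingConfig")
}

# He-normal init for a conv weight (kh, kw, cin, cout)
heInit <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

newBn <- function(params, prefix, c) {
  params[[paste0(prefix, "_g")]] <- rep(1, c)
  params[[paste0(prefix, "_be")]] <- rep(0, c)
  params[[paste0(prefix, "_rm")]] <- rep(0, c)
  params[[paste0(prefix, "_rv")]] <- rep(1, c)
  params
}

#' Build an untrained residual U-net
#'
#' Encoder: block 1 has three same-padded convolutions; blocks 2-5 prepend
#' a 2x2 max pooling. Every convolution is followed by batch normalization
#' and ReLU. Decoder: four blocks of a 2x2 stride-2 transpose convolution
#' (halving the channels), concatenation with the equal-size encoder
#' output, and two convolutions. A final 1x1 convolution produces the
#' residual r(x); the model output is f(x) = r(x) + x. The residual head is
#' zero-initialized so the untrained network is the identity mapping.
#'
#' @param config a \code{\link{networkConfig}}.
#' @param seed integer seed for weight initialization.
#' @return A named list of parameter arrays (an untrained parameter set for
#'   \code{\link{trainUnet}}).
#' @export
buildUnet <- function(config, seed = 1) {
  stopifnot(inherits(config, "echomapNetworkConfig"))
  k <- config$filterSize
  cs <- config$minFilters * 2L^(0:4)
  withSeed(seed, {
    p <- list()
    cin <- config$inChannels
    for (b in 1:5) {
      for (l in 1:3) {
        cout <- cs[b]
        nm <- sprintf("e%dc%d", b, l)
        p[[paste0(nm, "_w")]] <- heInit(k, k, cin, cout)
        p[[paste0(nm, "_b")]] <- rep(0, cout)
        p <- newBn(p, nm, cout)
        cin <- cout
      }
    }
    for (b in 1:4) {
      cupIn <- cs[6 - b]    # 512 -> ... entering decoder block b
      cup <- cs[5 - b]      # after transpose conv
      nm <- sprintf("d%dup", b)
      p[[paste0(nm, "_w")]] <- heInit(2, 2, cupIn, cup)
      p[[paste0(nm, "_b")]] <- rep(0, cup)
      p <- newBn(p, nm, cup)
      cin <- 2L * cup       # after skip concatenation
      for (l in 1:2) {
        nm <- sprintf("d%dc%d", b, l)
        p[[paste0(nm, "_w")]] <- heInit(k, k, cin, cup)
        p[[paste0(nm, "_b")]] <- rep(0, cup)
        p <- newBn(p, nm, cup)
        cin <- cup
      }
    }
    p[["out_w"]] <- array(0, c(1, 1, cs[1], 1))  # zero-init residual head
    p[["out_b"]] <- 0
    p
  })
}

#' Number of trainable parameters of a U-net parameter set
#'
#' @param params list from \code{\link{buildUnet}}.
#' @return Integer count (conv weights, biases and batch-norm scale/shift;
#'   running statistics excluded).
#' @export
countParameters <- function(params) {
  nm <- names(params)
  keep <- !grepl("_rm$|_rv$", nm)
  sum(vapply(params[keep], length, numeric(1)))
}

convBnRelu <- function(params, nm, x, training, transpose = FALSE) {
  if (transpose)
    z <- upconv_fwd(x, params[[paste0(nm, "_w")]], params[[paste0(nm, "_b")]])
  else
    z <- conv_fwd(x, params[[paste0(nm, "_w")]], params[[paste0(nm, "_b")]])
  bn <- bn_fwd(z, params[[paste0(nm, "_g")]], params[[paste0(nm, "_be")]],
               params[[paste0(nm, "_rm")]], params[[paste0(nm, "_rv")]],
               0.9, 1e-5, training)
  a <- bn$y
  y <- a * (a > 0)
  list(y = y, cache = list(nm = nm, x = x, xhat = bn$xhat,
                           invstd = bn$invstd, mask = (a > 0),
                           transpose = transpose),
       rmean = bn$rmean, rvar = bn$rvar)
}

concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  z <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  z[, , seq_len(da[3]), ] <- a
  z[, , da[3] + seq_len(db[3]), ] <- b
  z
}

# Forward pass. x: array (H, W, 1, N). Returns f(x) = r(x) + x plus caches
# for backprop; when training, updated BN running stats are collected.
unetForward <- function(params, x, training = FALSE) {
  H <- dim(x)[1]
  if (H %% 16 != 0 || dim(x)[2] %% 16 != 0)
    stopCond("echomapShapeError",
             "input sides must be divisible by 16 (got %dx%d); reflect-pad to the next multiple",
             H, dim(x)[2])
  caches <- list()
  running <- list()
  encOut <- vector("list", 5)
  h <- x
  for (b in 1:5) {
    if (b > 1) {
      mp <- maxpool_fwd(h)
      caches[[length(caches) + 1]] <- list(type = "pool", b = b,
                                           idx = mp$idx, H = dim(h)[1],
                                           W = dim(h)[2])
      h <- mp$y
    }
    for (l in 1:3) {
      nm <- sprintf("e%dc%d", b, l)
      cb <- convBnRelu(params, nm, h, training)
      caches[[length(caches) + 1]] <- c(cb$cache, type = "conv")
      running[[paste0(nm, "_rm")]] <- cb$rmean
      running[[paste0(nm, "_rv")]] <- cb$rvar
      h <- cb$y
    }
    encOut[[b]] <- h
  }
  for (b in 1:4) {
    nm <- sprintf("d%dup", b)
    cb <- convBnRelu(params, nm, h, training, transpose = TRUE)
    caches[[length(caches) + 1]] <- c(cb$cache, type = "conv")
    running[[paste0(nm, "_rm")]] <- cb$rmean
    running[[paste0(nm, "_rv")]] <- cb$rvar
    up <- cb$y
    skip <- encOut[[5 - b]]
    h <- concatChannels(up, skip)
    caches[[length(caches) + 1]] <- list(type = "concat", b = b,
                                         cUp = dim(up)[3],
                                         cSkip = dim(skip)[3])
    for (l in 1:2) {
      nm <- sprintf("d%dc%d", b, l)
      cb <- convBnRelu(params, nm, h, training)
      caches[[length(caches) + 1]] <- c(cb$cache, type = "conv")
      running[[paste0(nm, "_rm")]] <- cb$rmean
      running[[paste0(nm, "_rv")]] <- cb$rvar
      h <- cb$y
    }
  }
  r <- conv_fwd(h, params[["out_w"]], params[["out_b"]])
  caches[[length(caches) + 1]] <- list(type = "out", x = h)
  list(out = r + x, caches = caches, running = running)
}

# Backward pass for d(loss)/d(output); returns gradient list keyed like the
# parameter list. Skip connections accumulate gradients into the encoder
# branch via dSkip.
unetBackward <- function(params, fw, dOut) {
  grads <- list()
  caches <- fw$caches
  i <- length(caches)
  # residual head
  cc <- caches[[i]]; i <- i - 1
  g <- conv_bwd(cc$x, params[["out_w"]], dOut)
  grads[["out_w"]] <- g$dw
  grads[["out_b"]] <- g$db
  dh <- g$dx
  dSkip <- vector("list", 5)   # pending gradients for encoder outputs
  while (i >= 1) {
    cc <- caches[[i]]
    if (cc$type == "conv") {
      nm <- cc$nm
      da <- dh * cc$mask
      bn <- bn_bwd(cc$xhat, cc$invstd, params[[paste0(nm, "_g")]], da)
      grads[[paste0(nm, "_g")]] <- bn$dgamma
      grads[[paste0(nm, "_be")]] <- bn$dbeta
      if (isTRUE(cc$transpose))
        g <- upconv_bwd(cc$x, params[[paste0(nm, "_w")]], bn$dx)
      else
        g <- conv_bwd(cc$x, params[[paste0(nm, "_w")]], bn$dx)
      grads[[paste0(nm, "_w")]] <- g$dw
      grads[[paste0(nm, "_b")]] <- g$db
      dh <- g$dx
    } else if (cc$type == "pool") {
      dh <- maxpool_bwd(cc$idx, dh, cc$H, cc$W)
      # dh now sits at the output of encoder block (b-1); add pending skip grad
      b <- cc$b - 1L
      if (!is.null(dSkip[[b]])) {
        dh <- dh + dSkip[[b]]
        dSkip[b] <- list(NULL)
      }
    } else if (cc$type == "concat") {
      cUp <- cc$cUp
      dUp <- dh[, , seq_len(cUp), , drop = FALSE]
      dS <- dh[, , cUp + seq_len(cc$cSkip), , drop = FALSE]
      dSkip[[5 - cc$b]] <- dS
      dh <- dUp
    }
    i <- i - 1
  }
  # the input feeds the residual addition: total dx = dh + dOut (unused here)
  grads
}

#' @describeIn despeckle apply a trained model to a BModeImage
#' @export
setMethod("despeckle", signature(model = "UNetModel", image = "BModeImage"),
  function(model, image, clip = FALSE) {
    if (image@normalized != model@normalization)
      stopCond("echomapUsageError",
               "image normalization '%s' does not match the model's training normalization '%s'",
               image@normalized, model@normalization)
    despeckleMatrix(model, image@pixels, clip = clip)
  })

#' @describeIn despeckle apply a trained model to a plain matrix (assumed
#'   normalized like the training data)
#' @export
setMethod("despeckle", signature(model = "UNetModel", image = "matrix"),
  function(model, image, clip = FALSE) {
    despeckleMatrix(model, image, clip = clip)
  })

despeckleMatrix <- function(model, pixels, clip = FALSE) {
  H <- nrow(pixels); W <- ncol(pixels)
  Hp <- 16L * ceiling(H / 16L); Wp <- 16L * ceiling(W / 16L)
  x <- pixels
  if (Hp != H || Wp != W) {   # reflect-pad to a multiple of 16, crop after
    x <- rbind(x, x[H - seq_len(Hp - H) + 1L, , drop = FALSE])
    x <- cbind(x, x[, W - seq_len(Wp - W) + 1L, drop = FALSE])
  }
  xa <- array(x, c(Hp, Wp, 1, 1))
  out <- unetForward(model@params, xa, training = FALSE)$out[, , 1, 1]
  out <- out[seq_len(H), seq_len(W)]
  if (clip) out <- clamp01(out)
  out
}
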