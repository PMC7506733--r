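#' @include AllClasses.R unet.R loss.R dataset.R
NULL

adamInit <- function(params, trainable) {
  list(m = lapply(params[trainable], function(p) p * 0),
       v = lapply(params[trainable], function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

evalLoss <- function(params, dataset, idx, loss, beta, batchSize) {
  H <- dim(dataset@bmode)[1]; W <- dim(dataset@bmode)[2]
  total <- 0
  nb <- 0
  for (start in seq(1, length(idx), by = batchSize)) {
    take <- idx[start:min(start + batchSize - 1, length(idx))]
    x <- array(dataset@bmode[, , take], c(H, W, 1, length(take)))
    y <- array(dataset@truth[, , take], c(H, W, 1, length(take)))
    out <- unetForward(params, x, training = FALSE)$out
    total <- total + batchLossGrad(out, y, loss, beta)$value * length(take)
    nb <- nb + length(take)
  }
  total / nb
}

#' Train the residual U-net on a simulation dataset
#'
#' Minibatch training with the configured loss: the mixed option uses Adam
#' at a constant learning rate; the MSE option uses Adam with a step-decay
#' schedule (learning rate halved every 10 epochs). Batches are reshuffled
#' every epoch from the training split; per-epoch training and validation
#' losses are recorded.
#'
#' @param dataset a \linkS4class{SpeckleDataset} with both splits.
#' @param netConfig a \code{\link{networkConfig}}.
#' @param trainConfig a \code{\link{trainingConfig}}.
#' @param verbose print per-epoch losses.
#' @return A trained \linkS4class{UNetModel}.
#' @export
trainUnet <- function(dataset, netConfig, trainConfig, verbose = FALSE) {
  stopifnot(is(dataset, "SpeckleDataset"),
            inherits(netConfig, "echomapNetworkConfig"),
            inherits(trainConfig, "echomapTrainingConfig"))
  trainIdx <- splitIndices(dataset, "train")
  valIdx <- splitIndices(dataset, "validation")
  if (length(trainIdx) == 0 || length(valIdx) == 0)
    stopCond("echomapDatasetError", "dataset needs non-empty train and validation splits")
  H <- dim(dataset@bmode)[1]; W <- dim(dataset@bmode)[2]
  params <- buildUnet(netConfig, seed = trainConfig$seed)
  trainable <- names(params)[!grepl("_rm$|_rv$", names(params))]
  state <- adamInit(params, trainable)
  bs <- trainConfig$batchSize
  history <- data.frame(epoch = integer(0), train = numeric(0),
                        val = numeric(0))
  shuffleSeeds <- deriveSeeds(trainConfig$seed + 1L, trainConfig$epochs)
  for (epoch in seq_len(trainConfig$epochs)) {
    lr <- trainConfig$initialLr
    if (trainConfig$loss == "mse")
      lr <- lr * 0.5^((epoch - 1) %/% 10)   # step decay
    perm <- withSeed(shuffleSeeds[epoch], sample(trainIdx))
    epochLoss <- 0
    nSeen <- 0
    for (start in seq(1, length(perm), by = bs)) {
      take <- perm[start:min(start + bs - 1, length(perm))]
      x <- array(dataset@bmode[, , take], c(H, W, 1, length(take)))
      y <- array(dataset@truth[, , take], c(H, W, 1, length(take)))
      fw <- unetForward(params, x, training = TRUE)
      for (nm in names(fw$running)) params[[nm]] <- fw$running[[nm]]
      lg <- batchLossGrad(fw$out, y, trainConfig$loss, trainConfig$beta)
      if (!is.finite(lg$value))
        stopCond("echomapDivergenceError",
                 "non-finite loss at epoch %d; lower the learning rate", epoch)
      grads <- unetBackward(params, fw, lg$grad)
      st <- adamStep(params, grads, state, lr)
      params <- st$params
      state <- st$state
      epochLoss <- epochLoss + lg$value * length(take)
      nSeen <- nSeen + length(take)
    }
    valLoss <- evalLoss(params, dataset, valIdx, trainConfig$loss,
                        trainConfig$beta, bs)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train = epochLoss / nSeen,
                                         val = valLoss))
    if (verbose)
      message(sprintf("epoch %d/%d  train %.5g  val %.5g  (lr %.3g)",
                      epoch, trainConfig$epochs, epochLoss / nSeen,
                      valLoss, lr))
  }
  new("UNetModel", params = params, netConfig = unclass(netConfig),
      trainConfig = unclass(trainConfig), psf = dataset@psf,
      normalization = dataset@normalization, history = history)
}
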