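test_that("encoder channels follow the proportional doubling rule", {
  p32 <- buildUnet(networkConfig(minFilters = 32), seed = 1)
  chans <- vapply(1:5, function(b) dim(p32[[sprintf("e%dc1_w", b)]])[4],
                  numeric(1))
  expect_equal(chans, c(32, 64, 128, 256, 512))
  p16 <- buildUnet(networkConfig(minFilters = 16), seed = 1)
  expect_equal(dim(p16$e5c3_w)[4], 256)
  # decoder halves the channels back down to minFilters
  expect_equal(dim(p16$d4c2_w)[4], 16)
  expect_equal(dim(p16$out_w), c(1, 1, 16, 1))
})

test_that("the zero-initialized residual head makes f(x) = x exactly", {
  p <- buildUnet(networkConfig(minFilters = 4), seed = 2)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  out <- EchoMap:::unetForward(p, x, training = FALSE)$out
  expect_identical(out, x)
})

test_that("parameter count scales about fourfold with minFilters doubling", {
  n8 <- countParameters(buildUnet(networkConfig(minFilters = 8), seed = 1))
  n16 <- countParameters(buildUnet(networkConfig(minFilters = 16), seed = 1))
  expect_gt(n16 / n8, 3.5)
  expect_lt(n16 / n8, 4.0)
  # count is a pure function of the configuration
  expect_equal(n8, countParameters(buildUnet(networkConfig(minFilters = 8),
                                             seed = 99)))
})

test_that("inputs not divisible by 16 raise a shape error with guidance", {
  p <- buildUnet(networkConfig(minFilters = 2), seed = 1)
  x <- array(runif(24 * 24), c(24, 24, 1, 1))
  expect_error(EchoMap:::unetForward(p, x), class = "echomapShapeError")
  expect_error(EchoMap:::unetForward(p, x), regexp = "pad")
})

test_that("mixed loss obeys its oracle values", {
  x <- matrix(runif(64 * 64), 64)
  expect_equal(mixedLoss(x, x, beta = 300), 0)
  expect_equal(mixedLoss(pmin(x, 0.9) + 0.1, pmin(x, 0.9), beta = 0), 0.1,
               tolerance = 1e-12)
  expect_equal(formals(mixedLoss)$beta, 300)
  # non-negativity over random pairs, zero iff identical
  for (s in 1:5) {
    set.seed(s)
    a <- matrix(runif(32 * 32), 32)
    b <- matrix(runif(32 * 32), 32)
    expect_gt(mixedLoss(a, b), 0)
  }
  expect_error(mixedLoss(x, x[1:32, ]), class = "echomapUsageError")
})

test_that("the analytic MS-SSIM gradient matches finite differences", {
  set.seed(7)
  X <- matrix(runif(32 * 32), 32)
  Y <- matrix(runif(32 * 32), 32)
  ms <- msSsim(X, Y, gradient = TRUE)
  expect_equal(ms$value, msSsim(X, Y))
  eps <- 1e-6
  for (i in sample(length(X), 8)) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    fd <- (msSsim(Xp, Y) - msSsim(Xm, Y)) / (2 * eps)
    expect_equal(ms$grad[i], fd, tolerance = 1e-4)
  }
})

test_that("a tiny training run learns and keeps honest bookkeeping", {
  ds <- buildDataset(PSFSpec(3, 3), pairsPerCombo = 2, size = 32,
                     masterSeed = 5)
  tc <- trainingConfig(loss = "mixed", beta = 300, initialLr = 1e-3,
                       batchSize = 8, epochs = 4, seed = 2)
  m <- trainUnet(ds, networkConfig(minFilters = 4), tc)
  h <- lossHistory(m)
  expect_equal(nrow(h), 4)
  expect_true(all(is.finite(h$train)) && all(is.finite(h$val)))
  expect_lt(h$train[4], h$train[1])
  # reconstruction has the input's shape; despeckle pads odd sizes
  rec <- despeckle(m, ds@bmode[, , 1])
  expect_equal(dim(rec), c(32, 32))
  rec2 <- despeckle(m, ds@bmode[1:24, 1:30, 1])
  expect_equal(dim(rec2), c(24, 30))
})

test_that("training is deterministic under identical seeds", {
  ds <- buildDataset(PSFSpec(3, 3), pairsPerCombo = 1, size = 32,
                     masterSeed = 6)
  tc <- trainingConfig(loss = "mse", initialLr = 1e-3, batchSize = 8,
                       epochs = 2, seed = 3)
  m1 <- trainUnet(ds, networkConfig(minFilters = 2), tc)
  m2 <- trainUnet(ds, networkConfig(minFilters = 2), tc)
  expect_equal(lossHistory(m1)$val, lossHistory(m2)$val, tolerance = 1e-6)
})

test_that("despeckle checks the normalization contract", {
  ds <- buildDataset(PSFSpec(3, 3), pairsPerCombo = 1, size = 32,
                     masterSeed = 6)
  tc <- trainingConfig(loss = "mse", initialLr = 1e-3, epochs = 1, seed = 3)
  m <- trainUnet(ds, networkConfig(minFilters = 2), tc)
  raw <- new("BModeImage", pixels = matrix(0.5, 32, 32), psf = PSFSpec(3, 3),
             normalized = "theoretical", logCompressed = FALSE,
             dynamicRange = NA_real_, seed = 1L)
  expect_error(despeckle(m, raw), class = "echomapUsageError")
})
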