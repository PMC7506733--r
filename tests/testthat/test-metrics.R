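test_that("ROI statistics use the population standard deviation", {
  img <- matrix(7, 5, 5)
  expect_equal(roiStats(img, c(1, 1, 5, 5)), c(mean = 7, sd = 0))
  img2 <- matrix(c(9, 11), 1, 2)
  expect_equal(roiStats(img2, c(1, 1, 1, 2)), c(mean = 10, sd = 1))
  expect_equal(roiStats(img2, c(1, 1, 1, 1)), c(mean = 9, sd = 0))
  expect_error(roiStats(img, c(1, 1, 0, 2)), class = "echomapUsageError")
})

test_that("contrast ratio is a signed difference of ROI means", {
  img <- matrix(8, 10, 10)
  img[1:5, ] <- 10
  a <- c(1, 1, 5, 10); b <- c(6, 1, 5, 10)
  expect_equal(contrastRatio(img, a, b), 2)
  expect_equal(contrastRatio(img, b, a), -2)
  expect_equal(contrastRatio(img, a, a), 0)
})

test_that("CNR matches hand values and degenerates loudly", {
  img <- rbind(matrix(c(9, 11), 2, 10), matrix(c(7, 9), 2, 10))
  a <- c(1, 1, 2, 10); b <- c(3, 1, 2, 10)  # means 10/8, sds 1/1
  expect_equal(cnr(img, a, b), 2 / sqrt(2))
  expect_equal(cnr(img, a, a), 0)
  expect_error(cnr(matrix(5, 4, 4), c(1, 1, 2, 2), c(3, 3, 2, 2)),
               class = "echomapUndefinedCnr")
})

test_that("CR and CNR are invariant under the expected transforms", {
  set.seed(3)
  img <- matrix(runif(400, 10, 60), 20)
  a <- c(2, 2, 8, 8); b <- c(12, 12, 8, 8)
  expect_equal(contrastRatio(img + 17, a, b), contrastRatio(img, a, b))
  expect_equal(cnr(img + 17, a, b), cnr(img, a, b))
  expect_equal(cnr(img * 3.7, a, b), cnr(img, a, b))
})

test_that("FWHM of a sampled Gaussian matches 2.3548 sigma within 1%", {
  for (s in c(1, 2, 4, 8)) {
    n <- 2 * ceiling(8 * s) + 21
    ctr <- (n + 1) / 2
    g <- exp(-((1:n) - ctr)^2 / (2 * s^2))
    img <- outer(g, g)
    w <- fwhm(img, c(1, 1, n, n), "lateral")
    expect_equal(w, 2.3548 * s, tolerance = 0.01)
    expect_equal(fwhm(img, c(1, 1, n, n), "axial"), w, tolerance = 1e-6)
  }
})

test_that("FWHM handles impulses and flat profiles per the classic convention", {
  imp <- matrix(0, 21, 21)
  imp[11, 11] <- 1
  expect_equal(fwhm(imp, c(1, 1, 21, 21), "lateral", interp = "linear"), 1)
  expect_equal(fwhm(imp, c(1, 1, 21, 21), "axial", interp = "linear"), 1)
  expect_error(fwhm(matrix(1, 9, 9), c(1, 1, 9, 9)),
               class = "echomapNoCrossingError")
})

test_that("MSE and PSNR follow their defining identities", {
  X <- matrix(runif(64, 0, 255), 8)
  expect_equal(mseMetric(X, X), 0)
  expect_equal(mseMetric(X + 10, X), 100)
  expect_equal(mseMetric(matrix(c(0, 255), 2, 1), matrix(c(255, 0), 2, 1)),
               65025)
  expect_equal(psnrMetric(matrix(c(0, 255), 2, 1), matrix(c(255, 0), 2, 1)),
               0)
  expect_equal(psnrMetric(X + 10, X), 10 * log10(255^2 / 100))
  expect_identical(psnrMetric(X, X), Inf)
  expect_error(mseMetric(X, X[, 1:4]), class = "echomapUsageError")
  # strictly decreasing in MSE
  offsets <- c(1, 5, 20, 80)
  ps <- vapply(offsets, function(o) psnrMetric(X + o, X), numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("diagonal mutual information matches its closed forms", {
  X <- matrix(rep(0:255, 4), 32, 32)
  expect_equal(mutualInformationDiagonal(X, X), 8)   # log2(256)
  Y <- (X + 1) %% 256
  expect_equal(mutualInformationDiagonal(X, Y), 0)   # never equal
  C <- matrix(7, 16, 16)
  expect_equal(mutualInformationDiagonal(C, C), 0)   # single bin
  # equals the histogram entropy of X whenever Y = X
  set.seed(4)
  img <- matrix(sample(0:255, 900, replace = TRUE, prob = runif(256)), 30)
  px <- tabulate(img + 1L, 256L) / length(img)
  entropy <- -sum(px[px > 0] * log2(px[px > 0]))
  expect_equal(mutualInformationDiagonal(img, img), entropy)
  # full-joint variant agrees with the diagonal when Y = X (diagonal joint)
  expect_equal(mutualInformationDiagonal(img, img, full = TRUE), entropy)
})

test_that("SSIM and MS-SSIM behave like similarity indices", {
  set.seed(5)
  x <- matrix(runif(64 * 64, 60, 200), 64)
  expect_equal(ssimMetric(x, x), 1)
  expect_equal(msSsimMetric(x, x), 1, tolerance = 1e-9)
  expect_equal(ssimMetric(x, 255 - x), ssimMetric(255 - x, x))
  expect_lt(ssimMetric(x, 255 - x), 0.5)
  expect_error(ssimMetric(x[1:8, 1:8], x[1:8, 1:8]),
               class = "echomapUsageError")
})

test_that("evaluateReconstruction assembles a consistent report", {
  fix <- speckledCystDisplay(seed = 51)
  truth <- logCompress(pmin(pixelData(fix$map) / max(pixelData(fix$map)), 1))
  rep1 <- evaluateReconstruction(fix$display, fix$display, truth, fix$rois)
  expect_equal(rep1@psnr, 10 * log10(255^2 / rep1@mse), tolerance = 1e-9)
  expect_false(any(is.na(reportAsDataFrame(rep1)[, c("cr", "cnr", "mse",
                                                     "psnr", "ssim", "mi")])))
  rep2 <- evaluateReconstruction(fix$display, fix$display, NULL, fix$rois)
  expect_true(is.na(rep2@mse) && is.na(rep2@psnr) && is.na(rep2@ssim) &&
                is.na(rep2@mi))
  expect_false(is.na(rep2@cr) || is.na(rep2@cnr))
  expect_error(evaluateReconstruction(fix$display, fix$display, NULL,
                                      list(cyst = c(1, 1, 4, 4))),
               class = "echomapConfigError")
})
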