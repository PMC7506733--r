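test_that("wire-based PSF estimates recover programmed widths", {
  errs <- vapply(1:8, function(s) {
    w <- simulateWireImage(64, PSFSpec(6.2, 2.8), seed = s)
    est <- estimatePsfSize(w$image, list(w$roi))
    c(psfLateral(est) - 6.2, psfAxial(est) - 2.8)
  }, numeric(2))
  expect_lt(mean(abs(errs[1, ])), 0.5)
  expect_lt(mean(abs(errs[2, ])), 0.5)
})

test_that("the estimate is invariant to global amplitude scaling", {
  w <- simulateWireImage(64, PSFSpec(4, 4), seed = 3)
  a <- estimatePsfSize(w$image, list(w$roi))
  b <- estimatePsfSize(w$image * 73.2, list(w$roi))
  expect_equal(psfLateral(a), psfLateral(b), tolerance = 1e-12)
  expect_equal(psfAxial(a), psfAxial(b), tolerance = 1e-12)
})

test_that("wires of different amplitudes give the same -6 dB widths", {
  # three isolated wires on one anechoic image, amplitudes 1, 0.3, 5
  psf <- PSFSpec(6.2, 2.8)
  k <- gaussianPsfKernel(psf)
  img <- matrix(0, 96, 96)
  put <- function(img, r, c, amp) {
    rows <- r - nrow(k) %/% 2 + seq_len(nrow(k)) - 1
    cols <- c - ncol(k) %/% 2 + seq_len(ncol(k)) - 1
    img[rows, cols] <- img[rows, cols] + amp * k
    img
  }
  img <- put(img, 24, 24, 1)
  img <- put(img, 48, 64, 0.3)
  img <- put(img, 76, 30, 5)
  rois <- list(c(12, 12, 25, 25), c(36, 52, 25, 25), c(64, 18, 25, 25))
  single <- estimatePsfSize(put(matrix(0, 96, 96), 48, 48, 1),
                            list(c(36, 36, 25, 25)))
  multi <- estimatePsfSize(img, rois)
  expect_equal(psfLateral(multi), psfLateral(single), tolerance = 0.05)
  expect_equal(psfAxial(multi), psfAxial(single), tolerance = 0.05)
})

test_that("degenerate ROIs raise informative errors", {
  img <- matrix(0, 64, 64)
  expect_error(estimatePsfSize(img, list(c(10, 10, 20, 20))),
               class = "echomapNoWirePeak")
  expect_error(estimatePsfSize(img, list()), class = "echomapUsageError")
  img[10, 20] <- 1  # peak on the ROI border
  expect_error(estimatePsfSize(img, list(c(10, 11, 15, 15))),
               class = "echomapEdgePeakError")
  expect_error(estimatePsfSize(img, list(c(60, 60, 20, 20))),
               class = "echomapUsageError")
})

test_that("display-domain input is linearized before width measurement", {
  w <- simulateWireImage(64, PSFSpec(6, 3), seed = 11)
  lin <- w$image / max(w$image)
  disp <- logCompress(lin, dynamicRange = 60)
  a <- estimatePsfSize(lin, list(w$roi))
  b <- estimatePsfSize(disp, list(w$roi), domain = "display",
                       dynamicRange = 60)
  expect_equal(psfLateral(b), psfLateral(a), tolerance = 0.1)
  expect_equal(psfAxial(b), psfAxial(a), tolerance = 0.1)
})

test_that("optional smoothing changes estimates by less than 0.2 px", {
  w <- simulateWireImage(64, PSFSpec(6.2, 2.8), seed = 21)
  a <- estimatePsfSize(w$image, list(w$roi))
  b <- estimatePsfSize(w$image, list(w$roi), smooth = TRUE)
  expect_lt(abs(psfLateral(a) - psfLateral(b)), 0.2)
  expect_lt(abs(psfAxial(a) - psfAxial(b)), 0.2)
})
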