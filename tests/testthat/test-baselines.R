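test_that("all three filters fix constant images and respect range bounds", {
  cst <- matrix(42, 40, 40)
  expect_equal(nlmFilter(cst), cst)
  expect_equal(adfFilter(cst, iterations = 20), cst)
  expect_equal(blfFilter(cst), cst)
  set.seed(2)
  img <- matrix(runif(64 * 64, 0, 255), 64)
  for (f in list(nlmFilter, function(x) adfFilter(x, iterations = 10),
                 blfFilter)) {
    out <- f(img)
    expect_gte(min(out), min(img) - 1e-9)
    expect_lte(max(out), max(img) + 1e-9)
  }
})

test_that("anisotropic diffusion is conservative and guards stability", {
  set.seed(3)
  img <- matrix(runif(64 * 64, 0, 255), 64)
  expect_identical(adfFilter(img, iterations = 0), img)
  out <- adfFilter(img, iterations = 50)
  expect_lt(abs(mean(out) - mean(img)), 1e-6)
  out2 <- adfFilter(img, iterations = 50, conduction = "quotient")
  expect_lt(abs(mean(out2) - mean(img)), 1e-6)
  expect_error(adfFilter(img, dt = 0.3), class = "echomapStabilityError")
})

test_that("the bilateral filter has its two Gaussian limits", {
  set.seed(4)
  img <- matrix(runif(24 * 24, 0, 255), 24)
  # range sigma -> infinity: plain (truncated, renormalized) Gaussian blur
  bl <- blfFilter(img, sigmaSpatial = 2, sigmaRange = 1e9)
  rad <- ceiling(3 * 2)
  g <- exp(-((-rad):rad)^2 / (2 * 4))
  ref <- img
  for (r in 1:24) for (cc in 1:24) {
    ws <- 0; vs <- 0
    for (dr in -rad:rad) {
      r2 <- r + dr
      if (r2 < 1 || r2 > 24) next
      for (dc in -rad:rad) {
        c2 <- cc + dc
        if (c2 < 1 || c2 > 24) next
        w <- g[dr + rad + 1] * g[dc + rad + 1]
        ws <- ws + w; vs <- vs + w * img[r2, c2]
      }
    }
    ref[r, cc] <- vs / ws
  }
  expect_equal(bl, ref, tolerance = 1e-6)
  # range sigma -> 0: the self weight dominates
  expect_equal(blfFilter(img, sigmaSpatial = 2, sigmaRange = 1e-6), img,
               tolerance = 1e-6)
  expect_error(blfFilter(img, sigmaSpatial = 0), class = "echomapUsageError")
})

test_that("NLM weakens to the identity as h approaches zero", {
  set.seed(5)
  img <- matrix(runif(32 * 32, 0, 255), 32)
  out <- nlmFilter(img, h = 1e-9)
  expect_equal(out, img, tolerance = 1e-6)
  expect_error(nlmFilter(matrix(0, 10, 10), searchWindow = 21),
               class = "echomapUsageError")
})

test_that("each filter reduces speckle variance on a flat region", {
  um <- new("EchogenicityMap", pixels = matrix(1, 96, 96),
            structures = data.frame(), comboCyst = 0, comboEdgePoint = 0,
            seed = 1L)
  bm <- simulateBmode(um, PSFSpec(3, 3), seed = 8)
  disp <- logCompress(pixelData(bm) / max(pixelData(bm)))
  inner <- function(x) x[17:80, 17:80]
  s0 <- sd(inner(disp))
  expect_lt(sd(inner(nlmFilter(disp))), s0)
  expect_lt(sd(inner(adfFilter(disp))), s0)
  expect_lt(sd(inner(blfFilter(disp))), s0)
})

test_that("each filter raises cyst CNR on speckled phantoms", {
  for (seed in c(21, 33)) {
    fix <- speckledCystDisplay(seed = seed)
    base <- cnr(fix$display, fix$rois$cyst, fix$rois$background)
    for (f in list(nlmFilter, adfFilter, blfFilter)) {
      expect_gt(cnr(f(fix$display), fix$rois$cyst, fix$rois$background),
                base)
    }
  }
})
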