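test_that("the scatterer field is seeded complex white Gaussian noise", {
  a <- sampleScattererField(c(256, 256), seed = 3)
  b <- sampleScattererField(c(256, 256), seed = 3)
  expect_identical(a, b)
  expect_equal(mean(Mod(a)^2), 2, tolerance = 0.02)
  expect_equal(mean(Mod(a)) / sd(Mod(a)), speckleSnrTheoretical(),
               tolerance = 0.02)
})

test_that("the Gaussian kernel has the requested -6 dB widths", {
  psf <- PSFSpec(6.2, 2.8)
  k <- gaussianPsfKernel(psf)
  expect_equal(max(k), 1)
  expect_identical(k, k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))])
  est <- estimatePsfSize(k, list(c(1, 1, nrow(k), ncol(k))))
  expect_equal(psfLateral(est), 6.2, tolerance = 0.01)
  expect_equal(psfAxial(est), 2.8, tolerance = 0.01)
  # size 2.3548 corresponds to sigma 1: value exp(-1/2) one pixel off-peak
  k1 <- gaussianPsfKernel(PSFSpec(2 * sqrt(2 * log(2)), 2 * sqrt(2 * log(2))))
  ctr <- (dim(k1) + 1) / 2
  expect_equal(k1[ctr[1] + 1, ctr[2]], exp(-0.5), tolerance = 1e-12)
  expect_error(gaussianPsfKernel(PSFSpec(-1, 2)))
})

test_that("a uniform map yields fully developed Rayleigh speckle", {
  um <- new("EchogenicityMap", pixels = matrix(1, 128, 128),
            structures = data.frame(), comboCyst = 0, comboEdgePoint = 0,
            seed = 1L)
  bm <- simulateBmode(um, PSFSpec(6.2, 2.8), seed = 5)
  px <- pixelData(bm)
  expect_true(all(px >= 0))
  inner <- px[12:117, 12:117]  # away from zero-padded borders
  expect_equal(mean(inner) / sd(inner), speckleSnrTheoretical(),
               tolerance = 0.03)
  # KS needs (near-)independent draws: speckle is correlated over the PSF
  # scale, so decimate at a spacing beyond the correlation length
  ks <- rayleighKsTest(rayleighSample(PSFSpec(6.2, 2.8), seeds = 5:6))
  expect_gt(ks$p.value, 0.01)
})

test_that("the forward model is linear in the echogenicity map", {
  m <- generateEchogenicityMap(64, list(cyst = 6, edgePoint = 12), seed = 2)
  m3 <- m
  m3@pixels <- 3 * m@pixels
  a <- simulateBmode(m, PSFSpec(4, 4), seed = 9)
  b <- simulateBmode(m3, PSFSpec(4, 4), seed = 9)
  expect_equal(pixelData(b), 3 * pixelData(a), tolerance = 1e-12)
})

test_that("an anechoic cyst interior is dark and a +6 dB cyst shows the right contrast", {
  # anechoic: eroded interior < 2% of background mean
  pix <- matrix(1, 128, 128)
  ctr <- 64; rad <- 30
  d2 <- outer((1:128 - ctr)^2, (1:128 - ctr)^2, "+")
  pix[d2 <= rad^2] <- 0
  mk <- function(p) new("EchogenicityMap", pixels = p,
                        structures = data.frame(), comboCyst = 0,
                        comboEdgePoint = 0, seed = 1L)
  psf <- PSFSpec(4, 4)
  sig <- max(psfSigma(psf))
  bm <- simulateBmode(mk(pix), psf, seed = 3)
  interior <- d2 <= (rad - 3 * sig)^2
  bg <- pixelData(bm)[d2 > (rad + 3 * sig)^2]
  expect_lt(mean(pixelData(bm)[interior]), 0.02 * mean(bg))
  # +6 dB: interior/background envelope mean ratio near 10^(6/20)
  pix2 <- matrix(1, 128, 128)
  pix2[d2 <= rad^2] <- 10^(6 / 20)
  psf2 <- PSFSpec(2, 2)
  sig2 <- max(psfSigma(psf2))
  ratios <- vapply(1:6, function(s) {
    bm2 <- simulateBmode(mk(pix2), psf2, seed = 10 + s)
    int2 <- d2 <= (rad - 3 * sig2)^2
    bg2 <- pixelData(bm2)[d2 > (rad + 3 * sig2)^2 & d2 < 55^2]
    mean(pixelData(bm2)[int2]) / mean(bg2)
  }, numeric(1))
  expect_equal(mean(ratios), 10^(6 / 20), tolerance = 0.05)
})

test_that("max normalization sets each member's maximum to one", {
  m <- generateEchogenicityMap(64, list(cyst = -6, edgePoint = 12), seed = 4)
  bm <- simulateBmode(m, PSFSpec(4, 2), seed = 5)
  p <- normalizePair(bm, m, "max")
  expect_equal(max(pixelData(p$bmode)), 1)
  expect_equal(max(p$truth), 1)
  p2 <- normalizePair(bm, m, "max")
  expect_identical(pixelData(p$bmode), pixelData(p2$bmode))
  zero <- bm
  zero@pixels <- bm@pixels * 0
  expect_error(normalizePair(zero, m, "max"),
               class = "echomapDegenerateNormalization")
  expect_error(normalizePair(p$bmode, m, "max"), class = "echomapUsageError")
})

test_that("theoretical normalization closes the background amplitude gap", {
  m <- generateEchogenicityMap(128, list(cyst = 6, edgePoint = 20), seed = 9)
  bgMask <- pixelData(m) == 1
  amax <- max(pixelData(m))
  vals <- vapply(1:10, function(s) {
    bm <- simulateBmode(m, PSFSpec(6.2, 2.8), seed = 100 + s)
    p <- normalizePair(bm, m, "theoretical")
    mean(pixelData(p$bmode)[bgMask])
  }, numeric(1))
  expect_equal(mean(vals), 1 / amax, tolerance = 0.05)
})

test_that("log compression maps the dynamic range onto 8 bits", {
  img <- matrix(c(1, 10^(-60 / 20), 1e-5, 0.1), 2, 2)
  out <- logCompress(img, dynamicRange = 60)
  expect_equal(out[1, 1], 255)
  expect_equal(out[2, 1], 0)
  expect_equal(out[1, 2], 0)       # clipped below -60 dB
  expect_equal(out[2, 2], round((20 * log10(0.1) + 60) / 60 * 255))
  expect_error(logCompress(img * 2), class = "echomapUsageError")
  expect_equal(displayToLinear(255), 1)
  expect_equal(displayToLinear(0, 60), 1e-3)
})

test_that("datasets have the advertised size, split and determinism", {
  for (k in c(1, 2)) {
    ds <- buildDataset(PSFSpec(4, 4), pairsPerCombo = k, size = 64,
                       masterSeed = 7)
    n <- 28 * k
    expect_equal(dim(ds@bmode)[3], n)
    expect_equal(sum(ds@info$split == "train"), round(0.7 * n))
    expect_equal(max(ds@bmode[, , 1]), 1)  # normalized pairs
    expect_equal(max(ds@truth[, , n]), 1)
  }
  a <- buildDataset(PSFSpec(4, 4), pairsPerCombo = 1, size = 64, masterSeed = 7)
  b <- buildDataset(PSFSpec(4, 4), pairsPerCombo = 1, size = 64, masterSeed = 7)
  expect_identical(a@bmode, b@bmode)
  expect_identical(a@info, b@info)
})

test_that("datasets survive a save/load round trip", {
  ds <- buildDataset(PSFSpec(4, 4), pairsPerCombo = 1, size = 64,
                     masterSeed = 13)
  dir <- withr::local_tempdir()
  saveDataset(ds, dir)
  ds2 <- loadDataset(dir)
  expect_equal(ds2@bmode, ds@bmode, tolerance = 1e-6)  # 32-bit float TIFF
  expect_equal(ds2@info$split, ds@info$split)
  expect_equal(ds2@info$comboCyst, ds@info$comboCyst)
  expect_equal(psfLateral(ds2@psf), 4)
})
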