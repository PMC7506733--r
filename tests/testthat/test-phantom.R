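test_that("dB levels convert to linear amplitude, with the anechoic sentinel", {
  expect_identical(dbToAmplitude(0), 1)
  expect_identical(dbToAmplitude("anechoic"), 0)
  expect_identical(dbToAmplitude(-Inf), 0)
  expect_equal(dbToAmplitude(6), 10^(6 / 20))
  expect_equal(dbToAmplitude(c(-6, 20)), c(10^(-0.3), 10))
  expect_error(dbToAmplitude("hyperechoic"), class = "echomapInvalidLevel")
  expect_error(dbToAmplitude(NaN), class = "echomapInvalidLevel")
})

test_that("the level grid is the 7 x 4 Cartesian product, 28 unique combos", {
  lc <- levelCombinations()
  expect_equal(nrow(lc), 28)
  expect_equal(nrow(unique(lc)), 28)
  expect_setequal(unique(lc$cyst), c(6, -6, 18, -18, 30, -30, -Inf))
  expect_setequal(unique(lc$edgePoint), c(3, 6, 12, 20))
  expect_true(any(is.infinite(lc$cyst) & lc$edgePoint == 20))
})

test_that("generated maps satisfy the echogenicity invariants", {
  for (case in list(list(size = 256, combo = list(cyst = -6, edgePoint = 6), seed = 1),
                    list(size = 64, combo = list(cyst = -Inf, edgePoint = 20), seed = 7),
                    list(size = 128, combo = list(cyst = 18, edgePoint = 3), seed = 11))) {
    m <- generateEchogenicityMap(case$size, case$combo, seed = case$seed)
    px <- pixelData(m)
    expect_equal(dim(px), c(case$size, case$size))
    # every pixel is either background (1.0) or one of the two structure levels
    amps <- sort(unique(as.numeric(px)))
    expected <- sort(unique(c(1, dbToAmplitude(case$combo$cyst),
                              dbToAmplitude(case$combo$edgePoint))))
    expect_equal(amps, expected)
    # structures respect the border margin
    occ <- which(px != 1, arr.ind = TRUE)
    expect_true(all(occ >= 9 & occ <= case$size - 8))
    # a corner pixel is background
    expect_identical(px[1, 1], 1)
  }
})

test_that("cyst interiors carry exactly the combo amplitude", {
  m <- generateEchogenicityMap(256, list(cyst = -6, edgePoint = 6), seed = 1)
  st <- structures(m)
  cy <- st[st$kind == "cyst", ][1, ]
  expect_equal(pixelData(m)[round(cy$row), round(cy$col)], 10^(-6 / 20))
})

test_that("map generation is deterministic in the seed", {
  a <- generateEchogenicityMap(96, list(cyst = 30, edgePoint = 12), seed = 5)
  b <- generateEchogenicityMap(96, list(cyst = 30, edgePoint = 12), seed = 5)
  d <- generateEchogenicityMap(96, list(cyst = 30, edgePoint = 12), seed = 6)
  expect_identical(pixelData(a), pixelData(b))
  expect_identical(structures(a), structures(b))
  expect_false(identical(pixelData(a), pixelData(d)))
})

test_that("impossible placements raise a placement error", {
  expect_error(
    generateEchogenicityMap(32, list(cyst = 6, edgePoint = 6),
                            nPoints = c(60, 60), seed = 1, maxAttempts = 30),
    class = "echomapPlacementError")
})

test_that("structures do not overlap each other", {
  for (seed in 1:5) {
    m <- generateEchogenicityMap(128, list(cyst = 6, edgePoint = 12),
                                 seed = seed)
    st <- structures(m)
    # per-structure pixel counts must add up to the occupied area
    masks <- lapply(seq_len(nrow(st)), function(i) {
      r <- st[i, ]
      EchoMap:::structureMask(128, r$kind, as.list(r))
    })
    total <- Reduce(`+`, lapply(masks, function(m) m * 1))
    expect_lte(max(total), 1)
    expect_equal(sum(total), sum(pixelData(m) != 1))
  }
})
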