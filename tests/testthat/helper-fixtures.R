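# Shared fixtures, built once per test run. The desk-scale training runs
# are the expensive pieces; several test files reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

deskPsf <- function() PSFSpec(6.2, 2.8)

# 196-pair matched-PSF training set (7 pairs per level combination, 64 px)
deskDataset <- function() fixture("deskDataset",
  buildDataset(deskPsf(), pairsPerCombo = 7, size = 64, masterSeed = 42))

deskNetConfig <- function() networkConfig(minFilters = 8, filterSize = 3)

deskTrainConfig <- function() trainingConfig(loss = "mixed", beta = 300,
                                             initialLr = 7e-4, batchSize = 8,
                                             epochs = 10, seed = 1)

deskModel <- function() fixture("deskModel",
  trainUnet(deskDataset(), deskNetConfig(), deskTrainConfig()))

# matched vs mismatched PSF at 128 px: the PSF-specific effect needs scale
# separation between the speckle grain and the image, so this comparison
# runs at the larger image side (same pair count and training recipe)
psfMatchModels <- function() fixture("psfMatchModels", {
  nc <- deskNetConfig()
  tc <- deskTrainConfig()
  matched <- trainUnet(buildDataset(deskPsf(), pairsPerCombo = 7,
                                    size = 128, masterSeed = 42), nc, tc)
  mismatched <- trainUnet(buildDataset(PSFSpec(2, 2), pairsPerCombo = 7,
                                       size = 128, masterSeed = 42), nc, tc)
  evalSet <- buildDataset(deskPsf(), pairsPerCombo = 2, size = 128,
                          masterSeed = 819)
  list(matched = matched, mismatched = mismatched, evalSet = evalSet)
})

# held-out test images simulated at the matched PSF
deskEvalPairs <- function() fixture("deskEvalPairs",
  simulateEvalPairs(deskPsf(), n = 10, size = 64, masterSeed = 42))

# decimated background-envelope sample: speckle is correlated over the PSF
# scale, so pixels are taken on a grid with spacing beyond the correlation
# length to give (near-)independent Rayleigh draws for the KS test
rayleighSample <- function(psf, seeds, size = 512, spacing = 6) {
  um <- new("EchogenicityMap", pixels = matrix(1, size, size),
            structures = data.frame(), comboCyst = 0, comboEdgePoint = 0,
            seed = 1L)
  take <- seq(16, size - 16, by = spacing)
  unlist(lapply(seeds, function(s)
    as.numeric(pixelData(simulateBmode(um, psf, seed = s))[take, take])))
}

# speckled +6 dB cyst phantom in the display domain, with ROIs
speckledCystDisplay <- function(seed, psf = PSFSpec(4, 4), size = 128) {
  m <- generateEchogenicityMap(size, list(cyst = 6, edgePoint = 6),
                               seed = seed)
  bm <- simulateBmode(m, psf, seed = seed + 1000L)
  list(display = logCompress(normalizePair(bm, m, "max")$bmode),
       rois = autoRois(m), map = m)
}
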