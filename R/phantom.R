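#' @include AllClasses.R utils.R
NULL

#' Convert an echogenicity level in dB to a linear amplitude factor
#'
#' Echogenicity is expressed in dB relative to the background level
#' (amplitude 1.0). The anechoic sentinel (no echoes at all) maps to 0.
#'
#' @param level numeric dB value, the string \code{"anechoic"}, or
#'   \code{-Inf} (equivalent encoding of anechoic). Vectorized.
#' @return Linear amplitude factor(s) \eqn{10^{level/20}}; 0 for anechoic.
#' @examples
#' dbToAmplitude(0)           # 1
#' dbToAmplitude(6)           # 1.9953
#' dbToAmplitude("anechoic")  # 0
#' @export
dbToAmplitude <- function(level) {
  if (is.character(level)) {
    bad <- !(level %in% "anechoic") & is.na(suppressWarnings(as.numeric(level)))
    if (any(bad))
      stopCond("echomapInvalidLevel", "invalid echogenicity level: %s",
               paste(level[bad], collapse = ", "))
    level <- ifelse(level == "anechoic", -Inf, suppressWarnings(as.numeric(level)))
  }
  if (!is.numeric(level) || any(is.nan(level)) || any(level == Inf))
    stopCond("echomapInvalidLevel", "echogenicity level must be finite dB or 'anechoic'")
  10^(level / 20)
}

#' Enumerate the echogenicity level combinations of the training grid
#'
#' The training phantoms draw the cyst level from \{+6, -6, +18, -18, +30,
#' -30, anechoic\} dB and the shared edge/point level from \{+3, +6, +12,
#' +20\} dB; the Cartesian product gives 28 combinations.
#'
#' @return A 28-row data.frame with numeric columns \code{cyst} (\code{-Inf}
#'   = anechoic) and \code{edgePoint}, in deterministic order (cyst varying
#'   fastest).
#' @examples
#' nrow(levelCombinations())  # 28
#' @export
levelCombinations <- function() {
  cyst <- c(6, -6, 18, -18, 30, -30, -Inf)
  edgePoint <- c(3, 6, 12, 20)
  out <- expand.grid(cyst = cyst, edgePoint = edgePoint,
                     KEEP.OUT.ATTRS = FALSE)
  out[, c("cyst", "edgePoint")]
}

# grown-by-`clear` pixel mask of one structure, used for overlap rejection
structureMask <- function(size, kind, geom, grow = 0) {
  m <- matrix(FALSE, size, size)
  if (kind == "cyst") {
    r <- geom$radius + grow
    rows <- pmax(1, floor(geom$row - r)):pmin(size, ceiling(geom$row + r))
    cols <- pmax(1, floor(geom$col - r)):pmin(size, ceiling(geom$col + r))
    dr <- outer((rows - geom$row)^2, (cols - geom$col)^2, "+")
    m[rows, cols] <- dr <= r^2
  } else if (kind == "edge") {
    rows <- pmax(1, geom$top - grow):pmin(size, geom$top + geom$height - 1 + grow)
    cols <- pmax(1, geom$left - grow):pmin(size, geom$left + geom$width - 1 + grow)
    m[rows, cols] <- TRUE
  } else {
    rows <- pmax(1, geom$row - grow):pmin(size, geom$row + grow)
    cols <- pmax(1, geom$col - grow):pmin(size, geom$col + grow)
    m[rows, cols] <- TRUE
  }
  m
}

#' Generate a random ground-truth echogenicity map
#'
#' Places a random number of circular "cysts", hyperechoic rectangular
#' "edges" and single-pixel "wire" reflectors on a unit background.
#' Structures are kept a margin away from the image border and are rejected
#' if they come within 2 px of an already placed structure, so every pixel
#' has one unambiguous level. All cysts share the cyst level of the combo;
#' all edges and points share the edge/point level.
#'
#' @param size image side in pixels (square map), >= 32.
#' @param combo levels: a list or vector with elements/names \code{cyst}
#'   (dB or \code{-Inf}/"anechoic") and \code{edgePoint} (dB), e.g. one row
#'   of \code{\link{levelCombinations}}.
#' @param nCysts,nEdges,nPoints integer ranges \code{c(min, max)} for the
#'   per-kind structure counts.
#' @param margin clear border in pixels (default 8).
#' @param cystRadiusRange,edgeSideRange uniform sampling ranges in px;
#'   defaults scale with \code{size} and equal [8, 40] and [10, 60] at
#'   size 256.
#' @param seed integer seed; identical arguments give bit-identical maps.
#' @param maxAttempts rejection-sampling attempts per structure before a
#'   placement error is raised.
#' @return An \linkS4class{EchogenicityMap}.
#' @examples
#' m <- generateEchogenicityMap(64, list(cyst = -6, edgePoint = 6), seed = 1)
#' range(pixelData(m))
#' @export
generateEchogenicityMap <- function(size = 256, combo,
                                    nCysts = c(1, 3), nEdges = c(1, 2),
                                    nPoints = c(1, 4), margin = 8,
                                    cystRadiusRange = NULL,
                                    edgeSideRange = NULL,
                                    seed, maxAttempts = 200) {
  stopifnot(size >= 32)
  if (is.data.frame(combo)) combo <- as.list(combo[1, ])
  cystLevel <- if (is.character(combo$cyst) && combo$cyst == "anechoic") -Inf
               else as.numeric(combo$cyst)
  epLevel <- as.numeric(combo$edgePoint)
  if (is.null(cystRadiusRange)) cystRadiusRange <- size * c(8, 40) / 256
  if (is.null(edgeSideRange)) edgeSideRange <- size * c(10, 60) / 256
  seed <- as.integer(seed)

  # integer uniform on [a, b] immune to sample()'s scalar expansion
  rint <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L

  withSeed(seed, {
    counts <- c(cyst = rint(nCysts[1], nCysts[2]),
                edge = rint(nEdges[1], nEdges[2]),
                point = rint(nPoints[1], nPoints[2]))
    pixels <- matrix(1, size, size)
    occupied <- matrix(FALSE, size, size)
    recs <- list()
    lo <- margin + 1L
    hi <- size - margin
    for (kind in c("cyst", "edge", "point")) {
      lvl <- if (kind == "cyst") cystLevel else epLevel
      amp <- dbToAmplitude(lvl)
      for (i in seq_len(counts[[kind]])) {
        placed <- FALSE
        for (att in seq_len(maxAttempts)) {
          if (kind == "cyst") {
            rmax <- min(cystRadiusRange[2], (size - 2 * margin) / 2 - 1)
            rad <- stats::runif(1, min(cystRadiusRange[1], rmax), rmax)
            geom <- list(row = stats::runif(1, lo + rad, hi - rad),
                         col = stats::runif(1, lo + rad, hi - rad),
                         radius = rad)
          } else if (kind == "edge") {
            smax <- min(edgeSideRange[2], size - 2 * margin - 1)
            h <- round(stats::runif(1, min(edgeSideRange[1], smax), smax))
            w <- round(stats::runif(1, min(edgeSideRange[1], smax), smax))
            geom <- list(top = rint(lo, hi - h + 1L),
                         left = rint(lo, hi - w + 1L),
                         height = h, width = w)
          } else {
            geom <- list(row = rint(lo, hi), col = rint(lo, hi))
          }
          grown <- structureMask(size, kind, geom, grow = 2)
          if (!any(grown & occupied)) {
            mask <- structureMask(size, kind, geom, grow = 0)
            pixels[mask] <- amp
            occupied[mask] <- TRUE
            recs[[length(recs) + 1L]] <- data.frame(
              kind = kind, level_dB = lvl,
              row = if (kind == "edge") NA_real_ else geom$row,
              col = if (kind == "edge") NA_real_ else geom$col,
              radius = if (kind == "cyst") geom$radius else NA_real_,
              top = if (kind == "edge") geom$top else NA_real_,
              left = if (kind == "edge") geom$left else NA_real_,
              height = if (kind == "edge") geom$height else NA_real_,
              width = if (kind == "edge") geom$width else NA_real_)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stopCond("echomapPlacementError",
                   "could not place %s #%d within %d attempts (seed %d); retry with a new seed",
                   kind, i, maxAttempts, seed)
      }
    }
    new("EchogenicityMap", pixels = pixels,
        structures = do.call(rbind, recs),
        comboCyst = cystLevel, comboEdgePoint = epLevel, seed = seed)
  })
}
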