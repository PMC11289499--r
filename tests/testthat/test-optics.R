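test_that("hexagonal geometry reproduces the instrument periods and order table", {
  cfg <- opticalConfig()
  geom <- makeLatticeGeometry(cfg)
  tz <- 1 / geom@qFund
  naMid <- 0.525
  expect_equal(tz, 2 * cfg@lambdaExc / naMid, tolerance = 1e-12)
  expect_lt(abs(tz - 2.13) / 2.13, 0.02)          # nominal instrument axial period
  ## five phase steps cover one lateral period; nominal instrument step is 0.24 um
  expect_lt(abs(1 / geom@pFund / 5 - 0.24), 0.01)
  expect_setequal(geom@orderTable[["0"]], c(0, -2, 2, -4, 4))
  expect_setequal(geom@orderTable[["1"]], c(-3, -1, 1, 3))
  expect_setequal(geom@orderTable[["2"]], c(-2, 0, 2))
})

test_that("order tables are emergent from beam-pair enumeration, both patterns", {
  for (pattern in c("hexagonal", "square")) {
    geom <- makeLatticeGeometry(opticalConfig(pattern = pattern))
    b <- geom@beamCenters
    found <- list()
    for (i in seq_len(nrow(b))) for (j in seq_len(nrow(b))) {
      m <- (b[i, 1] - b[j, 1]) / geom@pFund
      n <- (b[i, 2] - b[j, 2]) / geom@qFund
      expect_lt(abs(m - round(m)), 1e-9)
      expect_lt(abs(n - round(n)), 1e-9)
      mc <- as.character(round(m))
      found[[mc]] <- union(found[[mc]], round(n))
    }
    expect_setequal(as.integer(names(found)), geom@mRange)
    for (mc in names(found))
      expect_setequal(found[[mc]], geom@orderTable[[mc]])
  }
})

test_that("detection PSF is centered, symmetric, and cut off at 2 NA / lambda", {
  cfg <- smallCfg()
  H <- makeDetectionPsf(cfg)
  v <- arrayData(H)
  ctr <- dim(v) %/% 2 + 1
  peak <- which(v == max(v), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), unname(ctr))
  ## inversion symmetry in (x, y) from the real circular pupil
  flipped <- v[c(1, rev(seq_len(dim(v)[1])[-1])),
               c(1, rev(seq_len(dim(v)[2])[-1])), ]
  expect_lt(relErr(flipped, v), 1e-9)
  expect_true(all(v >= 0))
  expect_equal(sum(v), 1, tolerance = 1e-12)

  ## lateral OTF cutoff; oracle = brute-force autocorrelation support of the
  ## aperture disk at fine sampling (support radius 2R for a radius-R disk)
  R <- 1
  xs <- seq(-1.5, 1.5, length.out = 121)
  disk <- outer(xs, xs, function(a, b) as.numeric(a^2 + b^2 <= R^2))
  acAt <- function(lagFrac) {       # autocorrelation at lag = lagFrac * 2R
    shift <- round(lagFrac * 2 * R / (xs[2] - xs[1]))
    n <- length(xs)
    if (shift >= n) return(0)
    sum(disk[seq_len(n - shift), ] * disk[seq_len(n - shift) + shift, ])
  }
  expect_gt(acAt(0.95), 0)          # support persists just inside 2R
  expect_equal(acAt(1.05), 0)       # and vanishes just beyond

  O <- fft(latticeSIMfocus:::ifftShift(v))
  g <- dim(v)
  kx <- latticeSIMfocus:::fftFreq(g[1], cfg@voxelXY / cfg@upsample)
  ky <- latticeSIMfocus:::fftFreq(g[2], cfg@voxelXY / cfg@upsample)
  kr <- sqrt(outer(kx^2, ky^2, `+`))
  cutoff <- 2 * cfg@naDet / cfg@lambdaDet
  lateral <- Mod(O[, , 1])                       # kz = 0 plane
  kStep <- kx[2]
  expect_lt(max(lateral[kr > cutoff + kStep]), 1e-6 * max(lateral))
  expect_gt(max(lateral[kr > 0.8 * cutoff & kr < 0.9 * cutoff]),
            1e-6 * max(lateral))
})

test_that("lattice pupil has six annulus-clipped segments with the right symmetry", {
  cfg <- opticalConfig()                          # fine kz sampling
  pup <- makeLatticePupil(cfg)
  f <- pup@field
  expect_true(all(f %in% c(0 + 0i, 1 + 0i)))
  ## count connected runs of nonzero samples within each column
  nSegments <- 0L
  for (icol in seq_len(nrow(f))) {
    col <- Mod(f[icol, ]) > 0
    if (!any(col)) next
    nSegments <- nSegments + sum(diff(c(0L, as.integer(col))) == 1L)
  }
  expect_identical(nSegments, 6L)
  ## centrosymmetric about the array center (edge row/col 1 has no partner)
  nx <- nrow(f); nz <- ncol(f)
  expect_equal(f[nx:2, nz:2], f[2:nx, 2:nz])
  ## widening the annulus strictly grows the support
  wide <- makeLatticePupil(opticalConfig(naAnnMin = 0.3))
  expect_gt(sum(Mod(wide@field) > 0), sum(Mod(f) > 0))
})

test_that("axial offset is a pure kz ramp: identity, inverse, translation", {
  cfg <- smallCfg()
  pup <- makeLatticePupil(cfg)
  expect_equal(applyAxialOffset(pup, 0)@field, pup@field)
  there <- applyAxialOffset(pup, 0.37)
  back <- applyAxialOffset(there, -0.37)
  expect_lt(relErr(back@field, pup@field), 1e-12)

  ## translation duality at grid multiples: offset pattern == shifted pattern
  vz <- cfg@voxelZ / cfg@upsample
  I0 <- latticeSIMfocus:::excitationPattern2d(pup)
  k <- 7L
  Ik <- latticeSIMfocus:::excitationPattern2d(applyAxialOffset(pup, k * vz))
  ## harmonics acquire exp(+2 pi i kz dz): features move toward -z
  expect_lt(relErr(Ik, latticeSIMfocus:::circShift(I0, c(0, -k))), 1e-9)

  ## sub-grid offset: cross-correlation of the x-averaged axial profiles
  ## peaks at the applied lag (dense-lag oracle)
  tz <- latticeAxialPeriod(cfg)
  dz <- 0.2 * tz
  Id <- latticeSIMfocus:::excitationPattern2d(applyAxialOffset(pup, dz))
  p0 <- colMeans(I0) - mean(colMeans(I0))
  pd <- colMeans(Id) - mean(colMeans(Id))
  ## the x-averaged profile repeats every Tz/2 (~21 voxels): restrict lags
  ## to half that so the matching correlation peak is unique
  lags <- -10:10
  cc <- vapply(lags, function(l)
    sum(p0 * latticeSIMfocus:::circShift(pd, -l)), numeric(1))
  expect_lt(abs(lags[which.max(cc)] + dz / vz), 1)

  expect_warning(applyAxialOffset(pup, 10), "wrap")
})

test_that("lateral phase convention: 2 pi is one period, 2 pi / 5 is 0.24 um", {
  cfg <- smallCfg()
  pup <- makeLatticePupil(cfg)
  expect_equal(applyLateralPhase(pup, 0)@field, pup@field)
  I0 <- latticeSIMfocus:::excitationPattern2d(pup)
  I2pi <- latticeSIMfocus:::excitationPattern2d(applyLateralPhase(pup, 2 * pi))
  expect_lt(relErr(I2pi, I0), 1e-9)
  ## one fifth of the (grid-snapped) period
  I5 <- latticeSIMfocus:::excitationPattern2d(applyLateralPhase(pup, 2 * pi / 5))
  vx <- cfg@voxelXY / cfg@upsample
  expected <- 1 / pup@pActual / 5 / vx
  p0 <- rowMeans(I0) - mean(rowMeans(I0))
  p5 <- rowMeans(I5) - mean(rowMeans(I5))
  lags <- -10:10
  cc <- vapply(lags, function(l)
    sum(p0 * latticeSIMfocus:::circShift(p5, -l)), numeric(1))
  expect_lt(abs(abs(lags[which.max(cc)]) - expected), 1)
})

test_that("excitation pattern: constant for one beam, periodic with side lobes for six", {
  cfg <- smallCfg()
  pup <- makeLatticePupil(cfg)
  single <- pup
  single@field[] <- 0 + 0i
  single@field[nrow(single@field) / 2 + 1, 5] <- 1 + 0i
  Is <- latticeSIMfocus:::excitationPattern2d(single)
  expect_lt(stats::sd(Is) / mean(Is), 1e-9)

  psf <- excitationPsfFromPupil(pup, cfg)
  q <- makeLatticeGeometry(cfg)@qFund
  expect_equal(measureAxialPeriod(psf), 1 / q, tolerance = 1e-6)
  ## x-averaging keeps only even axial orders: half the period
  expect_equal(measureAxialPeriod(psf, xAverage = TRUE), 1 / (2 * q),
               tolerance = 1e-6)
  ## central peak flanked by side lobes of comparable magnitude
  prof <- colMeans(arrayData(psf)[, 9, ])
  ctr <- length(prof) / 2 + 1                 # pattern node at the origin
  expect_equal(prof[ctr], max(prof), tolerance = 1e-9)
  vz <- cfg@voxelZ / cfg@upsample
  sideIdx <- ctr + round(1 / (2 * q) / vz)
  side <- max(prof[(sideIdx - 2):(sideIdx + 2)])
  expect_gt(side / prof[ctr], 0.4)
  expect_lt(side / prof[ctr], 1)
})

test_that("propagation along y: symmetric defocus, reduced contrast off focus", {
  cfg <- smallCfg()
  pup <- makeLatticePupil(cfg)
  at0 <- propagateAlongY(pup, 0, cfg)
  ref <- excitationPsfFromPupil(pup, cfg)
  expect_lt(relErr(arrayData(at0), arrayData(ref)), 1e-10)
  plus <- propagateAlongY(pup, 10, cfg)
  minus <- propagateAlongY(pup, -10, cfg)
  expect_lt(relErr(arrayData(plus), arrayData(minus)), 1e-9)
  depth <- function(psf) {
    prof <- colMeans(arrayData(psf)[, 9, ])
    (max(prof) - min(prof)) / (max(prof) + min(prof))
  }
  expect_lt(depth(plus), depth(ref))
})

test_that("order decomposition: five bands, emergent n(m) support, exact partition", {
  cfg <- opticalConfig()                          # envelope-resolving grid
  geom <- makeLatticeGeometry(cfg)
  pup <- makeLatticePupil(cfg, geom)
  dec <- decomposeExcitationOrders(pup, geom)
  expect_identical(dec$mRange, -2:2)
  expect_true(all(vapply(dec$Ikz, function(v) any(Mod(v) > 0), logical(1))))

  ## n(m) is emergent: cluster centroids of |I~m(kz)| sit at n * q
  nz <- length(dec$Ikz[["0"]])
  kStep <- pup@kStep[2]
  ## centered layout so harmonic clusters do not wrap across the DC edge
  kzn <- latticeSIMfocus:::centeredCoords(nz, 1) * kStep
  for (mc in names(dec$Ikz)) {
    mag <- latticeSIMfocus:::fftShift(Mod(dec$Ikz[[mc]]))
    above <- mag > 0.05 * max(mag)
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    found <- c()
    for (r in seq_along(runs$values)) {
      if (!runs$values[r]) next
      idx <- (ends[r] - runs$lengths[r] + 1):ends[r]
      cen <- sum(kzn[idx] * mag[idx]) / sum(mag[idx])
      found <- c(found, cen / geom@qFund)
    }
    found <- sort(round(found, 6))
    expected <- sort(geom@orderTable[[mc]])
    expect_equal(length(found), length(expected))
    expect_lt(max(abs(found - expected)), 0.25)
  }

  ## partition: the band columns carry all the excitation OTF energy
  I2 <- latticeSIMfocus:::excitationPattern2d(pup)
  Ik <- fft(latticeSIMfocus:::ifftShift(I2))
  pSamples <- round(pup@pActual / pup@kStep[1])
  cols <- 1 + (((-2:2) * pSamples) %% nrow(Ik))
  off <- sum(Mod(Ik[-cols, ])^2) / sum(Mod(Ik)^2)
  expect_lt(off, 1e-18)
  for (i in seq_along(cols))
    expect_equal(dec$Ikz[[as.character((-2:2)[i])]], Ik[cols[i], ])
})

test_that("transform bookkeeping: Parseval and Hermitian symmetry", {
  cfg <- smallCfg()
  pup <- applyAxialOffset(makeLatticePupil(cfg), 0.3)
  e <- fft(latticeSIMfocus:::ifftShift(pup@field), inverse = TRUE)
  expect_equal(sum(Mod(pup@field)^2), sum(Mod(e)^2) / length(e),
               tolerance = 1e-9)
  H <- arrayData(makeDetectionPsf(cfg))
  O <- fft(latticeSIMfocus:::ifftShift(H))
  rev1 <- function(n) c(1, rev(seq_len(n)[-1]))
  d <- dim(O)
  Orev <- O[rev1(d[1]), rev1(d[2]), rev1(d[3])]
  expect_lt(relErr(Orev, Conj(O)), 1e-9)
})
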