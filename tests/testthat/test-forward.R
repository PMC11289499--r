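test_that("bead generation: count, determinism, separation, failure mode", {
  cfg <- smallCfg()
  s <- smallBeads(n = 8, seed = 3)
  expect_identical(sum(arrayData(s) > 0), 8L)
  expect_true(all(arrayData(s) %in% c(0, 1)))
  s2 <- smallBeads(n = 8, seed = 3)
  expect_identical(arrayData(s), arrayData(s2))
  expect_false(identical(arrayData(s), arrayData(smallBeads(n = 8, seed = 4))))
  ## pairwise separation honors minSep (up to one voxel of rounding)
  pos <- sweep(s@positions - 1, 2, s@voxel, `*`)
  d <- as.matrix(stats::dist(pos))
  expect_gt(min(d[upper.tri(d)]), 0.5 - max(s@voxel))
  expect_error(
    generateBeads(50, cfg, minSep = 5, seed = 1,
                  marginZ = 1.2 * latticeAxialPeriod(cfg)),
    "placement error")
})

test_that("calibration identity: centered-bead bands equal the TF set", {
  cfg <- smallCfg()
  dz <- piToDz(0.3, latticeAxialPeriod(cfg))
  stack <- simulateRawStack(makeDeltaSample(cfg), cfg,
                            acquisitionParams(appliedDz = dz))
  bands <- separateOrders(stack)
  tf <- simulateTfSet(cfg, dz)
  for (m in -2:2)
    expect_lt(relErr(orderComponent(bands, m), orderComponent(tf, m)), 1e-6)
})

test_that("forward model is linear and shift covariant", {
  cfg <- smallCfg()
  acq <- acquisitionParams(appliedDz = 0.2)
  s1 <- smallBeads(n = 3, seed = 5)
  s2 <- smallBeads(n = 3, seed = 6)
  mix <- new("SampleVolume", values = 2 * arrayData(s1) + 0.5 * arrayData(s2),
             voxel = s1@voxel, positions = s1@positions)
  dMix <- arrayData(simulateRawStack(mix, cfg, acq))
  d1 <- arrayData(simulateRawStack(s1, cfg, acq))
  d2 <- arrayData(simulateRawStack(s2, cfg, acq))
  expect_lt(relErr(dMix, 2 * d1 + 0.5 * d2), 1e-9)

  ## whole-camera-voxel translation along y and z translates every phase
  ## (laterally the pattern stays fixed to the objectives, so x-shifts are
  ## covariant only by multiples of the lateral period)
  u <- cfg@upsample
  sh <- c(0L, 2L, 5L)                       # camera voxels
  shifted <- new("SampleVolume",
                 values = latticeSIMfocus:::circShift(arrayData(s1), sh * u),
                 voxel = s1@voxel, positions = s1@positions)
  dS <- arrayData(simulateRawStack(shifted, cfg, acq))
  for (j in 1:5)
    expect_lt(relErr(dS[, , , j],
                     latticeSIMfocus:::circShift(d1[, , , j], sh)), 1e-9)
})

test_that("phase stepping: uniform samples and order cancellation", {
  cfg <- smallCfg()
  g <- dim(arrayData(makeDeltaSample(cfg)))
  uni <- new("SampleVolume", values = array(1, g),
             voxel = makeDeltaSample(cfg)@voxel,
             positions = matrix(integer(), 0, 3))
  stack <- simulateRawStack(uni, cfg, acquisitionParams(appliedDz = 0.11))
  v <- arrayData(stack)
  ## x-averaged images are phase independent (phase only translates along x)
  ref <- apply(v[, , , 1], c(2, 3), mean)
  for (j in 2:5)
    expect_lt(relErr(apply(v[, , , j], c(2, 3), mean), ref), 1e-8)

  ## the phase-weight sums cancel every order but m = 0 (direct oracle) ...
  phases <- 2 * pi * (0:4) / 5
  for (m in c(-2, -1, 1, 2))
    expect_lt(Mod(sum(exp(1i * m * phases))), 1e-12)
  ## ... so summing the five uniform-sample phase images leaves power only
  ## in the DC column: lateral modulation at m * p cancels
  tot <- apply(v, 1:3, sum)
  spec <- fft(tot)
  pSamp <- round(stackMeta(stack)$pActual * dim(tot)[1] * stack@voxel[1])
  dc <- Mod(spec[1, 1, 1])
  for (m in c(-2, -1, 1, 2)) {
    col <- 1 + ((m * pSamp) %% dim(tot)[1])
    expect_lt(max(Mod(spec[col, , ])) / dc, 1e-6)
  }
})

test_that("Gaussian noise floor matches the peak-over-sigma SNR definition", {
  cfg <- smallCfg()
  clean <- simulateRawStack(smallBeads(n = 4, seed = 2), cfg,
                            acquisitionParams())
  expect_identical(arrayData(addGaussianNoise(clean, Inf)), arrayData(clean))
  for (snr in c(4, 25)) {
    noisy <- addGaussianNoise(clean, snr, seed = 1)
    sigma <- stats::sd(arrayData(noisy) - arrayData(clean))
    expect_lt(abs(max(arrayData(clean)) / sigma - snr) / snr, 0.05)
  }
  n1 <- addGaussianNoise(clean, 10, seed = 1)
  n2 <- addGaussianNoise(clean, 10, seed = 2)
  expect_false(identical(arrayData(n1), arrayData(n2)))
  s1 <- stats::sd(arrayData(n1) - arrayData(clean))
  s2 <- stats::sd(arrayData(n2) - arrayData(clean))
  expect_lt(abs(s1 - s2) / s1, 0.02)
})

test_that("transfer-function sets: DC dominance, Hermitian pairing, offset ramps", {
  cfg <- smallCfg()
  tf0 <- simulateTfSet(cfg, 0)
  O0 <- orderComponent(tf0, 0)
  expect_equal(unname(which(Mod(O0) == max(Mod(O0)), arr.ind = TRUE)[1, ]),
               c(1, 1, 1))                  # max magnitude at k = 0
  ## zero offset, zero lateral phase: the zero order is real on the
  ## simulation grid, positive on its strong support (the finite z window
  ## leaves percent-level sinc lobes further out)
  geom <- makeLatticeGeometry(cfg)
  Hn <- latticeSIMfocus:::ifftShift(arrayData(makeDetectionPsf(cfg)))
  dec <- decomposeExcitationOrders(makeLatticePupil(cfg, geom), geom)
  Oup <- latticeSIMfocus:::fftnd(latticeSIMfocus:::timesZProfile(
    Hn, latticeSIMfocus:::ifftShift(dec$Iz[["0"]])))
  expect_lt(max(abs(Im(Oup))) / max(Mod(Oup)), 1e-12)
  strong <- Mod(Oup) > 0.05 * max(Mod(Oup))
  expect_gt(min(Re(Oup[strong])), 0)
  ## O_{-m}(k) = conj(O_m(-k)) for every order (real raw data)
  rev1 <- function(n) c(1, rev(seq_len(n)[-1]))
  d <- dim(O0)
  for (m in 0:2) {
    Om <- orderComponent(tf0, m)
    Omm <- orderComponent(tf0, -m)
    expect_lt(relErr(Omm, Conj(Om[rev1(d[1]), rev1(d[2]), rev1(d[3])])), 1e-9)
  }
  ## an axial offset enters the excitation spectrum as an exact kz ramp
  pup <- makeLatticePupil(cfg)
  geom <- makeLatticeGeometry(cfg)
  dz <- 0.37
  dec0 <- decomposeExcitationOrders(pup, geom)
  decD <- decomposeExcitationOrders(applyAxialOffset(pup, dz), geom)
  nz <- length(dec0$Ikz[["1"]])
  kz <- latticeSIMfocus:::fftFreq(nz, cfg@voxelZ / cfg@upsample)
  for (mc in c("0", "1", "2"))
    expect_lt(relErr(decD$Ikz[[mc]],
                     dec0$Ikz[[mc]] * exp(2i * pi * kz * dz)), 1e-12)
  ## nonzero offset shows up as phase structure in the transfer functions
  tfD <- simulateTfSet(cfg, piToDz(0.4, latticeAxialPeriod(cfg)))
  OD <- orderComponent(tfD, 0)
  supD <- Mod(OD) > 1e-3 * max(Mod(OD))
  expect_gt(max(abs(Arg(OD[supD]))), 0.5)
})

test_that("simulation guards: dimension and ringing checks", {
  cfg <- smallCfg()
  wrongDims <- new("SampleVolume", values = array(0.5, c(16, 16, 16)),
                   voxel = rep(0.05, 3), positions = matrix(integer(), 0, 3))
  expect_error(simulateRawStack(wrongDims, cfg, acquisitionParams()),
               "upsampled simulation grid")
  ## noise-free output is nonnegative after the verified clip
  stk <- simulateRawStack(smallBeads(n = 2, seed = 1), cfg,
                          acquisitionParams(appliedDz = 0.17))
  expect_gte(min(arrayData(stk)), 0)
})
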