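## Shared fixtures, built lazily and cached for the whole test session.
## Two grids are used: a small one (64 x 16 x 64 camera voxels) for cheap
## unit checks, and a mid one (64 x 16 x 128) whose z extent resolves the
## light-sheet envelope (beam segments wider than one kz sample), needed by
## the retrieval/reconstruction property tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

smallCfg <- function() opticalConfig(gridShape = c(64L, 16L, 64L))
midCfg <- function() opticalConfig(gridShape = c(64L, 16L, 128L))

smallBeads <- function(n = 6, seed = 11) {
  cfg <- smallCfg()
  generateBeads(n, cfg, seed = seed,
                marginZ = 1.2 * latticeAxialPeriod(cfg))
}

midLibrary <- function() {
  fixture("midLibrary", function() simulateTfLibrary(midCfg()))
}

midBeads <- function() {
  fixture("midBeads", function() generateBeads(8, midCfg(), seed = 42))
}

midStackAt <- function(dzPi, snr = Inf, seed = 1L, sample = midBeads(),
                       phi = 0) {
  cfg <- midCfg()
  simulateRawStack(sample, cfg, acquisitionParams(
    appliedDz = piToDz(dzPi, latticeAxialPeriod(cfg)),
    appliedPhi = phi, snr = snr, seed = seed))
}

## detection PSFs are the slowest per-config piece; cache them indirectly by
## caching whole stacks/TF sets where tests share them
midCleanStack <- function() {
  fixture("midCleanStack", function() midStackAt(-0.4))
}

relErr <- function(a, b) {
  den <- sqrt(sum(Mod(b)^2))
  if (den == 0) sqrt(sum(Mod(a)^2)) else sqrt(sum(Mod(a - b)^2)) / den
}

## toy bands whose axial components are single delta harmonics: order m has
## one harmonic n(m), amplitude envelope shared, so Eq-style closed forms
## hold exactly. q in cycles/um; dz in um; phi0 the lateral starting phase.
toyHarmonicBands <- function(dz, q = 0.5, nOfM = c("0" = 0, "1" = 1, "2" = 2),
                             phi0 = 0, dims = c(16L, 4L, 32L)) {
  kz <- rep(latticeSIMfocus:::fftFreq(dims[3], 1 / (dims[3] * q * 0.25)),
            each = dims[1] * dims[2])
  ## smooth positive envelope over all of k-space (full support)
  env <- array(exp(-(kz / (4 * q))^2), dim = dims) + 0.1
  bands <- lapply(names(nOfM), function(mc) {
    m <- as.numeric(mc)
    env * exp(2i * pi * dz * nOfM[[mc]] * q) * exp(1i * m * phi0)
  })
  names(bands) <- names(nOfM)
  new("SeparatedBands", bands = bands,
      mRange = as.integer(names(nOfM)), pUsed = 0,
      tz = 1 / q, voxel = c(0.1, 0.1, 0.1), configKey = "toy")
}

toyHarmonicTfSet <- function(dzPrime, q = 0.5,
                             nOfM = c("0" = 0, "1" = 1, "2" = 2),
                             dims = c(16L, 4L, 32L)) {
  b <- toyHarmonicBands(dzPrime, q = q, nOfM = nOfM, phi0 = 0, dims = dims)
  new("TransferFunctionSet", otfs = b@bands, dzTag = dzPrime,
      mRange = b@mRange, pActual = 0, tz = 1 / q,
      voxel = c(0.1, 0.1, 0.1), configKey = "toy")
}

## sub-voxel full width at half maximum of a 1D profile
fwhmInterp <- function(prof) {
  idx <- which.max(prof)
  half <- prof[idx] / 2
  lo <- idx
  while (lo > 1 && prof[lo - 1] >= half) lo <- lo - 1
  hi <- idx
  while (hi < length(prof) && prof[hi + 1] >= half) hi <- hi + 1
  fl <- if (lo > 1) (prof[lo] - half) / (prof[lo] - prof[lo - 1]) else 0
  fh <- if (hi < length(prof)) (prof[hi] - half) / (prof[hi] - prof[hi + 1]) else 0
  (hi - lo) + fl + fh
}
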