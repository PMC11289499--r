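## Forward imaging model: D_j(r) = sum_m [(H Im) (x) (S Jm)](r), evaluated on
## the upsampled grid with periodic (FFT-native) boundaries and block-mean
## downsampled onto camera pixels.

## evaluate expr with a private RNG stream, restoring the caller's state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random point-emitter (bead) sample volume
#'
#' Places `nBeads` unit-intensity delta-like emitters (one upsampled voxel
#' each) uniformly at random, rejecting draws closer than `minSep` to an
#' already placed bead. Placement keeps a guard margin of two axial lattice
#' periods from the z faces and `marginXY` from the lateral faces so that
#' periodic wraparound of the detection PSF and of the ghost lobes does not
#' fold bead images across the volume boundary.
#'
#' @param nBeads number of beads (>= 1).
#' @param cfg an [OpticalConfig-class]; the volume is generated on its
#'   upsampled grid.
#' @param minSep minimum pairwise separation (um).
#' @param seed RNG seed; the same seed reproduces the same volume.
#' @param marginXY lateral guard margin (um).
#' @param marginZ axial guard margin (um); two axial lattice periods by
#'   default (ghost lobes extend about one period either side of a bead).
#' @return a [SampleVolume-class]; `@positions` holds the upsampled voxel
#'   index of each bead (rows: x, y, z).
#' @export
generateBeads <- function(nBeads, cfg, minSep = 0.5, seed = 1L,
                          marginXY = 1.0, marginZ = NULL) {
  stopifnot(nBeads >= 1)
  g <- upGrid(cfg)
  tz <- latticeAxialPeriod(cfg)
  if (is.null(marginZ)) marginZ <- 2 * tz
  ext <- g$n * g$d
  loZ <- marginZ; hiZ <- ext[3] - marginZ
  ## the margin is capped at a quarter extent so narrow axes (the sheet is
  ## y-invariant) still admit placements
  loX <- min(marginXY, ext[1] / 4); loY <- min(marginXY, ext[2] / 4)
  if (hiZ <= loZ)
    stop("placement error: volume too small for the guard margins")
  pos <- matrix(0, nBeads, 3)
  withSeed(seed, {
    placed <- 0L; tries <- 0L
    while (placed < nBeads) {
      tries <- tries + 1L
      if (tries > 1000L * nBeads)
        stop("placement error: could not place ", nBeads,
             " beads with minSep = ", minSep, " um")
      cand <- c(stats::runif(1, loX, ext[1] - loX),
                stats::runif(1, loY, ext[2] - loY),
                stats::runif(1, loZ, hiZ))
      if (placed > 0L) {
        d2 <- colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2)
        if (min(d2) < minSep^2) next
      }
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  })
  idx <- round(sweep(pos, 2, g$d, `/`)) + 1L     # voxel indices, 1-based
  idx <- pmin(pmax(idx, 1L), matrix(g$n, nBeads, 3, byrow = TRUE))
  vals <- array(0, dim = g$n)
  vals[idx] <- 1
  storage.mode(idx) <- "integer"
  colnames(idx) <- c("x", "y", "z")
  new("SampleVolume", values = vals, voxel = g$d, positions = idx)
}

#' A single centered delta emitter
#'
#' The calibration-bead sample: a unit delta at the grid origin. Its
#' simulated, band-separated stack equals the transfer-function set at the
#' same axial offset.
#' @param cfg an [OpticalConfig-class].
#' @return a [SampleVolume-class].
#' @export
makeDeltaSample <- function(cfg) {
  g <- upGrid(cfg)
  vals <- array(0, dim = g$n)
  ctr <- g$n %/% 2L + 1L
  vals[ctr[1], ctr[2], ctr[3]] <- 1
  pos <- matrix(ctr, 1, 3, dimnames = list(NULL, c("x", "y", "z")))
  new("SampleVolume", values = vals, voxel = g$d, positions = pos)
}

#' A filament-like extended test sample
#'
#' A smooth curved line (sinusoidal undulation in y and z, running along x)
#' of unit intensity, one upsampled voxel thick. Used to check that offset
#' retrieval is independent of the sample structure.
#' @param cfg an [OpticalConfig-class].
#' @param amplitude undulation amplitude (um).
#' @param period undulation period along x (um).
#' @return a [SampleVolume-class].
#' @export
makeFilamentSample <- function(cfg, amplitude = 1.0, period = 5.0) {
  g <- upGrid(cfg)
  tz <- latticeAxialPeriod(cfg)
  ext <- g$n * g$d
  vals <- array(0, dim = g$n)
  xs <- seq(1.0, ext[1] - 1.0, by = g$d[1])
  yc <- ext[2] / 2; zc <- ext[3] / 2
  zAmp <- min(amplitude, (ext[3] / 2 - 2 * tz) * 0.9)
  for (x in xs) {
    y <- yc + amplitude * 0.5 * sin(2 * pi * x / period)
    z <- zc + zAmp * cos(2 * pi * x / (1.7 * period))
    i <- pmin(pmax(round(c(x, y, z) / g$d) + 1L, 1L), g$n)
    vals[i[1], i[2], i[3]] <- 1
  }
  new("SampleVolume", values = vals, voxel = g$d,
      positions = matrix(integer(), 0, 3))
}

#' Phase-stepped acquisition parameters
#'
#' @param nPhases number of phase steps (default 5; must be at least the
#'   number of lateral orders).
#' @param phaseList phase steps (rad); default evenly covers one period.
#' @param appliedDz axial offset (um) of the excitation lattice relative to
#'   the detection focal plane.
#' @param appliedPhi lateral starting phase (rad).
#' @param snr peak-signal to noise-sigma ratio; `Inf` disables noise.
#' @param seed seed for the noise draw.
#' @return an [AcquisitionParams-class].
#' @export
acquisitionParams <- function(nPhases = 5L,
                              phaseList = 2 * pi * seq(0, nPhases - 1) / nPhases,
                              appliedDz = 0, appliedPhi = 0,
                              snr = Inf, seed = 1L) {
  new("AcquisitionParams", nPhases = as.integer(nPhases),
      phaseList = phaseList, appliedDz = appliedDz, appliedPhi = appliedPhi,
      snr = snr, seed = as.integer(seed))
}

## broadcast a z-profile over an (x, y, z) array
timesZProfile <- function(arr, prof) {
  d <- dim(arr)
  arr * rep(prof, each = d[1] * d[2])
}

#' Simulate a phase-stepped raw latticeSIM stack
#'
#' Implements the forward model order by order: the detection PSF is
#' multiplied by the axial excitation component Im(z) (carrying the applied
#' axial offset as a phase ramp), the sample by the lateral harmonic
#' Jm(x) = exp(2 pi i m p x); their spectra are multiplied and the orders
#' summed with the phase-step weights exp(i m (phi_j + appliedPhi)). The
#' result is evaluated on the upsampled grid and block-mean downsampled onto
#' camera pixels. Noise-free output is real and nonnegative up to numerical
#' ringing, which is verified to be below `clipTol` of the peak and clipped
#' at zero; Gaussian noise is added afterwards when `snr` is finite.
#'
#' @param S a [SampleVolume-class] on the upsampled grid of `cfg`.
#' @param cfg an [OpticalConfig-class].
#' @param acq an [AcquisitionParams-class].
#' @param clipTol tolerated relative magnitude of negative ringing.
#' @return a [RawSIMStack-class] on the camera grid, `(x, y, z, phase)`.
#' @export
simulateRawStack <- function(S, cfg, acq = acquisitionParams(),
                             clipTol = 1e-9) {
  g <- upGrid(cfg)
  if (!all(dim(S@values) == g$n))
    stop("sample dimensions must match the upsampled simulation grid (",
         paste(g$n, collapse = " x "), ")")
  geom <- makeLatticeGeometry(cfg)
  if (acq@nPhases < length(geom@mRange))
    stop("need at least as many phases as lateral orders")
  pupil <- applyAxialOffset(makeLatticePupil(cfg, geom), acq@appliedDz)
  dec <- decomposeExcitationOrders(pupil, geom)
  Hn <- ifftShift(makeDetectionPsf(cfg)@values)
  Sn <- ifftShift(S@values)
  xNat <- ifftShift(centeredCoords(g$n[1], g$d[1]))
  nPh <- acq@nPhases
  acc <- vector("list", nPh)
  for (i in seq_along(dec$mRange)) {
    m <- dec$mRange[i]
    IzNat <- ifftShift(dec$Iz[[as.character(m)]])
    HIf <- fftnd(timesZProfile(Hn, IzNat))
    SJf <- fftnd(Sn * exp(2i * pi * m * dec$pActual * xNat))
    term <- HIf * SJf
    rm(HIf, SJf)
    for (j in seq_len(nPh)) {
      w <- exp(1i * m * (acq@phaseList[j] + acq@appliedPhi))
      acc[[j]] <- if (is.null(acc[[j]])) term * w else acc[[j]] + term * w
    }
    rm(term)
  }
  nc <- cfg@gridShape
  out <- array(0, dim = c(nc, nPh))
  for (j in seq_len(nPh)) {
    D <- Re(ifftnd(acc[[j]]))
    acc[j] <- list(NULL)
    neg <- -min(D, 0)
    if (!all(is.finite(D))) stop("simulation error: non-finite intermediate")
    if (neg > clipTol * max(D))
      stop(sprintf(
        "simulation error: negative ringing %.2e exceeds tolerance", neg))
    D[D < 0] <- 0
    out[, , , j] <- blockDownsample(fftShift(D), g$u)
  }
  stack <- new("RawSIMStack", values = out,
               voxel = c(cfg@voxelXY, cfg@voxelXY, cfg@voxelZ),
               phases = acq@phaseList,
               meta = list(appliedDz = acq@appliedDz,
                           appliedPhi = acq@appliedPhi,
                           snr = Inf, seed = acq@seed,
                           pActual = dec$pActual,
                           tz = 1 / geom@qFund,
                           configKey = configKey(cfg)))
  if (is.finite(acq@snr)) stack <- addGaussianNoise(stack, acq@snr, acq@seed)
  stack
}

#' Add a Gaussian noise floor
#'
#' SNR is defined as the peak in-focus signal of the stack divided by the
#' noise standard deviation: `sigma = max(stack) / snr`. The noise is
#' zero-mean, i.i.d. across voxels and phases, and deterministic given
#' `seed`.
#'
#' @param stack a [RawSIMStack-class].
#' @param snr positive SNR; `Inf` returns the stack unchanged.
#' @param seed RNG seed.
#' @return the noisy [RawSIMStack-class].
#' @export
addGaussianNoise <- function(stack, snr, seed = 1L) {
  stopifnot(snr > 0)
  if (!is.finite(snr)) return(stack)
  sigma <- max(stack@values) / snr
  noise <- withSeed(seed, stats::rnorm(length(stack@values), sd = sigma))
  stack@values <- stack@values + array(noise, dim = dim(stack@values))
  stack@meta$snr <- snr
  stack@meta$seed <- seed
  stack
}

## shared by simulateTfSet / simulateTfLibrary: Hn = detection PSF in native
## order; pupilBase = lattice pupil with no ramps applied.
tfSetImpl <- function(Hn, pupilBase, geom, cfg, dzPrime) {
  g <- upGrid(cfg)
  dec <- decomposeExcitationOrders(applyAxialOffset(pupilBase, dzPrime), geom)
  otfs <- lapply(as.character(dec$mRange), function(mc) {
    IzNat <- ifftShift(dec$Iz[[mc]])
    fftnd(blockDownsample(fftShift(timesZProfile(Hn, IzNat)), g$u))
  })
  names(otfs) <- as.character(dec$mRange)
  new("TransferFunctionSet", otfs = otfs, dzTag = dzPrime,
      mRange = dec$mRange, pActual = dec$pActual, tz = 1 / geom@qFund,
      voxel = c(cfg@voxelXY, cfg@voxelXY, cfg@voxelZ),
      configKey = configKey(cfg))
}

#' Simulate the transfer functions at one calibration offset
#'
#' Computes, for each lateral order m, the transfer function
#' `O~'m(k) = FT{H(r) Im(z)}` with the excitation pattern displaced axially
#' by `dzPrime` and zero lateral phase -- exactly what band-separating a
#' simulated stack of a single centered calibration bead yields (the two
#' routes agree to numerical precision; the direct route skips the
#' redundant convolution with a delta).
#'
#' @param cfg an [OpticalConfig-class].
#' @param dzPrime calibration axial offset delta-z' (um).
#' @return a [TransferFunctionSet-class] on the camera grid.
#' @export
simulateTfSet <- function(cfg, dzPrime = 0) {
  geom <- makeLatticeGeometry(cfg)
  Hn <- ifftShift(makeDetectionPsf(cfg)@values)
  tfSetImpl(Hn, makeLatticePupil(cfg, geom), geom, cfg, dzPrime)
}

#' Simulate a library of transfer-function sets
#'
#' One [TransferFunctionSet-class] per axial offset node. The default grid
#' spans -1 to +1 pi units (one full half-period either side) in 0.1 pi
#' steps, covering the practically recoverable range of about one lattice
#' period.
#'
#' @param cfg an [OpticalConfig-class].
#' @param dzGridPi axial offsets in pi units (`2 dz / Tz`); ignored when
#'   `dzGrid` is given.
#' @param dzGrid axial offsets in um.
#' @return a [TFLibrary-class].
#' @export
simulateTfLibrary <- function(cfg, dzGridPi = seq(-1, 1, by = 0.1),
                              dzGrid = NULL) {
  geom <- makeLatticeGeometry(cfg)
  tz <- 1 / geom@qFund
  if (is.null(dzGrid)) dzGrid <- piToDz(dzGridPi, tz)
  Hn <- ifftShift(makeDetectionPsf(cfg)@values)
  pupilBase <- makeLatticePupil(cfg, geom)
  sets <- lapply(dzGrid, function(dz) tfSetImpl(Hn, pupilBase, geom, cfg, dz))
  new("TFLibrary", sets = sets, dzGrid = dzGrid, tz = tz,
      configKey = configKey(cfg))
}
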