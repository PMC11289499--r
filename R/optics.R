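## Pupils, PSFs and the lattice order decomposition.
##
## In-medium vs vacuum bookkeeping: all k-space radii (annulus, detection
## aperture) are NA / lambda_vacuum; the medium index enters only through the
## curvature of the Debye spherical cap (kz on the cap is
## sqrt((n/lambda)^2 - kr^2)).

#' Construct an optical configuration
#'
#' Defaults describe the hexagonal latticeSIM geometry used throughout the
#' package: excitation annulus NA 0.55/0.5, detection NA 1.0 in water
#' (n = 1.33), detection wavelength 0.605 um and excitation wavelength
#' 0.560 um (the excitation wavelength is chosen so the ideal hexagon
#' reproduces the instrument's 2.13 um axial lattice period:
#' Tz = 2 * lambda / NA_mid = 2.133 um). The default camera grid,
#' 128 x 32 x 128 voxels of 0.1 um, holds six axial lattice periods and keeps
#' a full retrieval run in the minutes range on one CPU.
#'
#' @param lambdaExc,lambdaDet excitation/detection wavelength (um).
#' @param nMedium immersion refractive index.
#' @param naDet detection NA.
#' @param naAnnMax,naAnnMin annulus bounds for the excitation pupil.
#' @param pattern `"hexagonal"` (default) or `"square"`.
#' @param gridShape camera grid `(nx, ny, nz)`; even, each >= 16.
#' @param voxelXY,voxelZ camera voxel size (um).
#' @param upsample simulation upsampling factor (default 2).
#' @return an [OpticalConfig-class] object.
#' @examples
#' cfg <- opticalConfig()
#' cfg
#' @export
opticalConfig <- function(lambdaExc = 0.560, lambdaDet = 0.605,
                          nMedium = 1.33, naDet = 1.0,
                          naAnnMax = 0.55, naAnnMin = 0.5,
                          pattern = c("hexagonal", "square"),
                          gridShape = c(128L, 32L, 128L),
                          voxelXY = 0.1, voxelZ = 0.1, upsample = 2L) {
  new("OpticalConfig", lambdaExc = lambdaExc, lambdaDet = lambdaDet,
      nMedium = nMedium, naDet = naDet, naAnnMax = naAnnMax,
      naAnnMin = naAnnMin, pattern = match.arg(pattern),
      gridShape = as.integer(gridShape), voxelXY = voxelXY, voxelZ = voxelZ,
      upsample = as.integer(upsample))
}

#' Deterministic key identifying a configuration
#'
#' Stacks, transfer-function libraries and separated bands carry this key;
#' retrieval refuses to mix objects generated under different keys.
#' @param cfg an [OpticalConfig-class].
#' @return a single character string.
#' @export
configKey <- function(cfg) {
  paste0("lam", cfg@lambdaExc, "/", cfg@lambdaDet,
         "_n", cfg@nMedium, "_na", cfg@naDet, "_ann", cfg@naAnnMax, "/",
         cfg@naAnnMin, "_", cfg@pattern,
         "_g", paste(cfg@gridShape, collapse = "x"),
         "_v", cfg@voxelXY, "/", cfg@voxelZ, "_u", cfg@upsample)
}

## upsampled grid helper
upGrid <- function(cfg) {
  u <- cfg@upsample
  list(n = cfg@gridShape * u,
       d = c(cfg@voxelXY, cfg@voxelXY, cfg@voxelZ) / u,
       u = u)
}

#' Axial period of the lattice (um)
#' @param x an [OpticalConfig-class] or [LatticeGeometry-class].
#' @return `Tz = 1/qFund` in um.
#' @export
latticeAxialPeriod <- function(x) {
  if (is(x, "OpticalConfig")) x <- makeLatticeGeometry(x)
  1 / x@qFund
}

#' Convert between um and pi-unit axial offsets
#'
#' Offsets are reported both in um and in "pi units" defined as
#' `offset_pi = 2 * dz / Tz`, so one full axial lattice period equals 2 pi.
#' @param dz axial offset (um).
#' @param dzPi axial offset (pi units).
#' @param tz axial lattice period (um).
#' @export
dzToPi <- function(dz, tz) 2 * dz / tz

#' @rdname dzToPi
#' @export
piToDz <- function(dzPi, tz) dzPi * tz / 2

## ---------------------------------------------------------------------------

#' Beam geometry of the illumination lattice
#'
#' For the hexagonal lattice the six beams sit at the vertices of a regular
#' hexagon of radius `k0 = NA_mid / lambdaExc` with two beams on the kz axis:
#' `(0, +/-k0)` and `(+/-(sqrt(3)/2) k0, +/-k0/2)`. This orientation yields
#' five lateral orders at multiples of `p = (sqrt(3)/2) k0` and axial
#' harmonics at multiples of `q = k0/2`, with the order support
#' `n(m) = {0,+/-2,+/-4}` for m = 0, `{+/-1,+/-3}` for m = +/-1 and
#' `{0,+/-2}` for m = +/-2. The square lattice uses four beams at
#' `(0, +/-k0)`, `(+/-k0, 0)` with `p = q = k0`.
#'
#' @param cfg an [OpticalConfig-class].
#' @return a [LatticeGeometry-class].
#' @examples
#' geom <- makeLatticeGeometry(opticalConfig())
#' 1 / geom@qFund   # axial period, um
#' @export
makeLatticeGeometry <- function(cfg) {
  naMid <- (cfg@naAnnMin + cfg@naAnnMax) / 2
  k0 <- naMid / cfg@lambdaExc
  if (cfg@pattern == "hexagonal") {
    s <- sqrt(3) / 2 * k0
    beams <- rbind(c(0, k0), c(0, -k0),
                   c(s, k0 / 2), c(s, -k0 / 2),
                   c(-s, k0 / 2), c(-s, -k0 / 2))
    p <- s; q <- k0 / 2
    ot <- list("-2" = c(-2L, 0L, 2L), "-1" = c(-3L, -1L, 1L, 3L),
               "0" = c(-4L, -2L, 0L, 2L, 4L),
               "1" = c(-3L, -1L, 1L, 3L), "2" = c(-2L, 0L, 2L))
  } else {
    beams <- rbind(c(0, k0), c(0, -k0), c(k0, 0), c(-k0, 0))
    p <- k0; q <- k0
    ot <- list("-2" = 0L, "-1" = c(-1L, 1L), "0" = c(-2L, 0L, 2L),
               "1" = c(-1L, 1L), "2" = 0L)
  }
  colnames(beams) <- c("kx", "kz")
  new("LatticeGeometry", beamCenters = beams, pFund = p, qFund = q,
      orderTable = ot, mRange = -2:2)
}

## ---------------------------------------------------------------------------

#' Detection PSF by the Debye approximation
#'
#' Builds the back pupil of a cone in a sphere (a uniform spherical cap of
#' half-angle asin(NA/n) on the sphere of radius `n/lambdaDet`) and
#' propagates it to real space plane by plane with the angular spectrum
#' (defocus phase `exp(2 pi i kz(kr) z)`, `kz = sqrt((n/lambda)^2 - kr^2)`).
#' The returned intensity `|field|^2` is normalized to unit sum with its peak
#' at the grid origin (index n/2 + 1 on every axis).
#'
#' @param cfg an [OpticalConfig-class].
#' @return a [PSF3D-class] of kind `"detection"` on the upsampled grid.
#' @export
makeDetectionPsf <- function(cfg) {
  g <- upGrid(cfg)
  nx <- g$n[1]; ny <- g$n[2]; nz <- g$n[3]
  kx <- fftFreq(nx, g$d[1]); ky <- fftFreq(ny, g$d[2])
  krMax <- cfg@naDet / cfg@lambdaDet
  if (krMax >= 1 / (2 * g$d[1]) || krMax >= 1 / (2 * g$d[2]))
    stop("sampling error: grid too small to contain the detection pupil cap; ",
         "reduce voxel size or raise upsampling")
  kr2 <- outer(kx^2, ky^2, `+`)
  ap <- kr2 <= krMax^2
  kSphere <- cfg@nMedium / cfg@lambdaDet
  kzCap <- sqrt(pmax(kSphere^2 - kr2, 0)) - kSphere   # piston removed
  zs <- centeredCoords(nz, g$d[3])
  H <- array(0, dim = c(nx, ny, nz))
  for (iz in seq_len(nz)) {
    P <- ap * exp(2i * pi * kzCap * zs[iz])
    e <- stats::fft(P, inverse = TRUE)
    H[, , iz] <- fftShift(Re(e)^2 + Im(e)^2)
  }
  new("PSF3D", values = H / sum(H), voxel = g$d, kind = "detection")
}

## ---------------------------------------------------------------------------

#' Lattice pupil: line segments clipped to the annulus
#'
#' Places a unit-amplitude vertical (kz-extended) line at each beam's kx,
#' keeping only the kz samples whose radius (at the beam's ideal kx) falls
#' inside the annulus. Each line occupies the nearest kx grid column; the
#' resulting effective lateral fundamental (an integer number of kx samples)
#' is recorded in `pActual` and shared with band shifting downstream, so the
#' simulator and the retrieval agree on the pattern frequency exactly.
#'
#' @param cfg an [OpticalConfig-class].
#' @param geom a [LatticeGeometry-class]; defaults to `makeLatticeGeometry(cfg)`.
#' @return a [Pupil-class] with a centered complex field over (kx, kz).
#' @export
makeLatticePupil <- function(cfg, geom = makeLatticeGeometry(cfg)) {
  g <- upGrid(cfg)
  nx <- g$n[1]; nz <- g$n[3]
  kStep <- c(1 / (nx * g$d[1]), 1 / (nz * g$d[3]))
  kzs <- centeredCoords(nz, 1) * kStep[2]      # centered kz values
  rMin <- cfg@naAnnMin / cfg@lambdaExc
  rMax <- cfg@naAnnMax / cfg@lambdaExc
  field <- matrix(0 + 0i, nx, nz)
  ctr <- nx / 2 + 1
  for (b in seq_len(nrow(geom@beamCenters))) {
    bx <- geom@beamCenters[b, 1]; bz <- geom@beamCenters[b, 2]
    icol <- ctr + round(bx / kStep[1])
    if (icol < 1 || icol > nx)
      stop("configuration error: beam kx outside the simulated pupil grid")
    r <- sqrt(bx^2 + kzs^2)
    seg <- r >= rMin & r <= rMax & sign(kzs) == sign(bz)
    if (!any(seg))
      stop("configuration error: beam falls outside the annulus at the ",
           "grid sampling; enlarge the grid or the annulus")
    field[icol, seg] <- 1 + 0i
  }
  pSamples <- round(geom@pFund / kStep[1])
  if (pSamples < 1)
    stop("configuration error: lateral fundamental below one frequency sample")
  new("Pupil", field = field, kStep = kStep,
      annulus = c(cfg@naAnnMin, cfg@naAnnMax), lambdaExc = cfg@lambdaExc,
      pActual = pSamples * kStep[1], dzApplied = 0, phiApplied = 0)
}

#' Encode an axial focal offset as a kz phase ramp
#'
#' Multiplies the pupil field by `exp(2 pi i kz dz)`, so every axial
#' harmonic n q acquires the phase `exp(2 pi i n q dz)` and the excitation
#' pattern translates rigidly by `dz` along z (with this sign convention,
#' pattern features move toward -z for positive `dz`; data and calibration
#' share the convention, so retrieved offsets are directly comparable to
#' applied ones).
#'
#' @param pupil a [Pupil-class].
#' @param dz axial offset (um).
#' @return the offset [Pupil-class].
#' @export
applyAxialOffset <- function(pupil, dz) {
  stopifnot(is.finite(dz))
  nz <- ncol(pupil@field)
  kzs <- centeredCoords(nz, 1) * pupil@kStep[2]
  zExtent <- 1 / pupil@kStep[2]
  if (abs(dz) > zExtent / 2)
    warning("axial offset exceeds half the grid z-extent; ",
            "the pattern wraps around")
  pupil@field <- pupil@field *
    matrix(exp(2i * pi * kzs * dz), nrow(pupil@field), nz, byrow = TRUE)
  pupil@dzApplied <- pupil@dzApplied + dz
  pupil
}

#' Encode a lateral starting phase as a kx phase ramp
#'
#' Convention: `phi = 2 pi` translates the pattern by one full lateral period
#' `Tx = 1/p`. The ramp applied is `exp(i kx phi / pActual)`, so a beam at
#' `kx = m * pActual` picks up the phase `m * phi`.
#'
#' @param pupil a [Pupil-class].
#' @param phi lateral starting phase (rad).
#' @return the phased [Pupil-class].
#' @export
applyLateralPhase <- function(pupil, phi) {
  stopifnot(is.finite(phi))
  nx <- nrow(pupil@field)
  kxs <- centeredCoords(nx, 1) * pupil@kStep[1]
  pupil@field <- pupil@field * exp(1i * kxs / pupil@pActual * phi)
  pupil@phiApplied <- pupil@phiApplied + phi
  pupil
}

## 2D excitation pattern (x, z), centered layout, not normalized
excitationPattern2d <- function(pupil) {
  e <- stats::fft(ifftShift(pupil@field), inverse = TRUE)
  fftShift(Re(e)^2 + Im(e)^2)
}

#' Excitation PSF (intensity) from a pupil
#'
#' The light sheet is treated as invariant along the propagation axis y over
#' the simulated field of view: the interference pattern
#' `|FT(pupil)|^2` is formed in (x, z) and replicated along y. The result is
#' normalized to unit maximum.
#'
#' @param pupil a [Pupil-class].
#' @param cfg the generating [OpticalConfig-class] (for the y extent).
#' @return a [PSF3D-class] of kind `"excitation"` on the upsampled grid.
#' @export
excitationPsfFromPupil <- function(pupil, cfg) {
  g <- upGrid(cfg)
  I2 <- excitationPattern2d(pupil)
  I2 <- I2 / max(I2)
  vals <- array(rep(I2, each = 1), dim = c(g$n[1], 1, g$n[3]))
  vals <- vals[, rep(1, g$n[2]), , drop = FALSE]
  new("PSF3D", values = vals, voxel = g$d, kind = "excitation")
}

#' Excitation pattern displaced along the propagation axis
#'
#' Propagates the pupil field by `yOffset` with the angular spectrum before
#' forming the intensity: each plane-wave component at (kx, kz) advances by
#' `exp(2 pi i ky yOffset)` with `ky = sqrt((n/lambda)^2 - kx^2 - kz^2)`.
#' At `yOffset = 0` this reduces to [excitationPsfFromPupil()]; away from the
#' waist the pattern loses modulation contrast symmetrically in +/- y.
#'
#' @param pupil a [Pupil-class].
#' @param yOffset displacement along the beam propagation direction (um).
#' @param cfg the generating [OpticalConfig-class].
#' @return a [PSF3D-class] of kind `"excitation"`.
#' @export
propagateAlongY <- function(pupil, yOffset, cfg) {
  stopifnot(is.finite(yOffset))
  nx <- nrow(pupil@field); nz <- ncol(pupil@field)
  kxs <- centeredCoords(nx, 1) * pupil@kStep[1]
  kzs <- centeredCoords(nz, 1) * pupil@kStep[2]
  kSphere <- cfg@nMedium / cfg@lambdaExc
  ky2 <- kSphere^2 - outer(kxs^2, kzs^2, `+`)
  ky <- sqrt(pmax(ky2, 0)) - kSphere           # piston removed
  pupil@field <- pupil@field * exp(2i * pi * ky * yOffset) * (ky2 > 0)
  excitationPsfFromPupil(pupil, cfg)
}

## ---------------------------------------------------------------------------

#' Decompose the excitation pattern into lateral orders
#'
#' Computes the excitation OTF (the spectrum of `|FT(pupil)|^2`, i.e. the
#' autocorrelation of the pupil) and extracts, for each lateral order m, the
#' kx column at `m * pActual` as the axial spectrum `I~m(kz)`. For the ideal
#' single-sample line pupil the order bands are exactly one kx sample wide;
#' the function verifies that no appreciable energy lies outside the order
#' columns and errors otherwise (overlapping bands cannot be unmixed).
#'
#' @param pupil a [Pupil-class] (with any axial/lateral ramps applied).
#' @param geom the matching [LatticeGeometry-class].
#' @param tol relative off-band energy tolerated before declaring the
#'   decomposition invalid.
#' @return a list with elements `mRange`, `pActual`, and per-order lists
#'   `Ikz` (complex axial spectra over kz, native FFT order) and `Iz`
#'   (complex axial profiles Im(z), centered layout).
#' @export
decomposeExcitationOrders <- function(pupil, geom, tol = 1e-9) {
  I2 <- excitationPattern2d(pupil)            # centered (x, z)
  Ik <- stats::fft(ifftShift(I2))             # native (kx, kz)
  nx <- nrow(Ik)
  pSamples <- round(pupil@pActual / pupil@kStep[1])
  mRange <- geom@mRange
  cols <- 1 + ((mRange * pSamples) %% nx)     # native kx index per order
  colEnergy <- colSums(t(Mod(Ik)^2))          # energy per kx column
  offBand <- sum(colEnergy[-cols]) / sum(colEnergy)
  if (offBand > tol)
    stop("decomposition error: excitation orders overlap in kx ",
         sprintf("(off-band energy %.2e)", offBand))
  Ikz <- lapply(seq_along(mRange), function(i) Ik[cols[i], ])
  names(Ikz) <- as.character(mRange)
  Iz <- lapply(Ikz, function(v) fftShift(ifftnd(v)))
  list(mRange = mRange, pActual = pupil@pActual, Ikz = Ikz, Iz = Iz)
}

## ---------------------------------------------------------------------------

#' Measure the axial period of an excitation pattern
#'
#' Takes the z-spectrum of the pattern, locates contiguous peak clusters
#' above `frac` of the strongest non-DC peak, and returns the period
#' `1 / f0` where `f0` is the magnitude-weighted centroid of the
#' lowest-frequency cluster -- the fundamental axial frequency of the
#' pattern.
#'
#' With `xAverage = TRUE` the profile is averaged over x first. Averaging
#' over x retains only the m = 0 lateral band, whose axial orders are even
#' (n = 0, +/-2, +/-4 for the hexagonal lattice), so the measured period is
#' then Tz/2: the x-averaged profile repeats twice per lattice period, which
#' is why the half-period-offset pattern looks nearly identical to the
#' aligned one in that projection.
#'
#' @param x a [PSF3D-class] (excitation) or a numeric (x, z) matrix in
#'   centered layout.
#' @param voxelZ axial sample spacing (um); taken from the PSF when omitted.
#' @param xAverage average over x before transforming (see Details).
#' @param frac cluster detection threshold, relative to the strongest
#'   non-DC peak.
#' @return the axial period (um).
#' @export
measureAxialPeriod <- function(x, voxelZ = NULL, xAverage = FALSE,
                               frac = 0.2) {
  if (is(x, "PSF3D")) {
    if (is.null(voxelZ)) voxelZ <- x@voxel[3]
    v <- x@values
    P <- v[, dim(v)[2] %/% 2 + 1, ]           # any y slice (y-invariant)
  } else {
    P <- x
    if (is.null(voxelZ)) stop("voxelZ required for a plain matrix")
  }
  nz <- ncol(P)
  if (xAverage) {
    mag <- Mod(stats::fft(colMeans(P)))
  } else {
    sp <- stats::mvfft(t(P))                  # fft along z per x column
    mag <- rowSums(Mod(sp))
  }
  pos <- mag[2:(nz / 2)]                      # positive frequencies
  freqs <- (1:(nz / 2 - 1)) / (nz * voxelZ)
  ## drop DC-leakage bins right next to zero frequency
  guard <- 2L
  pos[seq_len(guard)] <- 0
  thr <- frac * max(pos)
  above <- pos > thr
  if (!any(above)) stop("no axial modulation found")
  i0 <- which(above)[1]
  iEnd <- i0
  while (iEnd < length(above) && above[iEnd + 1]) iEnd <- iEnd + 1
  cl <- i0:iEnd
  f0 <- sum(freqs[cl] * pos[cl]) / sum(pos[cl])
  1 / f0
}
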