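#' @import methods
NULL

## ---------------------------------------------------------------------------
## Optical configuration
## ---------------------------------------------------------------------------

#' Optical configuration for a latticeSIM instrument
#'
#' Bundles the wavelengths, numerical apertures, lattice pattern choice and
#' simulation grid used by every stage of the package. The defaults describe
#' the instrument geometry assumed throughout: a hexagonal lattice bounded by
#' an NA 0.55/0.5 annulus at the excitation back pupil, a 1.0 NA detection
#' objective in water (n = 1.33), and a simulation grid that is 2x upsampled
#' relative to the camera voxels so the continuous image-formation physics is
#' sampled finely before discretization.
#'
#' @slot lambdaExc excitation wavelength (um).
#' @slot lambdaDet detection (emission) wavelength (um).
#' @slot nMedium refractive index of the immersion medium.
#' @slot naDet detection numerical aperture.
#' @slot naAnnMax,naAnnMin outer/inner NA of the annular excitation mask.
#' @slot pattern `"hexagonal"` or `"square"`.
#' @slot gridShape integer `(nx, ny, nz)` camera voxels.
#' @slot voxelXY,voxelZ camera voxel size (um) laterally / axially.
#' @slot upsample integer simulation upsampling factor (>= 1).
#' @seealso [opticalConfig()]
#' @export
setClass("OpticalConfig", representation(
  lambdaExc = "numeric", lambdaDet = "numeric", nMedium = "numeric",
  naDet = "numeric", naAnnMax = "numeric", naAnnMin = "numeric",
  pattern = "character", gridShape = "integer",
  voxelXY = "numeric", voxelZ = "numeric", upsample = "integer"
))

setValidity("OpticalConfig", function(object) {
  msg <- character()
  if (!(object@naAnnMin > 0 && object@naAnnMin < object@naAnnMax &&
        object@naAnnMax <= object@naDet && object@naDet <= object@nMedium))
    msg <- c(msg, "need 0 < naAnnMin < naAnnMax <= naDet <= nMedium")
  if (!object@pattern %in% c("hexagonal", "square"))
    msg <- c(msg, "pattern must be 'hexagonal' or 'square'")
  if (length(object@gridShape) != 3L || any(object@gridShape < 16L) ||
      any(object@gridShape %% 2L != 0L))
    msg <- c(msg, "gridShape must be 3 even integers >= 16")
  if (object@upsample < 1L) msg <- c(msg, "upsample must be >= 1")
  if (any(c(object@lambdaExc, object@lambdaDet, object@voxelXY,
            object@voxelZ) <= 0))
    msg <- c(msg, "wavelengths and voxel sizes must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Lattice geometry
## ---------------------------------------------------------------------------

#' Interference geometry of the excitation lattice
#'
#' Holds the beam positions at the back pupil and the fundamental spatial
#' frequencies of the resulting interference pattern: `pFund` laterally (the
#' lateral SIM orders sit at m * pFund) and `qFund` axially (the axial
#' harmonics of order m sit at n * qFund for the n listed in `orderTable`).
#' `TxFund = 1/pFund` and `Tz = 1/qFund` are the pattern periods.
#'
#' @slot beamCenters numeric matrix, one row per beam, columns `(kx, kz)` in
#'   cycles/um.
#' @slot pFund,qFund fundamental lateral/axial frequency (cycles/um).
#' @slot orderTable named list mapping each lateral order m to the integer
#'   axial orders n it carries.
#' @slot mRange integer vector of lateral orders.
#' @export
setClass("LatticeGeometry", representation(
  beamCenters = "matrix", pFund = "numeric", qFund = "numeric",
  orderTable = "list", mRange = "integer"
))

setValidity("LatticeGeometry", function(object) {
  msg <- character()
  if (!is.finite(object@pFund) || object@pFund <= 0 ||
      !is.finite(object@qFund) || object@qFund <= 0)
    msg <- c(msg, "pFund and qFund must be positive and finite")
  if (!setequal(names(object@orderTable), as.character(object@mRange)))
    msg <- c(msg, "orderTable names must match mRange")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Pupil
## ---------------------------------------------------------------------------

#' Complex excitation pupil over (kx, kz)
#'
#' The field is stored with the zero-frequency sample at the array center
#' (row/column `n/2 + 1`) for readability; transforms shift it internally.
#' Axial and lateral focal offsets are encoded as phase ramps on this field
#' (see [applyAxialOffset()] and [applyLateralPhase()]).
#'
#' @slot field complex matrix over (kx, kz), centered layout.
#' @slot kStep frequency per sample (cycles/um) along both axes.
#' @slot annulus `(naMin, naMax)` of the clipping annulus.
#' @slot lambdaExc excitation wavelength (um) the annulus radii refer to.
#' @slot pActual effective lateral fundamental frequency after snapping beam
#'   columns to the grid (cycles/um); an integer multiple of `kStep`.
#' @slot dzApplied,phiApplied cumulative axial offset (um) and lateral starting
#'   phase (rad) encoded on the field, for provenance.
#' @export
setClass("Pupil", representation(
  field = "matrix", kStep = "numeric", annulus = "numeric",
  lambdaExc = "numeric", pActual = "numeric",
  dzApplied = "numeric", phiApplied = "numeric"
))

setValidity("Pupil", function(object) {
  if (!is.complex(object@field)) return("field must be complex")
  if (length(object@annulus) != 2L) return("annulus must be (naMin, naMax)")
  TRUE
})

## ---------------------------------------------------------------------------
## Real-space volumes
## ---------------------------------------------------------------------------

#' A 3D point-spread function
#'
#' Real, nonnegative intensity over `(x, y, z)` with the peak convention that
#' the grid origin (index `n/2 + 1` on each axis) is the focal position.
#'
#' @slot values real nonnegative array `(x, y, z)`.
#' @slot voxel voxel sizes (um) per axis.
#' @slot kind `"detection"` or `"excitation"`.
#' @export
setClass("PSF3D", representation(
  values = "array", voxel = "numeric", kind = "character"
))

setValidity("PSF3D", function(object) {
  if (any(!is.finite(object@values))) return("PSF values must be finite")
  if (min(object@values) < 0) return("PSF values must be nonnegative")
  TRUE
})

#' Fluorophore density volume S(r)
#'
#' @slot values real nonnegative 3D array `(x, y, z)`.
#' @slot voxel voxel sizes (um).
#' @slot positions optional integer matrix of point-emitter voxel indices
#'   (one row per bead), kept for artifact scoring.
#' @export
setClass("SampleVolume", representation(
  values = "array", voxel = "numeric", positions = "matrix"
))

setValidity("SampleVolume", function(object) {
  if (any(!is.finite(object@values)) || min(object@values) < 0)
    return("sample values must be finite and nonnegative")
  TRUE
})

## ---------------------------------------------------------------------------
## Acquisition
## ---------------------------------------------------------------------------

#' Phase-stepped acquisition parameters
#'
#' @slot nPhases number of lateral phase steps (5 for the hexagonal lattice).
#' @slot phaseList phases (rad), default `2*pi*(0:4)/5`.
#' @slot appliedDz axial offset (um) of the excitation lattice relative to the
#'   detection focal plane during acquisition.
#' @slot appliedPhi lateral starting phase (rad) of the pattern.
#' @slot snr peak-signal-to-noise-sigma ratio; `Inf` means noise-free.
#' @slot seed RNG seed for the noise draw.
#' @export
setClass("AcquisitionParams", representation(
  nPhases = "integer", phaseList = "numeric",
  appliedDz = "numeric", appliedPhi = "numeric",
  snr = "numeric", seed = "integer"
))

setValidity("AcquisitionParams", function(object) {
  if (length(object@phaseList) != object@nPhases)
    return("phaseList length must equal nPhases")
  ph <- object@phaseList %% (2 * pi)
  if (anyDuplicated(round(ph, 12)))
    return("phases must be distinct modulo 2*pi")
  TRUE
})

#' Raw phase-stepped latticeSIM stack
#'
#' Stored as a real 4D array `(x, y, z, phase)` on the camera grid, together
#' with the provenance needed to reproduce it.
#'
#' @slot values real 4D array `(x, y, z, phase)`.
#' @slot voxel camera voxel sizes (um).
#' @slot phases the lateral phase steps (rad).
#' @slot meta list with at least `appliedDz`, `appliedPhi`, `snr`, `seed`,
#'   `pActual`, `configKey`.
#' @export
setClass("RawSIMStack", representation(
  values = "array", voxel = "numeric", phases = "numeric", meta = "list"
))

setValidity("RawSIMStack", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L) return("values must be a 4D (x, y, z, phase) array")
  if (d[4] != length(object@phases))
    return("4th dimension must equal the number of phases")
  if (any(!is.finite(object@values))) return("stack values must be finite")
  TRUE
})

## ---------------------------------------------------------------------------
## Frequency-space containers
## ---------------------------------------------------------------------------

#' Per-order transfer functions at one calibration offset
#'
#' One complex 3D OTF per lateral order m, on the camera grid in native FFT
#' order, simulated (or measured) with a known axial offset `dzTag` between
#' excitation lattice and detection focal plane and zero lateral phase.
#'
#' @slot otfs named list (names = m) of complex arrays.
#' @slot dzTag calibration axial offset delta-z' (um).
#' @slot mRange integer lateral orders present.
#' @slot pActual effective lateral fundamental (cycles/um) shared with the
#'   simulator.
#' @slot tz axial lattice period (um), used for pi-unit conversion.
#' @slot voxel camera voxel sizes (um).
#' @slot configKey deterministic key of the generating configuration.
#' @export
setClass("TransferFunctionSet", representation(
  otfs = "list", dzTag = "numeric", mRange = "integer",
  pActual = "numeric", tz = "numeric", voxel = "numeric", configKey = "character"
))

setValidity("TransferFunctionSet", function(object) {
  if (!setequal(names(object@otfs), as.character(object@mRange)))
    return("otfs names must match mRange")
  TRUE
})

#' Library of transfer-function sets over a grid of axial offsets
#'
#' @slot sets list of [TransferFunctionSet-class] entries.
#' @slot dzGrid axial offsets (um) of the entries.
#' @slot tz axial lattice period (um).
#' @slot configKey deterministic key of the generating configuration.
#' @export
setClass("TFLibrary", representation(
  sets = "list", dzGrid = "numeric", tz = "numeric", configKey = "character"
))

setValidity("TFLibrary", function(object) {
  if (length(object@sets) != length(object@dzGrid))
    return("one dzGrid value per set required")
  if (length(object@sets) == 0L) return("library must be nonempty")
  TRUE
})

#' Lateral-order components of a raw stack
#'
#' The result of inverting the phase mixing matrix: one complex spectrum
#' D~m(k) per lateral order, unshifted (centered at kx = 0 as acquired).
#'
#' @slot bands named list (names = m) of complex arrays.
#' @slot mRange integer lateral orders.
#' @slot pUsed lateral fundamental (cycles/um) to be used when shifting.
#' @slot tz axial lattice period (um).
#' @slot voxel camera voxel sizes (um).
#' @slot configKey deterministic key of the generating configuration.
#' @export
setClass("SeparatedBands", representation(
  bands = "list", mRange = "integer", pUsed = "numeric",
  tz = "numeric", voxel = "numeric", configKey = "character"
))

setValidity("SeparatedBands", function(object) {
  if (!setequal(names(object@bands), as.character(object@mRange)))
    return("band names must match mRange")
  TRUE
})

#' Overlap-region ratio field between two shifted orders
#'
#' @slot ratio complex array R(k) on the overlap support (0 elsewhere).
#' @slot numerator complex array N * conj(D); `Arg()` of it is the residual
#'   phase actually consumed by the metric.
#' @slot mask logical support array.
#' @slot weights nonnegative array (product-magnitude based), 0 off mask.
#' @slot pair the `(m1, m2)` order pair.
#' @export
setClass("OverlapRatioField", representation(
  ratio = "array", numerator = "array", mask = "array",
  weights = "array", pair = "integer"
))

setValidity("OverlapRatioField", function(object) {
  if (object@pair[1] == object@pair[2]) return("pair orders must differ")
  if (any(object@weights[!object@mask] != 0))
    return("weights must vanish off the mask")
  TRUE
})

#' 2D residual-phase metric surface over (dz', phi) candidates
#'
#' @slot metric real matrix, rows = library axial offsets, cols = lateral
#'   phase candidates.
#' @slot dzGrid library axial offsets (um).
#' @slot dzGridPi the same in pi units (`2 * dz / Tz`).
#' @slot phiGrid lateral phase candidates (rad) spanning (-pi, pi].
#' @slot pairs list of order pairs summed into the metric.
#' @export
setClass("ResidualPhaseMap", representation(
  metric = "matrix", dzGrid = "numeric", dzGridPi = "numeric",
  phiGrid = "numeric", pairs = "list"
))

setValidity("ResidualPhaseMap", function(object) {
  if (!all(dim(object@metric) == c(length(object@dzGrid),
                                   length(object@phiGrid))))
    return("metric shape must match grids")
  if (min(object@metric) < -1e-12) return("metric must be nonnegative")
  TRUE
})

#' Retrieved focal-plane offset
#'
#' @slot dzHat retrieved axial offset (um).
#' @slot dzHatPi the same in pi units.
#' @slot phiHat retrieved lateral phase (rad), inside the lateral search range.
#' @slot metricAtMin metric value at the minimum.
#' @slot secondary list `(dz, dzPi, phi, metric)` for the half-period-off
#'   local minimum of the unrestricted map, or empty list if none found.
#' @slot ambiguityRatio metric gap between the two minima normalized by the
#'   map range; small values flag an ambiguous retrieval.
#' @slot searchRangeLateral the lateral range the primary minimum was
#'   restricted to.
#' @slot degenerate TRUE when the map was flat and the tie-break (smallest
#'   |dz|) decided the answer.
#' @export
setClass("OffsetEstimate", representation(
  dzHat = "numeric", dzHatPi = "numeric", phiHat = "numeric",
  metricAtMin = "numeric", secondary = "list", ambiguityRatio = "numeric",
  searchRangeLateral = "numeric", degenerate = "logical"
))

#' Reconstructed SIM volume
#'
#' @slot values real 3D array `(x, y, z)`.
#' @slot voxel voxel sizes (um).
#' @slot provenance list: `dzTf` (TF offset used, um), `phi`, `wiener`,
#'   `apodized`.
#' @export
setClass("ReconVolume", representation(
  values = "array", voxel = "numeric", provenance = "list"
))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig:", object@pattern, "lattice\n")
  cat(sprintf("  lambda exc/det: %.3f / %.3f um, n = %.2f\n",
              object@lambdaExc, object@lambdaDet, object@nMedium))
  cat(sprintf("  NA det %.2f, annulus %.2f/%.2f\n",
              object@naDet, object@naAnnMax, object@naAnnMin))
  cat(sprintf("  camera grid %d x %d x %d, voxel %.3f/%.3f um, upsample %dx\n",
              object@gridShape[1], object@gridShape[2], object@gridShape[3],
              object@voxelXY, object@voxelZ, object@upsample))
})

setMethod("show", "LatticeGeometry", function(object) {
  cat(sprintf("LatticeGeometry: %d beams, m in {%s}\n",
              nrow(object@beamCenters),
              paste(object@mRange, collapse = ", ")))
  cat(sprintf("  p = %.4f, q = %.4f cycles/um (Tx = %.3f, Tz = %.3f um)\n",
              object@pFund, object@qFund, 1 / object@pFund, 1 / object@qFund))
})

setMethod("show", "Pupil", function(object) {
  cat(sprintf("Pupil: %d x %d samples, kStep %.4f/%.4f cycles/um, annulus NA %.2f-%.2f\n",
              nrow(object@field), ncol(object@field), object@kStep[1],
              object@kStep[2], object@annulus[1], object@annulus[2]))
  cat(sprintf("  %d nonzero samples; dz = %.4f um, phi = %.4f rad\n",
              sum(object@field != 0), object@dzApplied, object@phiApplied))
})

setMethod("show", "RawSIMStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("RawSIMStack: %d x %d x %d voxels, %d phases\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel %.3f x %.3f x %.3f um; applied dz = %s um, snr = %s\n",
              object@voxel[1], object@voxel[2], object@voxel[3],
              format(object@meta$appliedDz), format(object@meta$snr)))
})

setMethod("show", "TransferFunctionSet", function(object) {
  cat(sprintf("TransferFunctionSet: orders {%s}, dz' = %.4f um (%.2f pi)\n",
              paste(object@mRange, collapse = ", "), object@dzTag,
              2 * object@dzTag / object@tz))
})

setMethod("show", "TFLibrary", function(object) {
  cat(sprintf("TFLibrary: %d entries, dz' in [%.3f, %.3f] um (%.2f..%.2f pi)\n",
              length(object@sets), min(object@dzGrid), max(object@dzGrid),
              2 * min(object@dzGrid) / object@tz,
              2 * max(object@dzGrid) / object@tz))
})

setMethod("show", "SeparatedBands", function(object) {
  cat(sprintf("SeparatedBands: orders {%s}, p = %.4f cycles/um\n",
              paste(object@mRange, collapse = ", "), object@pUsed))
})

setMethod("show", "ResidualPhaseMap", function(object) {
  cat(sprintf("ResidualPhaseMap: %d dz' x %d phi candidates, pairs %s\n",
              length(object@dzGrid), length(object@phiGrid),
              paste(vapply(object@pairs, function(p)
                sprintf("(%d,%d)", p[1], p[2]), ""), collapse = " ")))
  cat(sprintf("  metric range [%.3g, %.3g]\n",
              min(object@metric), max(object@metric)))
})

setMethod("show", "OffsetEstimate", function(object) {
  cat(sprintf("OffsetEstimate: dz = %.4f um (%.3f pi), phi = %.4f rad\n",
              object@dzHat, object@dzHatPi, object@phiHat))
  cat(sprintf("  metric %.4g; ambiguity ratio %.3f%s\n",
              object@metricAtMin, object@ambiguityRatio,
              if (object@degenerate) " [degenerate map]" else ""))
  if (length(object@secondary))
    cat(sprintf("  secondary minimum: dz = %.4f um (%.3f pi), phi = %.4f, metric %.4g\n",
                object@secondary$dz, object@secondary$dzPi,
                object@secondary$phi, object@secondary$metric))
})

setMethod("show", "ReconVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ReconVolume: %d x %d x %d, TF dz' = %s um, wiener %.2g\n",
              d[1], d[2], d[3], format(object@provenance$dzTf),
              object@provenance$wiener))
})
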