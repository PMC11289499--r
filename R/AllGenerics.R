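## Accessor generics. Slots are never reached into from user code.

#' Extract the numeric array payload of an image-like object
#' @param x a PSF3D, SampleVolume, RawSIMStack or ReconVolume.
#' @return the underlying numeric array.
#' @export
setGeneric("arrayData", function(x) standardGeneric("arrayData"))

#' @rdname arrayData
#' @export
setMethod("arrayData", "PSF3D", function(x) x@values)
#' @rdname arrayData
#' @export
setMethod("arrayData", "SampleVolume", function(x) x@values)
#' @rdname arrayData
#' @export
setMethod("arrayData", "RawSIMStack", function(x) x@values)
#' @rdname arrayData
#' @export
setMethod("arrayData", "ReconVolume", function(x) x@values)

#' Voxel sizes (um) of an image-like object
#' @param x an object with a voxel slot.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "PSF3D", function(x) x@voxel)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "SampleVolume", function(x) x@voxel)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "RawSIMStack", function(x) x@voxel)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "ReconVolume", function(x) x@voxel)

#' Lateral orders present in a frequency-space container
#' @param x a SeparatedBands or TransferFunctionSet.
#' @export
setGeneric("orderRange", function(x) standardGeneric("orderRange"))

#' @rdname orderRange
#' @export
setMethod("orderRange", "SeparatedBands", function(x) x@mRange)
#' @rdname orderRange
#' @export
setMethod("orderRange", "TransferFunctionSet", function(x) x@mRange)

#' Retrieve one lateral-order component
#' @param x a SeparatedBands or TransferFunctionSet.
#' @param m integer lateral order.
#' @return complex 3D array in native FFT order.
#' @export
setGeneric("orderComponent", function(x, m) standardGeneric("orderComponent"))

#' @rdname orderComponent
#' @export
setMethod("orderComponent", "SeparatedBands", function(x, m) {
  x@bands[[as.character(m)]]
})
#' @rdname orderComponent
#' @export
setMethod("orderComponent", "TransferFunctionSet", function(x, m) {
  x@otfs[[as.character(m)]]
})

#' Calibration axial offset (um) of a transfer-function set
#' @param x a TransferFunctionSet.
#' @export
setGeneric("dzTag", function(x) standardGeneric("dzTag"))

#' @rdname dzTag
#' @export
setMethod("dzTag", "TransferFunctionSet", function(x) x@dzTag)

#' Axial offset grid of a transfer-function library
#' @param x a TFLibrary or ResidualPhaseMap.
#' @param units `"um"` or `"pi"`.
#' @export
setGeneric("dzGrid", function(x, units = c("um", "pi")) standardGeneric("dzGrid"))

#' @rdname dzGrid
#' @export
setMethod("dzGrid", "TFLibrary", function(x, units = c("um", "pi")) {
  if (match.arg(units) == "um") x@dzGrid else 2 * x@dzGrid / x@tz
})
#' @rdname dzGrid
#' @export
setMethod("dzGrid", "ResidualPhaseMap", function(x, units = c("um", "pi")) {
  if (match.arg(units) == "um") x@dzGrid else x@dzGridPi
})

#' Lateral phase candidate grid (rad) of a residual-phase map
#' @param x a ResidualPhaseMap.
#' @export
setGeneric("phiGrid", function(x) standardGeneric("phiGrid"))

#' @rdname phiGrid
#' @export
setMethod("phiGrid", "ResidualPhaseMap", function(x) x@phiGrid)

#' The residual-phase metric surface as a matrix (dz' rows, phi columns)
#' @param x a ResidualPhaseMap.
#' @export
setGeneric("metricMap", function(x) standardGeneric("metricMap"))

#' @rdname metricMap
#' @export
setMethod("metricMap", "ResidualPhaseMap", function(x) x@metric)

#' Retrieved axial offset
#' @param x an OffsetEstimate.
#' @param units `"um"` or `"pi"` (pi units are `2 * dz / Tz`).
#' @export
setGeneric("dzHat", function(x, units = c("um", "pi")) standardGeneric("dzHat"))

#' @rdname dzHat
#' @export
setMethod("dzHat", "OffsetEstimate", function(x, units = c("um", "pi")) {
  if (match.arg(units) == "um") x@dzHat else x@dzHatPi
})

#' Retrieved lateral starting phase (rad)
#' @param x an OffsetEstimate.
#' @export
setGeneric("phiHat", function(x) standardGeneric("phiHat"))

#' @rdname phiHat
#' @export
setMethod("phiHat", "OffsetEstimate", function(x) x@phiHat)

#' Phase steps (rad) of a raw stack
#' @param x a RawSIMStack.
#' @export
setGeneric("phaseList", function(x) standardGeneric("phaseList"))

#' @rdname phaseList
#' @export
setMethod("phaseList", "RawSIMStack", function(x) x@phases)

#' Provenance metadata of a raw stack
#' @param x a RawSIMStack.
#' @export
setGeneric("stackMeta", function(x) standardGeneric("stackMeta"))

#' @rdname stackMeta
#' @export
setMethod("stackMeta", "RawSIMStack", function(x) x@meta)
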