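## File formats: multi-page 32-bit-float TIFF for image data (complex data
## as interleaved real/imaginary pages), JSON sidecars/manifests for
## calibration metadata, plain-text key/value configuration files.
##
## The TIFF writer stores each file affinely rescaled to [0, 1] (the float
## storage contract of the tiff package) and records `offset`/`scale` in the
## sidecar; values are recovered as offset + scale * stored. Every round
## trip is exact within float32 quantization (the scaling is recomputed per
## write, so repeated trips stay at single precision rather than bit-equal).

## ---- low-level float tiff helpers -----------------------------------------

writeScaledTiff <- function(pages, path) {
  lo <- min(vapply(pages, min, numeric(1)))
  hi <- max(vapply(pages, max, numeric(1)))
  scale <- hi - lo
  if (scale == 0) scale <- 1
  scaled <- lapply(pages, function(p) (p - lo) / scale)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  list(offset = lo, scale = scale)
}

readScaledTiff <- function(path, offset, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) offset + scale * p)
}

## complex 3D array <-> interleaved re/im pages along the 3rd axis
complexToPages <- function(arr) {
  nz <- dim(arr)[3]
  pages <- vector("list", 2L * nz)
  for (iz in seq_len(nz)) {
    pages[[2L * iz - 1L]] <- t(Re(arr[, , iz]))
    pages[[2L * iz]] <- t(Im(arr[, , iz]))
  }
  pages
}

pagesToComplex <- function(pages, dims) {
  arr <- array(0 + 0i, dim = dims)
  for (iz in seq_len(dims[3]))
    arr[, , iz] <- t(pages[[2L * iz - 1L]]) + 1i * t(pages[[2L * iz]])
  arr
}

#' Write / read a complex 3D array as an interleaved-plane float TIFF
#'
#' Pages alternate real and imaginary planes, kz (third axis) ascending; a
#' JSON sidecar (`<path>.json`) records dimensions and the affine storage
#' scaling.
#' @param arr complex 3D array.
#' @param path output TIFF path.
#' @return `writeComplexTiff`: the path, invisibly. `readComplexTiff`: the
#'   complex array.
#' @export
writeComplexTiff <- function(arr, path) {
  sc <- writeScaledTiff(complexToPages(arr), path)
  jsonlite::write_json(
    list(kind = "complex3d", dims = dim(arr), offset = sc$offset,
         scale = sc$scale, pageOrder = "re/im interleaved, plane ascending"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeComplexTiff
#' @export
readComplexTiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pagesToComplex(readScaledTiff(path, side$offset, side$scale),
                 as.integer(side$dims))
}

## ---- raw stacks -----------------------------------------------------------

#' Write a raw stack as a phase-fastest multi-page TIFF
#'
#' Page order matches the acquisition: for each z plane, the `nPhases`
#' phase-stepped copies in sequence (`(z0, phi0..phi4), (z1, phi0..phi4),
#' ...`). A JSON sidecar carries dimensions, voxel sizes, phases, the
#' storage scaling and the provenance metadata.
#'
#' @param stack a [RawSIMStack-class].
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @return the path, invisibly.
#' @export
writeRawStack <- function(stack, path) {
  d <- dim(stack@values)
  pages <- vector("list", d[3] * d[4])
  k <- 0L
  for (iz in seq_len(d[3])) for (j in seq_len(d[4])) {
    k <- k + 1L
    pages[[k]] <- t(stack@values[, , iz, j])
  }
  sc <- writeScaledTiff(pages, path)
  meta <- stack@meta
  meta$snr <- if (is.finite(meta$snr)) meta$snr else "none"
  jsonlite::write_json(
    list(kind = "rawSIMStack", dims = d, voxel = stack@voxel,
         phases = stack@phases, pageOrder = "pzyx",
         offset = sc$offset, scale = sc$scale, meta = meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raw stack written by [writeRawStack()]
#'
#' Without a sidecar the reader refuses unless `assumeOrder = "pzyx"` is
#' given explicitly, in which case defaults (five phases of `2 pi j / 5`,
#' 0.1 um voxels) are assumed with a warning.
#'
#' @param path TIFF path.
#' @param assumeOrder page-order override for sidecar-less files.
#' @return a [RawSIMStack-class].
#' @export
readRawStack <- function(path, assumeOrder = NULL) {
  sidePath <- paste0(path, ".json")
  if (file.exists(sidePath)) {
    side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
    pages <- readScaledTiff(path, side$offset, side$scale)
    dims <- as.integer(side$dims)
    phases <- side$phases
    voxel <- side$voxel
    meta <- as.list(side$meta)
    if (identical(meta$snr, "none")) meta$snr <- Inf
  } else {
    if (!identical(assumeOrder, "pzyx"))
      stop("missing calibration sidecar ", sidePath,
           " (expected fields: dims, voxel, phases, offset, scale, meta); ",
           "pass assumeOrder = \"pzyx\" to read with defaults")
    warning("no sidecar found; assuming phase-fastest order, 5 phases, ",
            "0.1 um voxels, unit scaling")
    pages <- tiff::readTIFF(path, all = TRUE)
    nPh <- 5L
    if (length(pages) %% nPh != 0L)
      stop("page count ", length(pages), " is not divisible by ", nPh,
           " phases")
    dims <- c(ncol(pages[[1]]), nrow(pages[[1]]),
              length(pages) %/% nPh, nPh)
    phases <- 2 * pi * (0:4) / 5
    voxel <- c(0.1, 0.1, 0.1)
    meta <- list()
  }
  if (length(pages) != dims[3] * dims[4])
    stop("page count ", length(pages), " does not match ", dims[3], " z x ",
         dims[4], " phases")
  vals <- array(0, dim = dims)
  k <- 0L
  for (iz in seq_len(dims[3])) for (j in seq_len(dims[4])) {
    k <- k + 1L
    vals[, , iz, j] <- t(pages[[k]])
  }
  new("RawSIMStack", values = vals, voxel = as.numeric(voxel),
      phases = as.numeric(phases), meta = meta)
}

## ---- transfer-function libraries ------------------------------------------

#' Write / read a transfer-function library directory
#'
#' One directory per library: a `manifest.json` listing the dz' grid, the
#' axial period, configuration key and per-entry files, plus one complex
#' TIFF per (entry, order).
#'
#' @param library a [TFLibrary-class].
#' @param dir target directory (created if needed).
#' @return `writeTfLibrary`: `dir`, invisibly; `readTfLibrary`: the
#'   [TFLibrary-class].
#' @export
writeTfLibrary <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(library@sets), function(i) {
    tf <- library@sets[[i]]
    files <- lapply(as.character(tf@mRange), function(mc) {
      fn <- sprintf("entry%03d_m%s.tif", i, sub("-", "neg", mc))
      writeComplexTiff(tf@otfs[[mc]], file.path(dir, fn))
      fn
    })
    names(files) <- as.character(tf@mRange)
    list(dz = tf@dzTag, mRange = tf@mRange, pActual = tf@pActual,
         voxel = tf@voxel, files = files)
  })
  jsonlite::write_json(
    list(kind = "tfLibrary", dzGrid = library@dzGrid, tz = library@tz,
         configKey = library@configKey, entries = entries),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeTfLibrary
#' @export
readTfLibrary <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  sets <- lapply(man$entries, function(e) {
    mRange <- as.integer(unlist(e$mRange))
    otfs <- lapply(as.character(mRange), function(mc)
      readComplexTiff(file.path(dir, e$files[[mc]])))
    names(otfs) <- as.character(mRange)
    new("TransferFunctionSet", otfs = otfs, dzTag = e$dz, mRange = mRange,
        pActual = e$pActual, tz = man$tz,
        voxel = as.numeric(unlist(e$voxel)), configKey = man$configKey)
  })
  new("TFLibrary", sets = sets, dzGrid = as.numeric(unlist(man$dzGrid)),
      tz = man$tz, configKey = man$configKey)
}

## ---- plain-text configuration ---------------------------------------------

#' Write / read an optical configuration as flat key = value text
#'
#' Keys mirror the [OpticalConfig-class] fields (`lambdaExc`, `lambdaDet`,
#' `nMedium`, `naDet`, `naAnnMax`, `naAnnMin`, `pattern`, `gridShape`
#' (comma separated), `voxelXY`, `voxelZ`, `upsample`). Unknown keys are an
#' error; missing keys fall back to the package defaults.
#'
#' @param cfg an [OpticalConfig-class].
#' @param path text file path.
#' @return `writeConfigFile`: the path, invisibly; `readConfigFile`: an
#'   [OpticalConfig-class].
#' @export
writeConfigFile <- function(cfg, path) {
  lines <- c(
    paste("lambdaExc =", cfg@lambdaExc), paste("lambdaDet =", cfg@lambdaDet),
    paste("nMedium =", cfg@nMedium), paste("naDet =", cfg@naDet),
    paste("naAnnMax =", cfg@naAnnMax), paste("naAnnMin =", cfg@naAnnMin),
    paste("pattern =", cfg@pattern),
    paste("gridShape =", paste(cfg@gridShape, collapse = ",")),
    paste("voxelXY =", cfg@voxelXY), paste("voxelZ =", cfg@voxelZ),
    paste("upsample =", cfg@upsample))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeConfigFile
#' @export
readConfigFile <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  known <- c("lambdaExc", "lambdaDet", "nMedium", "naDet", "naAnnMax",
             "naAnnMin", "pattern", "gridShape", "voxelXY", "voxelZ",
             "upsample")
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- switch(k,
      pattern = v,
      gridShape = as.integer(strsplit(v, ",")[[1]]),
      upsample = as.integer(v),
      as.numeric(v))
  }
  do.call(opticalConfig, args)
}

## ---- reports --------------------------------------------------------------

#' Write a JSON retrieval report
#'
#' Emits `dz_um`, `dz_pi`, `phi_rad`, `metric_min`, `secondary_min`,
#' `ambiguity_ratio` plus any extra fields supplied (library path, config
#' key, timings).
#'
#' @param estimate an [OffsetEstimate-class].
#' @param path output JSON path.
#' @param extra named list of additional fields.
#' @return the path, invisibly.
#' @export
writeOffsetReport <- function(estimate, path, extra = list()) {
  rep <- c(list(
    dz_um = estimate@dzHat, dz_pi = estimate@dzHatPi,
    phi_rad = estimate@phiHat, metric_min = estimate@metricAtMin,
    secondary_min = if (length(estimate@secondary)) estimate@secondary else NULL,
    ambiguity_ratio = estimate@ambiguityRatio,
    degenerate = estimate@degenerate), extra)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
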