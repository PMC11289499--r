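## Separating the phase-stepped stack into lateral-order components and
## moving bands in frequency space.
##
## Sign convention (package-wide): order m enters the mixing as
## exp(+i m phi_j); positive m corresponds to the +kx direction, i.e. the
## m-th band holds S~(k - m p e_x).

#' Separate a phase-stepped stack into lateral orders
#'
#' Fourier transforms each phase image and inverts the mixing matrix
#' `M[j, m] = exp(i m phi_j)` per frequency sample. For five equally spaced
#' phases M is a scaled DFT matrix (condition number 1) and the inversion is
#' exact; any set of distinct phases with `nPhases >=` the number of orders
#' is accepted and solved in the least-squares sense via the normal
#' equations of `solve()`.
#'
#' @param stack a [RawSIMStack-class].
#' @param phases phase steps (rad); defaults to the stack's own.
#' @param mRange lateral orders to extract.
#' @return a [SeparatedBands-class] holding complex spectra in native FFT
#'   order, still centered at kx = 0 as acquired.
#' @export
separateOrders <- function(stack, phases = phaseList(stack), mRange = -2:2) {
  nPh <- length(phases)
  if (nPh < length(mRange))
    stop("need at least ", length(mRange), " phases to separate ",
         length(mRange), " orders")
  M <- outer(phases, mRange, function(ph, m) exp(1i * m * ph))
  gram <- Conj(t(M)) %*% M
  Minv <- tryCatch(solve(gram, Conj(t(M))), error = function(e)
    stop("separation error: phase set is rank deficient ",
         "(duplicate phases modulo 2*pi?)", call. = FALSE))
  Fj <- lapply(seq_len(nPh), function(j) fftnd(stack@values[, , , j]))
  bands <- lapply(seq_along(mRange), function(i) {
    b <- Minv[i, 1] * Fj[[1]]
    for (j in seq_len(nPh)[-1]) b <- b + Minv[i, j] * Fj[[j]]
    b
  })
  names(bands) <- as.character(mRange)
  meta <- stack@meta
  new("SeparatedBands", bands = bands, mRange = as.integer(mRange),
      pUsed = meta$pActual, tz = meta$tz, voxel = stack@voxel,
      configKey = if (is.null(meta$configKey)) "" else meta$configKey)
}

#' Remix separated bands into phase-image spectra
#'
#' The forward mixing `F_j = sum_m exp(i m phi_j) B_m`; the inverse of
#' [separateOrders()]. Used to verify the round trip and energy
#' conservation of the separation.
#'
#' @param bands a [SeparatedBands-class].
#' @param phases phase steps (rad).
#' @return list of complex spectra, one per phase.
#' @export
remixOrders <- function(bands, phases) {
  lapply(phases, function(ph) {
    acc <- NULL
    for (m in bands@mRange) {
      term <- bands@bands[[as.character(m)]] * exp(1i * m * ph)
      acc <- if (is.null(acc)) term else acc + term
    }
    acc
  })
}

#' Translate a spectrum along kx
#'
#' Returns `B(k + shift e_x)`: the spectrum evaluated at a kx-shifted
#' argument, so that after shifting band m by `m * p` the sample information
#' `S~(k)` is aligned across orders. Integer multiples of the frequency
#' step are handled by exact circular shifting; other shifts by modulation
#' in real space (subsample accurate).
#'
#' @param band complex 3D array in native FFT order (kx first).
#' @param shift lateral frequency shift (cycles/um), `|shift|` below the
#'   grid Nyquist.
#' @param d lateral sample spacing (um) of the underlying image.
#' @return the shifted complex array.
#' @export
shiftBand <- function(band, shift, d) {
  if (shift == 0) return(band)
  nx <- dim(band)[1]
  kStep <- 1 / (nx * d)
  if (abs(shift) > 1 / (2 * d))
    stop("band shift beyond the grid Nyquist frequency")
  sSamp <- shift / kStep
  if (abs(sSamp - round(sSamp)) < 1e-9) {
    return(circShift(band, c(-round(sSamp), rep(0, length(dim(band)) - 1))))
  }
  xIdx <- (seq_len(nx) - 1) * d
  b <- ifftnd(band)
  fftnd(b * exp(-2i * pi * shift * xIdx))
}

#' Refine the pattern frequency by overlap cross-correlation
#'
#' Scans candidate lateral fundamentals around the geometric value and
#' returns the one maximizing the normalized magnitude cross-correlation
#' between the two overlap products of the order pair (data band m1 times
#' shifted transfer function m2, and vice versa). By default the simulator
#' and the retrieval share the configured p exactly, so this refinement is
#' only needed for data acquired with an imperfectly known pattern.
#'
#' @param bands a [SeparatedBands-class].
#' @param tfset a [TransferFunctionSet-class].
#' @param pair order pair to correlate (default `c(0, 1)`).
#' @param halfWidth half-width of the search interval as a fraction of p.
#' @param nCandidates number of candidates across the interval.
#' @param maskThreshold relative support threshold (see [overlapSupport()]).
#' @return list with `p` (the argmax), `pGrid`, `score`, and
#'   `lowConfidence` (TRUE when the correlation surface is too flat or
#'   empty to trust).
#' @export
estimatePatternFrequency <- function(bands, tfset, pair = c(0L, 1L),
                                     halfWidth = 0.02, nCandidates = 21L,
                                     maskThreshold = 1e-3) {
  p0 <- bands@pUsed
  d <- bands@voxel[1]
  pGrid <- p0 * seq(1 - halfWidth, 1 + halfWidth, length.out = nCandidates)
  B1 <- bands@bands[[as.character(pair[1])]]
  B2 <- bands@bands[[as.character(pair[2])]]
  T1 <- tfset@otfs[[as.character(pair[1])]]
  T2 <- tfset@otfs[[as.character(pair[2])]]
  score <- vapply(pGrid, function(p) {
    N <- shiftBand(B1, pair[1] * p, d) * shiftBand(T2, pair[2] * p, d)
    D <- shiftBand(B2, pair[2] * p, d) * shiftBand(T1, pair[1] * p, d)
    w <- Mod(N) * Mod(D)
    keep <- w > 0 & w >= maskThreshold * max(w)
    if (!any(keep)) return(0)
    Mod(sum(N[keep] * Conj(D[keep]))) /
      sqrt(sum(Mod(N[keep])^2) * sum(Mod(D[keep])^2))
  }, numeric(1))
  flat <- max(score) <= 0 ||
    (max(score) - min(score)) < 1e-3 * max(score)
  list(p = pGrid[which.max(score)], pGrid = pGrid, score = score,
       lowConfidence = flat)
}
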