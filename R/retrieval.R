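## Residual-phase offset retrieval: the overlap-region ratio between order
## pairs cancels the sample spectrum; its phase carries a kz-ramp
## proportional to (dz - dz') plus the constant (m1 - m2) * phi. Scanning a
## transfer-function library over dz' and a lateral phase grid and
## minimizing the weighted residual phase locates both offsets.

## weighted circular sums of the residual phase for one order pair:
## A = sum w cos(arg), B = sum w sin(arg), W = sum w, over the support mask.
overlapPhaseSums <- function(N, D, maskThreshold) {
  w <- Mod(N) * Mod(D)
  keep <- w > 0 & w >= maskThreshold * max(w)
  if (!any(keep))
    stop("retrieval error: empty overlap support")
  ND <- N[keep] * Conj(D[keep])
  ang <- Arg(ND)
  w <- w[keep]
  list(A = sum(w * cos(ang)), B = sum(w * sin(ang)), W = sum(w))
}

#' Support mask and weights of an overlap region
#'
#' The ratio between two shifted components is meaningful only where both
#' products have appreciable magnitude. The mask keeps samples where
#' `|tf1| * |tf2|` exceeds `relThreshold` times its maximum (and is
#' nonzero); the weights are `|tf1| * |tf2|` on the mask and 0 elsewhere.
#'
#' @param tf1,tf2 complex arrays, already shifted to their true positions.
#' @param relThreshold relative magnitude threshold in `[0, 1]`.
#' @return list with logical `mask` and numeric `weights`.
#' @export
overlapSupport <- function(tf1, tf2, relThreshold = 1e-3) {
  w <- Mod(tf1) * Mod(tf2)
  mask <- w > 0 & w >= relThreshold * max(w)
  if (!any(mask)) stop("retrieval error: empty overlap support")
  w[!mask] <- 0
  list(mask = mask, weights = w)
}

#' Overlap-region ratio field for one order pair
#'
#' Shifts data bands and transfer functions to their true positions and
#' forms, on the overlap support,
#' `R = [D~m1(k + m1 p) O~'m2(k + m2 p)] / [D~m2(k + m2 p) O~'m1(k + m1 p)]`.
#' The sample spectrum cancels by construction; what remains is the phase
#' mismatch between acquisition and calibration. The division is
#' regularized as `N conj(D) / (|D|^2 + eps max |D|^2)`; the residual phase
#' consumed by the metric is `Arg(N conj(D))`, which needs no
#' regularization.
#'
#' @param bands a [SeparatedBands-class].
#' @param tfset a [TransferFunctionSet-class] sharing the configuration.
#' @param pair integer pair `(m1, m2)`, `m1 != m2`; retrieval uses
#'   `(0, 1)` and `(1, 2)` (negative orders are conjugate-redundant).
#' @param p lateral fundamental (cycles/um); defaults to the bands' own.
#' @param maskThreshold relative support threshold.
#' @param eps regularization of the denominator magnitude.
#' @return an [OverlapRatioField-class].
#' @export
computeOverlapRatio <- function(bands, tfset, pair = c(0L, 1L), p = NULL,
                                maskThreshold = 1e-3, eps = 1e-6) {
  stopifnot(pair[1] != pair[2])
  if (nzchar(bands@configKey) && nzchar(tfset@configKey) &&
      bands@configKey != tfset@configKey)
    stop("configuration mismatch between bands and transfer functions")
  if (is.null(p)) p <- bands@pUsed
  d <- bands@voxel[1]
  B1 <- shiftBand(bands@bands[[as.character(pair[1])]], pair[1] * p, d)
  B2 <- shiftBand(bands@bands[[as.character(pair[2])]], pair[2] * p, d)
  T1 <- shiftBand(tfset@otfs[[as.character(pair[1])]], pair[1] * p, d)
  T2 <- shiftBand(tfset@otfs[[as.character(pair[2])]], pair[2] * p, d)
  N <- B1 * T2
  D <- B2 * T1
  sup <- overlapSupport(N, D, maskThreshold)
  ND <- N * Conj(D)
  ratio <- ND / (Mod(D)^2 + eps * max(Mod(D))^2)
  ratio[!sup$mask] <- 0
  ND[!sup$mask] <- 0
  new("OverlapRatioField", ratio = ratio, numerator = ND,
      mask = sup$mask, weights = sup$weights,
      pair = as.integer(pair))
}

#' Weighted residual-phase deviation for one lateral phase candidate
#'
#' `metric = sum w (1 - cos(arg R - (m1 - m2) phi)) / sum w`: a weighted
#' circular deviation of the residual phase from the constant the candidate
#' phase would explain. It is zero exactly when the residual phase is
#' uniform and equal to `(m1 - m2) phi` -- i.e. when the axial term
#' vanishes (dz = dz') and the lateral term is absorbed.
#'
#' @param R an [OverlapRatioField-class].
#' @param phiCandidate lateral phase candidate (rad).
#' @return nonnegative scalar.
#' @export
residualPhaseMetric <- function(R, phiCandidate) {
  dm <- R@pair[1] - R@pair[2]
  ang <- Arg(R@numerator[R@mask])
  w <- R@weights[R@mask]
  max(0, sum(w * (1 - cos(ang - dm * phiCandidate))) / sum(w))
}

#' Default lateral phase candidate grid
#' @param n number of samples over (-pi, pi].
#' @export
defaultPhiGrid <- function(n = 64L) -pi + 2 * pi * seq_len(n) / n

#' Build the 2D residual-phase map over (dz', phi)
#'
#' For every library entry and every lateral phase candidate, sums the
#' residual-phase metric over the order pairs (equal weighting). The map's
#' global minimum sits at the acquisition offsets; a second local minimum
#' appears half a lattice period away both axially and laterally.
#'
#' @param bands a [SeparatedBands-class] from the stack under analysis.
#' @param library a [TFLibrary-class] sharing the configuration.
#' @param phiGrid lateral phase candidates (rad) spanning (-pi, pi].
#' @param pairs list of order pairs; default `(0,1)` and `(1,2)`.
#' @param maskThreshold relative support threshold.
#' @return a [ResidualPhaseMap-class].
#' @export
buildResidualPhaseMap <- function(bands, library,
                                  phiGrid = defaultPhiGrid(),
                                  pairs = list(c(0L, 1L), c(1L, 2L)),
                                  maskThreshold = 1e-3) {
  if (nzchar(bands@configKey) && nzchar(library@configKey) &&
      bands@configKey != library@configKey)
    stop("configuration mismatch between bands and transfer-function library")
  d <- bands@voxel[1]
  p <- bands@pUsed
  orders <- sort(unique(unlist(pairs)))
  Bs <- lapply(orders, function(m)
    shiftBand(bands@bands[[as.character(m)]], m * p, d))
  names(Bs) <- as.character(orders)
  nDz <- length(library@sets)
  metric <- matrix(0, nDz, length(phiGrid))
  for (i in seq_len(nDz)) {
    tf <- library@sets[[i]]
    Ts <- lapply(orders, function(m)
      shiftBand(tf@otfs[[as.character(m)]], m * p, d))
    names(Ts) <- as.character(orders)
    rows <- lapply(pairs, function(pr) {
      s <- overlapPhaseSums(Bs[[as.character(pr[1])]] * Ts[[as.character(pr[2])]],
                            Bs[[as.character(pr[2])]] * Ts[[as.character(pr[1])]],
                            maskThreshold)
      dm <- pr[1] - pr[2]
      1 - (s$A * cos(dm * phiGrid) + s$B * sin(dm * phiGrid)) / s$W
    })
    metric[i, ] <- pmax(0, Reduce(`+`, rows) / length(pairs))
  }
  new("ResidualPhaseMap", metric = metric, dzGrid = library@dzGrid,
      dzGridPi = 2 * library@dzGrid / library@tz, phiGrid = phiGrid,
      pairs = pairs)
}

## strict/weak local minima of the map with circular phi wrapping
localMinima <- function(metric) {
  nD <- nrow(metric); nP <- ncol(metric)
  mins <- matrix(TRUE, nD, nP)
  for (di in -1:1) for (pj in -1:1) {
    if (di == 0 && pj == 0) next
    rows <- pmin(pmax(seq_len(nD) + di, 1), nD)
    cols <- ((seq_len(nP) - 1 + pj) %% nP) + 1
    mins <- mins & (metric <= metric[rows, cols, drop = FALSE])
  }
  which(mins, arr.ind = TRUE)
}

#' Locate the offset at the map minimum
#'
#' The primary estimate is the global grid minimum with the lateral phase
#' restricted to `lateralRange` (default `(-pi/2, pi/2]`), which resolves
#' the half-period ambiguity in favor of the central lattice lobe. The
#' unrestricted secondary local minimum (half a period away axially and
#' laterally) and the metric gap between the two, normalized by the map
#' range (`ambiguityRatio`), are reported regardless. Exact ties are broken
#' toward smaller `|dz|` with a warning.
#'
#' @param map a [ResidualPhaseMap-class].
#' @param lateralRange lateral phase search interval (rad), interpreted as
#'   the half-open interval `(lo, hi]`.
#' @param refineDz apply a 3-point parabolic sub-grid refinement along dz'
#'   (off by default; grid-node answers are reported otherwise).
#' @return an [OffsetEstimate-class].
#' @export
findMinimum <- function(map, lateralRange = c(-pi / 2, pi / 2),
                        refineDz = FALSE) {
  M <- map@metric
  stopifnot(all(is.finite(M)))
  phis <- map@phiGrid
  dzs <- map@dzGrid
  sel <- which(phis > lateralRange[1] & phis <= lateralRange[2])
  if (!length(sel)) stop("lateral search range contains no phi candidates")
  sub <- M[, sel, drop = FALSE]
  rng <- max(M) - min(M)
  degenerate <- rng <= max(M) * 1e-12 || rng == 0
  if (degenerate) {
    iD <- which.min(abs(dzs))
    iP <- sel[which.min(abs(phis[sel]))]
    warning("residual-phase map is flat; tie broken toward dz = 0")
  } else {
    hits <- which(sub == min(sub), arr.ind = TRUE)
    if (nrow(hits) > 1) {
      warning("tied minima in the residual-phase map; ",
              "tie broken toward smaller |dz|")
      hits <- hits[order(abs(dzs[hits[, 1]])), , drop = FALSE]
    }
    iD <- hits[1, 1]
    iP <- sel[hits[1, 2]]
  }
  dzHatV <- dzs[iD]
  if (refineDz && !degenerate && iD > 1 && iD < length(dzs)) {
    y <- M[(iD - 1):(iD + 1), iP]
    denom <- y[1] - 2 * y[2] + y[3]
    if (denom > 0) {
      delta <- 0.5 * (y[1] - y[3]) / denom
      dzHatV <- dzs[iD] + delta * (dzs[2] - dzs[1])
    }
  }
  ## unrestricted secondary minimum, half a period away laterally
  secondary <- list()
  ambiguity <- NA_real_
  if (!degenerate) {
    lm <- localMinima(M)
    phiDist <- abs(wrapPhase(phis[lm[, 2]] - phis[iP]))
    cand <- lm[phiDist > pi / 2, , drop = FALSE]
    if (nrow(cand)) {
      vals <- M[cand]
      k <- which.min(vals)
      secondary <- list(dz = dzs[cand[k, 1]],
                        dzPi = map@dzGridPi[cand[k, 1]],
                        phi = phis[cand[k, 2]],
                        metric = vals[k])
      ambiguity <- (vals[k] - M[iD, iP]) / rng
    }
  }
  piPerUm <- if (length(dzs) >= 2) {
    (map@dzGridPi[2] - map@dzGridPi[1]) / (dzs[2] - dzs[1])
  } else if (dzs[1] != 0) map@dzGridPi[1] / dzs[1] else 0
  new("OffsetEstimate", dzHat = dzHatV,
      dzHatPi = dzHatV * piPerUm,
      phiHat = phis[iP], metricAtMin = M[iD, iP],
      secondary = secondary, ambiguityRatio = ambiguity,
      searchRangeLateral = lateralRange, degenerate = degenerate)
}

#' End-to-end offset retrieval from a raw stack
#'
#' Convenience wrapper: separates the lateral orders, builds the residual
#' phase map against the library, and locates its minimum. Refuses to mix a
#' stack and a library generated under different optical configurations.
#'
#' @param stack a [RawSIMStack-class].
#' @param library a [TFLibrary-class].
#' @param lateralRange lateral search interval (rad).
#' @param phiGrid lateral phase candidates.
#' @param pairs order pairs for the metric.
#' @param maskThreshold relative support threshold.
#' @param returnMap also return the map for inspection.
#' @return an [OffsetEstimate-class], or (with `returnMap = TRUE`) a list
#'   with elements `estimate` and `map`.
#' @export
retrieveOffset <- function(stack, library,
                           lateralRange = c(-pi / 2, pi / 2),
                           phiGrid = defaultPhiGrid(),
                           pairs = list(c(0L, 1L), c(1L, 2L)),
                           maskThreshold = 1e-3, returnMap = FALSE) {
  key <- stack@meta$configKey
  if (!is.null(key) && nzchar(library@configKey) && key != library@configKey)
    stop("configuration mismatch: stack and library were generated under ",
         "different optical configurations")
  bands <- separateOrders(stack)
  map <- buildResidualPhaseMap(bands, library, phiGrid = phiGrid,
                               pairs = pairs, maskThreshold = maskThreshold)
  est <- findMinimum(map, lateralRange = lateralRange)
  if (returnMap) list(estimate = est, map = map) else est
}
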