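## Fourier bookkeeping shared across the package.
##
## Conventions (package-wide):
##  * frequencies are in cycles/um, never rad/um;
##  * arrays are stored in native FFT order (DC at index [1,1,...]); the
##    centered layout used for display is obtained with fftShift();
##  * real-space coordinate of index i on an axis of length n and step d is
##    (i - 1 - n/2) * d, i.e. the origin sits at index n/2 + 1;
##  * fftnd(x) is the unnormalized forward DFT, ifftnd(x) divides by length(x),
##    so ifftnd(fftnd(x)) == x and Parseval reads sum|x|^2 == sum|X|^2/N.

#' Sample frequencies of the DFT
#'
#' @param n number of samples (even).
#' @param d sample spacing (um).
#' @return numeric vector of length `n` with frequencies in cycles/um, in
#'   native FFT order (`0, 1/(n d), ..., -1/(n d)`).
#' @keywords internal
fftFreq <- function(n, d = 1) {
  c(seq.int(0L, n / 2 - 1L), seq.int(-n / 2, -1L)) / (n * d)
}

#' Centered real-space coordinates
#' @keywords internal
centeredCoords <- function(n, d = 1) {
  (seq_len(n) - 1 - n / 2) * d
}

#' @keywords internal
fftnd <- function(x) stats::fft(x)

#' @keywords internal
ifftnd <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Swap half-spaces so DC moves to the array center (or back)
#'
#' For even dimensions fftShift and ifftShift coincide; both are provided for
#' readability at call sites.
#' @keywords internal
fftShift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    h <- n %/% 2
    c(seq.int(h + 1L, n), seq_len(h))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @keywords internal
ifftShift <- fftShift

#' Circularly shift an array by whole samples along each axis
#' @keywords internal
circShift <- function(x, shift) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    s <- ((shift[1] %% n) + n) %% n
    if (s == 0) return(x)
    return(x[c(seq.int(n - s + 1L, n), seq_len(n - s))])
  }
  stopifnot(length(shift) == length(d))
  idx <- mapply(function(n, s) {
    s <- ((s %% n) + n) %% n
    if (s == 0) seq_len(n) else c(seq.int(n - s + 1L, n), seq_len(n - s))
  }, d, shift, SIMPLIFY = FALSE)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Block-mean downsampling (camera pixel integration)
#'
#' Averages non-overlapping `factor`-wide blocks along every axis, emulating
#' integration of the continuous (upsampled) image onto camera pixels.
#' @param x real or complex array whose dimensions are multiples of `factor`.
#' @param factor integer block size (the simulation upsampling factor).
#' @keywords internal
blockDownsample <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  d <- dim(x)
  stopifnot(all(d %% factor == 0L))
  for (ax in seq_along(d)) {
    dc <- dim(x)
    n <- dc[ax]
    ## reshape axis ax into (factor, n/factor) and average the first
    perm <- c(ax, seq_along(dc)[-ax])
    y <- aperm(x, perm)
    dim(y) <- c(factor, n %/% factor, dc[-ax])
    y <- colMeans(y)                       # drops the block axis
    dim(y) <- c(n %/% factor, dc[-ax])
    x <- aperm(y, order(perm))
  }
  x
}

#' Relative L2 difference between two arrays
#' @keywords internal
relDiff <- function(a, b) {
  den <- sqrt(sum(Mod(b)^2))
  if (den == 0) return(sqrt(sum(Mod(a)^2)))
  sqrt(sum(Mod(a - b)^2)) / den
}

#' Wrap phases to (-pi, pi]
#' @keywords internal
wrapPhase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}
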