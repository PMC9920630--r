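## Signal conditioning: GSR -> EDA conversion, 2 Hz downsampling, median
## filtering. These are the first three stages of the feature-extraction
## chain; they are kept separate so each is testable on its own.

#' Convert a raw resistance trace to an EDA conductance signal
#'
#' Skin resistance (ohm) and skin conductance (siemens) are reciprocal
#' descriptions of the same electrodermal state: conductance in
#' microsiemens is `10^6 / resistance`. Device timestamps are not exactly
#' uniform, so the converted samples are linearly interpolated onto a
#' uniform grid at the session's nominal acquisition rate.
#'
#' @param x a [RawSession-class] or [LabeledSegment-class].
#' @param rate target uniform rate, Hz; defaults to the session's nominal
#'   rate.
#' @return An [EDASignal-class] in microsiemens.
#' @examples
#' s <- RawSession(c(0, 500, 1000), c(1e6, 5e5, 2.5e5), nominalRate = 2)
#' signalValues(gsrToEda(s)) # 1, 2, 4 uS
#' @export
gsrToEda <- function(x, rate = NULL) {
  stopifnot(is(x, "RawSession"))
  if (any(x@resistance <= 0))
    stop("resistance must be strictly positive to convert to conductance")
  if (is.null(rate)) rate <- x@nominalRate
  ts <- x@timestamp / 1000
  eda <- 1e6 / x@resistance
  if (length(ts) == 1L) return(EDASignal(eda, rate, startTime = ts))
  grid <- seq(min(ts), max(ts), by = 1 / rate)
  vals <- stats::approx(ts, eda, xout = grid, ties = mean)$y
  EDASignal(vals, rate, startTime = grid[1])
}

#' Downsample an EDA signal by block averaging
#'
#' Reduces the sampling rate to `targetRate` (default two samples per
#' second). Each output sample is the mean of its block of source samples,
#' which preserves the slow conductance information while discarding only
#' within-block high-frequency content. If the source rate is not an
#' integer multiple of the target, the signal is first linearly resampled
#' to the nearest integer multiple.
#'
#' @param signal an [EDASignal-class].
#' @param targetRate output rate in Hz (default 2).
#' @return An [EDASignal-class] at `targetRate`.
#' @examples
#' s <- EDASignal(c(1, 3, 1, 3, 1, 3, 1, 3), rate = 4)
#' signalValues(downsampleSignal(s)) # 2 2 2 2
#' @export
downsampleSignal <- function(signal, targetRate = 2) {
  stopifnot(is(signal, "EDASignal"))
  if (targetRate > signal@rate)
    stop(
      "cannot downsample from ", signal@rate, " Hz to ", targetRate,
      " Hz (upsampling)"
    )
  if (signal@rate == targetRate) return(signal)
  block <- signal@rate / targetRate
  v <- signal@values
  if (abs(block - round(block)) > 1e-9) {
    ## resample to the nearest integer multiple of the target rate first
    block <- max(1, round(block))
    n <- length(v)
    dur <- (n - 1) / signal@rate
    grid <- seq(0, dur, by = 1 / (block * targetRate))
    v <- stats::approx(seq(0, dur, length.out = n), v, xout = grid)$y
  } else {
    block <- as.integer(round(block))
  }
  nOut <- length(v) %/% block
  if (nOut == 0L) stop("signal too short to downsample")
  v <- v[seq_len(nOut * block)]
  out <- colMeans(matrix(v, nrow = block))
  EDASignal(out, targetRate, startTime = signal@startTime)
}

## reflect-pad a vector by k samples on each side
reflectPad <- function(v, k) {
  n <- length(v)
  k <- min(k, n - 1L)
  if (k <= 0L) return(v)
  c(v[(k + 1):2], v, v[(n - 1):(n - k)])
}

#' Remove motion artifacts with a running median filter
#'
#' Replaces each sample by the median of a centred window, suppressing the
#' short spikes produced by electrode motion while leaving genuine (slower)
#' skin conductance responses intact. Edges are handled by reflect padding,
#' so length and rate are unchanged.
#'
#' @param signal an [EDASignal-class].
#' @param window odd window width in samples, at least 3 (default 5, i.e.
#'   2.5 s at 2 Hz).
#' @return The filtered [EDASignal-class].
#' @examples
#' s <- EDASignal(c(1, 1, 9, 1, 1), rate = 2)
#' signalValues(removeArtifacts(s)) # spike rejected
#' @export
removeArtifacts <- function(signal, window = 5) {
  stopifnot(is(signal, "EDASignal"))
  if (window < 3 || window %% 2 == 0)
    stop("median filter window must be an odd integer >= 3")
  v <- signal@values
  n <- length(v)
  if (n < 2L) return(signal)
  k <- (window - 1L) %/% 2L
  padded <- reflectPad(v, k)
  if (length(padded) < window) {
    out <- rep(stats::median(v), n)
  } else {
    out <- stats::runmed(padded, window, endrule = "keep")
    out <- out[(k + 1):(k + n)]
  }
  EDASignal(pmax(out, 0), signal@rate, startTime = signal@startTime)
}
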