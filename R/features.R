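## The fifteen per-segment descriptors: nine statistical features computed
## directly from the filtered conductance trace, six event-related features
## computed from the detected SCR peaks and offsets.

#' Canonical feature names
#'
#' The fifteen features, in canonical order: nine statistical (Mean,
#' Median, Std, Max, Min, Kurtosis, Skewness, AUC, PSD) and six
#' event-related (MeanPA, MaxPA, MeanOA, MaxOA, PPS, OPS).
#'
#' @return character(15).
#' @export
featureNames <- function() {
  c(
    "Mean", "Median", "Std", "Max", "Min", "Kurtosis", "Skewness",
    "AUC", "PSD",
    "MeanPA", "MaxPA", "MeanOA", "MaxOA", "PPS", "OPS"
  )
}

#' Feature-extraction configuration
#'
#' Bundles the tunable parameters of the per-segment processing chain.
#'
#' @param targetRate downsampling target, Hz (default 2).
#' @param medianWindow median-filter width in samples (default 5).
#' @param tonicWindow tonic moving-average window, seconds (default 10).
#' @param params SCR [detectionParams()].
#' @param amplitudeUnits `"uS"` or `"s"`, see [detectEvents()].
#' @param welchSegment Welch periodogram segment length, samples (default 64).
#' @return A named list.
#' @export
extractionConfig <- function(targetRate = 2, medianWindow = 5,
                             tonicWindow = 10, params = detectionParams(),
                             amplitudeUnits = "uS", welchSegment = 64) {
  list(
    targetRate = targetRate, medianWindow = medianWindow,
    tonicWindow = tonicWindow, params = params,
    amplitudeUnits = amplitudeUnits, welchSegment = welchSegment
  )
}

## Welch power-spectral-density estimate: Hann-windowed segments with 50%
## overlap, per-segment mean removal, one-sided density scaling.
welchPSD <- function(v, rate, segLength = 64) {
  n <- length(v)
  segLength <- min(segLength, n)
  step <- max(1L, segLength %/% 2L)
  starts <- seq(1L, n - segLength + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(segLength) - 1) / (segLength - 1))
  U <- sum(w^2)
  nf <- segLength %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- v[s:(s + segLength - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / (rate * U)
    half <- sp[seq_len(nf)]
    ## double the interior bins to fold the negative frequencies in
    if (nf > 2L) half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    if (segLength %% 2L == 1L && nf > 1L) half[nf] <- 2 * sp[nf]
    acc <- acc + half
  }
  acc / length(starts)
}

#' Statistical features of an EDA signal
#'
#' Computes the nine statistical descriptors over the (filtered) signal
#' values: mean, median, population standard deviation, maximum, minimum,
#' excess kurtosis, skewness (standardised third moment), AUC (trapezoidal
#' area under the conductance trace divided by its duration, i.e. mean µS
#' per second of signal) and PSD (the median of the Welch
#' power-spectral-density estimate). Skewness and kurtosis are 0 by
#' convention for zero-variance input.
#'
#' @param signal an [EDASignal-class] of length at least 2.
#' @param welchSegment Welch segment length in samples (default 64, 50%
#'   overlap, Hann window).
#' @return Named numeric(9).
#' @examples
#' statisticalFeatures(EDASignal(c(1, 2, 3, 4), rate = 2))
#' @export
statisticalFeatures <- function(signal, welchSegment = 64) {
  stopifnot(is(signal, "EDASignal"))
  v <- signal@values
  n <- length(v)
  if (n < 2L) stop("need at least 2 samples for statistical features")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  tt <- (seq_len(n) - 1) / signal@rate
  auc <- pracma::trapz(tt, v) / tt[n]
  psd <- stats::median(welchPSD(v, signal@rate, welchSegment))
  c(
    Mean = m, Median = stats::median(v), Std = sqrt(m2),
    Max = max(v), Min = min(v), Kurtosis = kurt, Skewness = skew,
    AUC = auc, PSD = psd
  )
}

#' Event-related features from detected SCRs
#'
#' Mean and maximum amplitude over the detected peaks (`MeanPA`, `MaxPA`)
#' and offsets (`MeanOA`, `MaxOA`), plus peak and offset counts divided by
#' the window duration in seconds (`PPS`, `OPS`). Empty event sets yield 0
#' for their features.
#'
#' @param events a data.frame from [detectEvents()].
#' @param windowDuration duration of the analysed window, seconds.
#' @return Named numeric(6).
#' @examples
#' ev <- data.frame(
#'   kind = c("PEAK", "PEAK"), start = c(1, 20), end = c(8, 27),
#'   duration = c(3.5, 3.5), amplitude = c(0.1, 0.3)
#' )
#' eventFeatures(ev, 60)
#' @export
eventFeatures <- function(events, windowDuration) {
  if (windowDuration <= 0) stop("windowDuration must be positive")
  pk <- events$amplitude[events$kind == "PEAK"]
  of <- events$amplitude[events$kind == "OFFSET"]
  m0 <- function(x) if (length(x) == 0L) 0 else mean(x)
  x0 <- function(x) if (length(x) == 0L) 0 else max(x)
  c(
    MeanPA = m0(pk), MaxPA = x0(pk), MeanOA = m0(of), MaxOA = x0(of),
    PPS = length(pk) / windowDuration, OPS = length(of) / windowDuration
  )
}

## Full conditioning chain for one raw trace: EDA conversion, 2 Hz
## downsampling, median filtering. Shared by feature extraction and the
## streaming recogniser.
conditionSignal <- function(x, config = extractionConfig()) {
  eda <- gsrToEda(x)
  eda <- downsampleSignal(eda, config$targetRate)
  removeArtifacts(eda, config$medianWindow)
}

#' Extract the 15-feature vector of one labelled segment
#'
#' Runs the full processing chain on the segment's raw samples — GSR to EDA
#' conversion, downsampling to the target rate, median filtering — then the
#' nine statistical features on the filtered signal and, after tonic/phasic
#' decomposition and SCR detection, the six event-related features.
#' Deterministic for a fixed configuration.
#'
#' @param segment a [LabeledSegment-class] (or any [RawSession-class]).
#' @param config an [extractionConfig()] list.
#' @return Named numeric(15) in [featureNames()] order.
#' @export
extractFeatures <- function(segment, config = extractionConfig()) {
  filt <- conditionSignal(segment, config)
  stat <- statisticalFeatures(filt, config$welchSegment)
  dec <- decomposeSignal(filt, config$tonicWindow)
  ev <- detectEvents(dec, config$params, config$amplitudeUnits)
  evf <- eventFeatures(ev, signalDuration(filt))
  c(stat, evf)[featureNames()]
}

#' Build a feature table from labelled segments
#'
#' @param segments list of [LabeledSegment-class].
#' @param config an [extractionConfig()] list.
#' @return An [EDAFeatureSet-class] with one column per segment (assay rows
#'   are the 15 features), labels in `colData`, not yet normalised.
#' @export
buildFeatureTable <- function(segments, config = extractionConfig()) {
  stopifnot(length(segments) > 0L)
  mat <- vapply(segments, extractFeatures, numeric(15), config = config)
  rownames(mat) <- featureNames()
  colnames(mat) <- vapply(segments, function(s) s@sessionId, "")
  cd <- DataFrame(
    label = vapply(segments, function(s) s@label, ""),
    sourceSession = vapply(segments, function(s) s@sourceSession, ""),
    songIndex = vapply(segments, function(s) s@songIndex, 1L)
  )
  se <- SummarizedExperiment(assays = list(features = mat), colData = cd)
  out <- new("EDAFeatureSet", se)
  metadata(out)$normalized <- FALSE
  out
}

#' Min-max normalise a feature table
#'
#' Rescales each feature so that its minimum maps to 0 and its maximum to
#' 1, using the minima and maxima of `fitRows` (default: all columns, i.e.
#' scaler fitted on the whole table). Fitting on training columns only and
#' transforming the rest avoids information leaking from evaluation data
#' into the scaler; fitting globally reproduces whole-dataset
#' normalisation. A constant feature maps to all zeros. The fitted scaler
#' is retained in the metadata so later segments or streaming windows can
#' be transformed consistently via [applyScaler()].
#'
#' @param fs an [EDAFeatureSet-class].
#' @param fitRows optional integer/logical index of the columns (segments)
#'   on which to fit the per-feature min/max.
#' @return The normalised [EDAFeatureSet-class].
#' @export
normalizeFeatures <- function(fs, fitRows = NULL) {
  stopifnot(is(fs, "EDAFeatureSet"), ncol(fs) > 0L)
  mat <- assay(fs)
  fit <- if (is.null(fitRows)) mat else mat[, fitRows, drop = FALSE]
  mins <- apply(fit, 1L, min)
  maxs <- apply(fit, 1L, max)
  scaler <- list(min = mins, max = maxs)
  assay(fs) <- applyScaler(mat, scaler)
  metadata(fs)$normalized <- TRUE
  metadata(fs)$scaler <- scaler
  fs
}

#' Apply a fitted min-max scaler
#'
#' @param x numeric matrix (features x segments) or named numeric vector.
#' @param scaler a list with per-feature `min` and `max` (from
#'   [normalizeFeatures()] / [featureScaler()]).
#' @return `x` rescaled; constant features (max == min) map to 0.
#' @export
applyScaler <- function(x, scaler) {
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1 # constant feature -> 0 after centring
  if (is.matrix(x)) {
    sweep(sweep(x, 1L, scaler$min), 1L, rng, "/")
  } else {
    (x - scaler$min[names(x)]) / rng[names(x)]
  }
}

#' Write / read a feature table as CSV
#'
#' The CSV uses one row per segment, the 15 feature columns named by
#' [featureNames()], plus `label`, `sourceSession` and `songIndex`.
#'
#' @param fs an [EDAFeatureSet-class].
#' @param path output CSV path.
#' @return `writeFeatureTable()`: `path` invisibly; `readFeatureTable()`:
#'   an [EDAFeatureSet-class].
#' @export
writeFeatureTable <- function(fs, path) {
  df <- as.data.frame(t(assay(fs)))
  df$label <- segmentLabels(fs)
  df$sourceSession <- colData(fs)$sourceSession
  df$songIndex <- colData(fs)$songIndex
  utils::write.csv(cbind(segment = colnames(fs), df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @param normalized logical flag recorded on the read table.
#' @export
readFeatureTable <- function(path, normalized = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mat <- t(as.matrix(df[, featureNames()]))
  colnames(mat) <- df$segment
  cd <- DataFrame(
    label = df$label,
    sourceSession = if ("sourceSession" %in% names(df)) df$sourceSession else NA,
    songIndex = if ("songIndex" %in% names(df)) df$songIndex else NA
  )
  se <- SummarizedExperiment(assays = list(features = mat), colData = cd)
  out <- new("EDAFeatureSet", se)
  metadata(out)$normalized <- normalized
  out
}
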