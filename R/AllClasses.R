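#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData colData<-
NULL

## Quadrant vocabulary -------------------------------------------------------

#' Russell circumplex quadrant labels
#'
#' The four quadrants of Russell's valence x arousal circumplex used as
#' emotion classes, in canonical order, plus the label used for the
#' relaxation song played at the start of a listening session.
#'
#' Quadrant semantics: Happy = (+valence, +arousal), Sad = (-, -),
#' Aggressive = (-, +), Relaxed = (+, -).
#'
#' @return `quadrantLabels()` returns `c("Happy", "Sad", "Aggressive",
#'   "Relaxed")`; `relaxLabel()` returns `"Relax"`.
#' @examples
#' quadrantLabels()
#' @export
quadrantLabels <- function() c("Happy", "Sad", "Aggressive", "Relaxed")

#' @rdname quadrantLabels
#' @export
relaxLabel <- function() "Relax"

## RawSession ----------------------------------------------------------------

#' Raw wearable session
#'
#' A timestamped skin-resistance trace as logged by the wearable's GSR
#' sensor. Timestamps are milliseconds since session start; resistances are
#' ohms. Validity deliberately does *not* require monotone timestamps or
#' in-range resistances: corrupted sessions must be representable so that
#' [validateSession()] can report on them.
#'
#' @slot timestamp numeric, milliseconds since session start.
#' @slot resistance numeric, ohms.
#' @slot sessionId character scalar identifier.
#' @slot nominalRate numeric, the device acquisition rate in Hz.
#' @export
setClass("RawSession",
  representation(
    timestamp = "numeric",
    resistance = "numeric",
    sessionId = "character",
    nominalRate = "numeric"
  )
)

setValidity("RawSession", function(object) {
  msg <- NULL
  if (length(object@timestamp) != length(object@resistance))
    msg <- c(msg, "timestamp and resistance must have equal length")
  if (length(object@timestamp) == 0L)
    msg <- c(msg, "session must contain at least one sample")
  if (anyNA(object@timestamp) || anyNA(object@resistance))
    msg <- c(msg, "samples must not contain NA")
  if (length(object@sessionId) != 1L)
    msg <- c(msg, "sessionId must be a single string")
  if (length(object@nominalRate) != 1L || object@nominalRate <= 0)
    msg <- c(msg, "nominalRate must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' Construct a RawSession
#'
#' @param timestamp numeric vector of timestamps (ms since session start).
#' @param resistance numeric vector of resistances (ohm), same length.
#' @param sessionId character identifier.
#' @param nominalRate device acquisition rate in Hz.
#' @return A [RawSession-class] object.
#' @examples
#' RawSession(c(0, 125, 250), c(1e6, 9.9e5, 9.8e5), "s1", 8)
#' @export
RawSession <- function(timestamp, resistance, sessionId = "session",
                       nominalRate = 8) {
  new("RawSession",
    timestamp = as.numeric(timestamp),
    resistance = as.numeric(resistance),
    sessionId = as.character(sessionId),
    nominalRate = as.numeric(nominalRate)
  )
}

#' @describeIn RawSession number of samples
#' @param x,object a `RawSession`
#' @export
setMethod("length", "RawSession", function(x) length(x@timestamp))

setMethod("show", "RawSession", function(object) {
  dur <- diff(range(object@timestamp)) / 1000
  cat("RawSession '", object@sessionId, "': ", length(object),
    " samples, ", sprintf("%.1f", dur), " s @ ", object@nominalRate,
    " Hz nominal\n",
    sep = ""
  )
})

#' Accessors for raw sessions
#'
#' @param x a [RawSession-class] (or [LabeledSegment-class]).
#' @return `sessionTimestamps()`: numeric ms; `sessionResistances()`:
#'   numeric ohm; `sessionId()`: character; `nominalRate()`: Hz.
#' @export
sessionTimestamps <- function(x) x@timestamp

#' @rdname sessionTimestamps
#' @export
sessionResistances <- function(x) x@resistance

#' @rdname sessionTimestamps
#' @export
sessionId <- function(x) x@sessionId

#' @rdname sessionTimestamps
#' @export
nominalRate <- function(x) x@nominalRate

## ProtocolSpec --------------------------------------------------------------

#' Listening-session protocol
#'
#' The song schedule of a listening session: an ordered set of songs, each
#' with an emotion label (a Russell quadrant or the relaxation label) and a
#' duration, separated by fixed silent pauses. The default protocol is nine
#' songs -- one relaxation song first, then two per quadrant -- of 260 s
#' each with 15 s pauses, for a 2460 s (41 min) playlist.
#'
#' @slot labels character, one label per song.
#' @slot durations numeric, song durations in seconds.
#' @slot pause numeric, inter-song pause in seconds.
#' @slot relaxFirst logical, whether the schedule opens with a relaxation
#'   song (exactly one `"Relax"` entry required when set).
#' @export
setClass("ProtocolSpec",
  representation(
    labels = "character",
    durations = "numeric",
    pause = "numeric",
    relaxFirst = "logical"
  )
)

setValidity("ProtocolSpec", function(object) {
  msg <- NULL
  if (length(object@labels) != length(object@durations))
    msg <- c(msg, "labels and durations must have equal length")
  ok <- c(quadrantLabels(), relaxLabel())
  if (!all(object@labels %in% ok))
    msg <- c(msg, paste("labels must be in", paste(ok, collapse = ", ")))
  if (any(object@durations <= 0))
    msg <- c(msg, "durations must be positive")
  if (length(object@pause) != 1L || object@pause < 0)
    msg <- c(msg, "pause must be a non-negative scalar")
  if (isTRUE(object@relaxFirst)) {
    if (sum(object@labels == relaxLabel()) != 1L ||
      object@labels[1] != relaxLabel())
      msg <- c(msg, "relaxFirst requires exactly one leading Relax entry")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a protocol
#'
#' @param labels character vector of song labels.
#' @param durations numeric vector of song durations (s).
#' @param pause inter-song pause (s), default 15.
#' @param relaxFirst logical; schedule opens with a relaxation song.
#' @return A [ProtocolSpec-class].
#' @export
ProtocolSpec <- function(labels, durations, pause = 15, relaxFirst = FALSE) {
  new("ProtocolSpec",
    labels = labels, durations = as.numeric(durations),
    pause = as.numeric(pause), relaxFirst = relaxFirst
  )
}

#' The nine-song listening protocol
#'
#' One relaxation song followed by two songs per quadrant, 260 s per song,
#' 15 s pauses: 9 x 260 + 8 x 15 = 2460 s, i.e. 41 minutes.
#'
#' @param songDuration duration of each song in seconds (default 260).
#' @param pause inter-song pause in seconds (default 15).
#' @return A [ProtocolSpec-class].
#' @examples
#' p <- defaultProtocol()
#' protocolDuration(p) / 60 # 41 minutes
#' @export
defaultProtocol <- function(songDuration = 260, pause = 15) {
  ProtocolSpec(
    labels = c(relaxLabel(), rep(quadrantLabels(), each = 2)),
    durations = rep(songDuration, 9),
    pause = pause,
    relaxFirst = TRUE
  )
}

#' Schedule arithmetic for a protocol
#'
#' `protocolSchedule()` returns the start/end offset (seconds on the
#' schedule clock) of every song; pauses separate consecutive songs and are
#' not part of any song. `protocolDuration()` is the total schedule length.
#'
#' @param protocol a [ProtocolSpec-class].
#' @return `protocolSchedule()`: a data.frame with columns `songIndex`,
#'   `label`, `start`, `end` (seconds); `protocolDuration()`: seconds.
#' @export
protocolSchedule <- function(protocol) {
  n <- length(protocol@labels)
  if (n == 0L) {
    return(data.frame(
      songIndex = integer(0), label = character(0),
      start = numeric(0), end = numeric(0)
    ))
  }
  starts <- cumsum(c(0, protocol@durations[-n] + protocol@pause))
  data.frame(
    songIndex = seq_len(n),
    label = protocol@labels,
    start = starts,
    end = starts + protocol@durations,
    stringsAsFactors = FALSE
  )
}

#' @rdname protocolSchedule
#' @export
protocolDuration <- function(protocol) {
  n <- length(protocol@labels)
  if (n == 0L) return(0)
  sum(protocol@durations) + protocol@pause * (n - 1L)
}

setMethod("show", "ProtocolSpec", function(object) {
  cat("ProtocolSpec: ", length(object@labels), " songs, pause ",
    object@pause, " s, total ", protocolDuration(object), " s\n",
    sep = ""
  )
})

## ValidationReport ----------------------------------------------------------

#' Session validation report
#'
#' Result of applying the session validation rules. `valid` is `TRUE` iff
#' `reasons` is empty. Reason codes: `TRUNCATED` (coverage below the
#' threshold fraction of the protocol duration), `NONMONOTONE_TIME`
#' (timestamps not strictly increasing), `OUT_OF_RANGE` (resistance outside
#' the plausible range), `GAP` (inter-sample gap above the limit).
#'
#' @slot valid logical scalar.
#' @slot reasons character vector of reason codes.
#' @export
setClass("ValidationReport",
  representation(valid = "logical", reasons = "character")
)

setValidity("ValidationReport", function(object) {
  if (object@valid != (length(object@reasons) == 0L))
    "valid must be TRUE exactly when reasons is empty"
  else TRUE
})

ValidationReport <- function(reasons = character(0)) {
  new("ValidationReport",
    valid = length(reasons) == 0L,
    reasons = unique(reasons)
  )
}

#' Query a validation report
#'
#' `isValid()` returns `TRUE` iff the session passed all checks;
#' `validationReasons()` returns the failure codes (empty when valid).
#'
#' @param x a [ValidationReport-class].
#' @return `isValid()`: logical scalar; `validationReasons()`: character.
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))

#' @rdname isValid
#' @export
setMethod("isValid", "ValidationReport", function(x) x@valid)

#' @rdname isValid
#' @export
validationReasons <- function(x) x@reasons

setMethod("show", "ValidationReport", function(object) {
  if (object@valid) {
    cat("ValidationReport: valid\n")
  } else {
    cat("ValidationReport: INVALID (", paste(object@reasons, collapse = ", "),
      ")\n",
      sep = ""
    )
  }
})

## LabeledSegment ------------------------------------------------------------

#' Labelled per-song segment
#'
#' The sub-trace of a raw session recorded while one (non-relaxation) song
#' was playing, carrying the quadrant label the song was chosen to induce.
#' Inherits the sample slots of [RawSession-class]; timestamps keep the
#' session clock.
#'
#' @slot label one of the four quadrant labels.
#' @slot sourceSession identifier of the originating session.
#' @slot songIndex position of the song in the protocol schedule.
#' @export
setClass("LabeledSegment",
  contains = "RawSession",
  representation(
    label = "character",
    sourceSession = "character",
    songIndex = "integer"
  )
)

setValidity("LabeledSegment", function(object) {
  msg <- NULL
  if (!object@label %in% quadrantLabels())
    msg <- c(msg, "label must be one of the four quadrant labels")
  if (length(object@songIndex) != 1L)
    msg <- c(msg, "songIndex must be a single integer")
  if (is.null(msg)) TRUE else msg
})

#' @rdname sessionTimestamps
#' @export
segmentLabel <- function(x) x@label

setMethod("show", "LabeledSegment", function(object) {
  dur <- diff(range(object@timestamp)) / 1000
  cat("LabeledSegment [", object@label, "] song ", object@songIndex,
    " of '", object@sourceSession, "': ", length(object), " samples, ",
    sprintf("%.1f", dur), " s\n",
    sep = ""
  )
})

## EDASignal -----------------------------------------------------------------

#' Uniformly sampled EDA signal
#'
#' Skin conductance in microsiemens on a uniform time grid.
#'
#' @slot values numeric conductances (µS), finite and non-negative.
#' @slot rate sampling rate in Hz.
#' @slot startTime time of the first sample in seconds.
#' @export
setClass("EDASignal",
  representation(values = "numeric", rate = "numeric", startTime = "numeric")
)

setValidity("EDASignal", function(object) {
  msg <- NULL
  if (length(object@values) < 1L)
    msg <- c(msg, "signal must contain at least one sample")
  if (!all(is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "values must be finite and non-negative")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' Construct an EDA signal
#'
#' @param values conductance values in microsiemens.
#' @param rate sampling rate, Hz.
#' @param startTime time of the first sample (s), default 0.
#' @return An [EDASignal-class].
#' @export
EDASignal <- function(values, rate, startTime = 0) {
  new("EDASignal",
    values = as.numeric(values), rate = as.numeric(rate),
    startTime = as.numeric(startTime)
  )
}

#' @describeIn EDASignal number of samples
#' @param x,object an `EDASignal`
#' @export
setMethod("length", "EDASignal", function(x) length(x@values))

#' Accessors for EDA signals
#' @param x an [EDASignal-class].
#' @return `signalValues()`: numeric µS; `signalRate()`: Hz;
#'   `signalDuration()`: seconds (n / rate).
#' @export
signalValues <- function(x) x@values

#' @rdname signalValues
#' @export
signalRate <- function(x) x@rate

#' @rdname signalValues
#' @export
signalDuration <- function(x) length(x@values) / x@rate

setMethod("show", "EDASignal", function(object) {
  cat("EDASignal: ", length(object), " samples @ ", object@rate, " Hz (",
    sprintf("%.1f", signalDuration(object)), " s), mean ",
    sprintf("%.3f", mean(object@values)), " uS\n",
    sep = ""
  )
})

## PhasicDecomposition -------------------------------------------------------

#' Tonic/phasic decomposition of an EDA signal
#'
#' The tonic component is the slow-varying conductance level (skin
#' conductance level); the phasic component carries the fast
#' stimulus-locked fluctuations. By construction tonic + phasic
#' reconstructs the input exactly.
#'
#' @slot tonic numeric µS series.
#' @slot phasic numeric µS series, same length.
#' @slot rate sampling rate in Hz.
#' @export
setClass("PhasicDecomposition",
  representation(tonic = "numeric", phasic = "numeric", rate = "numeric")
)

setValidity("PhasicDecomposition", function(object) {
  msg <- NULL
  if (length(object@tonic) != length(object@phasic))
    msg <- c(msg, "tonic and phasic must have equal length")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' Accessors for decompositions
#' @param x a [PhasicDecomposition-class].
#' @return numeric series (µS) or rate (Hz).
#' @export
tonicComponent <- function(x) x@tonic

#' @rdname tonicComponent
#' @export
phasicComponent <- function(x) x@phasic

setMethod("show", "PhasicDecomposition", function(object) {
  cat("PhasicDecomposition: ", length(object@tonic), " samples @ ",
    object@rate, " Hz; tonic mean ", sprintf("%.3f", mean(object@tonic)),
    " uS, phasic sd ", sprintf("%.4f", stats::sd(object@phasic)), " uS\n",
    sep = ""
  )
})

## DetectionParams -----------------------------------------------------------

#' SCR detection parameters
#'
#' A physiologically relevant change (skin conductance response peak, or the
#' mirrored offset) must sustain a slope of at least `slopeThreshold`
#' microsiemens per second, with constant sign, for at least `minDuration`
#' seconds.
#'
#' @param slopeThreshold minimum absolute slope, µS/s (default 0.01).
#' @param minDuration minimum run duration, s (default 3).
#' @return A named list with class `DetectionParams`.
#' @examples
#' detectionParams()
#' @export
detectionParams <- function(slopeThreshold = 0.01, minDuration = 3) {
  stopifnot(slopeThreshold > 0, minDuration > 0)
  structure(
    list(slopeThreshold = slopeThreshold, minDuration = minDuration),
    class = "DetectionParams"
  )
}

## FeatureRanking ------------------------------------------------------------

#' Feature relevance ranking
#'
#' An ordering of the fifteen features from most to least relevant,
#' produced by one statistical test (chi-square, ANOVA F, mutual
#' information) or by Borda voting over several tests.
#'
#' @slot features character, feature names in decreasing relevance order.
#' @slot scores numeric score per feature (test statistic, or rank sum for
#'   the voted ranking where *smaller* is better).
#' @slot source identifier of the producing test, or `"VOTE"`.
#' @export
setClass("FeatureRanking",
  representation(features = "character", scores = "numeric", source = "character")
)

setValidity("FeatureRanking", function(object) {
  msg <- NULL
  if (anyDuplicated(object@features))
    msg <- c(msg, "feature names must be unique")
  if (length(object@features) != length(object@scores))
    msg <- c(msg, "features and scores must have equal length")
  if (is.null(msg)) TRUE else msg
})

FeatureRanking <- function(features, scores, source) {
  new("FeatureRanking",
    features = features, scores = as.numeric(scores),
    source = source
  )
}

#' Accessors for rankings
#' @param x a [FeatureRanking-class].
#' @param n optional number of leading features to return.
#' @return `rankedFeatures()`: character vector (most relevant first);
#'   `rankingScores()`: named numeric scores.
#' @export
rankedFeatures <- function(x, n = NULL) {
  f <- x@features
  if (!is.null(n)) f <- f[seq_len(min(n, length(f)))]
  f
}

#' @rdname rankedFeatures
#' @export
rankingScores <- function(x) stats::setNames(x@scores, x@features)

setMethod("show", "FeatureRanking", function(object) {
  cat("FeatureRanking (", object@source, "): ",
    paste(utils::head(object@features, 5), collapse = " > "),
    if (length(object@features) > 5) " > ..." else "", "\n",
    sep = ""
  )
})

## EmotionPrediction ---------------------------------------------------------

#' Thresholded emotion prediction
#'
#' Four (flag, probability) pairs in Happy, Sad, Aggressive, Relaxed order:
#' a flag is raised exactly when its probability reaches the classification
#' threshold. For example ((TRUE, FALSE, FALSE, FALSE),
#' (0.84, 0.18, 0.12, 0.06)) at threshold 0.5 encodes a happy emotion with
#' probability 0.84.
#'
#' @slot flags logical length 4.
#' @slot probabilities numeric length 4, each in \[0, 1\].
#' @slot threshold numeric scalar.
#' @export
setClass("EmotionPrediction",
  representation(
    flags = "logical", probabilities = "numeric",
    threshold = "numeric"
  )
)

setValidity("EmotionPrediction", function(object) {
  msg <- NULL
  if (length(object@flags) != 4L || length(object@probabilities) != 4L)
    msg <- c(msg, "flags and probabilities must have length 4")
  if (any(object@probabilities < 0 | object@probabilities > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (!identical(
    unname(object@flags),
    unname(object@probabilities >= object@threshold)
  ))
    msg <- c(msg, "flags must equal probabilities >= threshold")
  if (is.null(msg)) TRUE else msg
})

#' Construct an emotion prediction from probabilities
#'
#' @param probabilities numeric length 4 (Happy, Sad, Aggressive, Relaxed).
#' @param threshold classification threshold, default 0.5.
#' @return An [EmotionPrediction-class]; flags are derived from the
#'   probabilities and threshold.
#' @examples
#' EmotionPrediction(c(0.84, 0.18, 0.12, 0.06))
#' @export
EmotionPrediction <- function(probabilities, threshold = 0.5) {
  probabilities <- stats::setNames(as.numeric(probabilities), quadrantLabels())
  new("EmotionPrediction",
    flags = probabilities >= threshold,
    probabilities = probabilities,
    threshold = threshold
  )
}

#' Accessors for predictions
#' @param x an [EmotionPrediction-class].
#' @return `predictionFlags()`: named logical(4); `predictionProbs()`:
#'   named numeric(4).
#' @export
predictionFlags <- function(x) x@flags

#' @rdname predictionFlags
#' @export
predictionProbs <- function(x) x@probabilities

setMethod("show", "EmotionPrediction", function(object) {
  cat("EmotionPrediction ((",
    paste(tolower(object@flags), collapse = ", "), "), (",
    paste(sprintf("%.2f", object@probabilities), collapse = ", "),
    ")) @ threshold ", object@threshold, "\n",
    sep = ""
  )
})

## EDAFeatureSet -------------------------------------------------------------

#' Feature table of labelled segments
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay holds
#' the 15 features (rows) for every labelled segment (columns). Column data
#' carry `label`, `sourceSession` and `songIndex`. Metadata slots:
#' `normalized` (logical) and, once normalised, `scaler` (per-feature min
#' and max fitted on the training rows, retained so future segments and
#' streaming windows can be transformed consistently).
#'
#' @export
setClass("EDAFeatureSet", contains = "SummarizedExperiment")

#' Construct a feature set from a feature matrix
#'
#' Mainly useful for programmatic construction (simulation studies,
#' tests); [buildFeatureTable()] is the usual entry point.
#'
#' @param features numeric matrix, features (rows, named) x segments
#'   (columns).
#' @param labels character vector of quadrant labels, one per column.
#' @param normalized whether the values are already min-max normalised.
#' @return An [EDAFeatureSet-class].
#' @export
EDAFeatureSet <- function(features, labels, normalized = FALSE) {
  stopifnot(is.matrix(features), ncol(features) == length(labels))
  se <- SummarizedExperiment(
    assays = list(features = features),
    colData = DataFrame(label = labels)
  )
  out <- new("EDAFeatureSet", se)
  metadata(out)$normalized <- normalized
  if (normalized) {
    metadata(out)$scaler <- list(
      min = stats::setNames(rep(0, nrow(features)), rownames(features)),
      max = stats::setNames(rep(1, nrow(features)), rownames(features))
    )
  }
  out
}

#' @describeIn EDAFeatureSet segment labels (one per column)
#' @param x an `EDAFeatureSet`
#' @export
segmentLabels <- function(x) as.character(colData(x)$label)

#' @describeIn EDAFeatureSet whether min-max normalisation has been applied
#' @export
isNormalized <- function(x) isTRUE(metadata(x)$normalized)

#' @describeIn EDAFeatureSet the fitted min-max scaler (list with `min`,
#'   `max` named by feature), or NULL
#' @export
featureScaler <- function(x) metadata(x)$scaler
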