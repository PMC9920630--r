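## Synthetic listening experiment: raw-format sessions with
## quadrant-conditioned EDA dynamics, plus controlled corruption so the
## validation stage has something to discard. Generation is a pure
## function of (spec, profiles, seed).

#' Quadrant-conditioned EDA generation profile
#'
#' Parameters of the simulated electrodermal response while a song of one
#' quadrant is playing: a tonic level with random-walk drift, skin
#' conductance responses (linear rise, exponential decay) arriving as a
#' Poisson process with log-normal amplitudes, and additive Gaussian
#' sensor noise.
#'
#' The rise geometry is constrained so that a median-amplitude SCR is
#' detectable under the default [detectionParams()]: rise time at least
#' the 3 s minimum duration and median rise slope at least 3x the
#' 0.01 µS/s threshold.
#'
#' @slot tonicBaseline tonic level, µS.
#' @slot tonicDriftSd random-walk scale, µS per sqrt(second).
#' @slot scrRate SCR arrival rate, events/min.
#' @slot scrAmpMedian median SCR amplitude, µS.
#' @slot scrAmpSigmaLog log-normal sigma of amplitudes.
#' @slot scrRise linear rise time, s.
#' @slot scrDecay exponential decay time constant, s.
#' @slot noiseSd sensor noise standard deviation, µS.
#' @export
setClass("QuadrantProfile",
  representation(
    tonicBaseline = "numeric", tonicDriftSd = "numeric",
    scrRate = "numeric", scrAmpMedian = "numeric",
    scrAmpSigmaLog = "numeric", scrRise = "numeric",
    scrDecay = "numeric", noiseSd = "numeric"
  )
)

setValidity("QuadrantProfile", function(object) {
  msg <- NULL
  vals <- c(
    object@tonicBaseline, object@scrAmpMedian, object@scrAmpSigmaLog,
    object@scrRise, object@scrDecay
  )
  if (any(vals <= 0)) msg <- c(msg, "profile parameters must be positive")
  if (object@tonicDriftSd < 0 || object@noiseSd < 0 || object@scrRate < 0)
    msg <- c(msg, "drift, noise and rate must be non-negative")
  dp <- detectionParams()
  if (object@scrRise < dp$minDuration)
    msg <- c(msg, "scrRise must be at least the detector's minimum duration")
  if (object@scrAmpMedian / object@scrRise < 3 * dp$slopeThreshold)
    msg <- c(msg, "median rise slope must be at least 3x the slope threshold")
  if (is.null(msg)) TRUE else msg
})

#' Construct a quadrant profile
#'
#' @param tonicBaseline tonic level (µS).
#' @param tonicDriftSd random-walk scale (µS/sqrt(s)), default 0.02.
#' @param scrRate SCR rate (events/min).
#' @param scrAmpMedian median SCR amplitude (µS).
#' @param scrAmpSigmaLog log-normal sigma (default 0.4).
#' @param scrRise rise time (s).
#' @param scrDecay decay constant (s), default 8.
#' @param noiseSd sensor noise sd (µS), default 0.01.
#' @return A [QuadrantProfile-class].
#' @export
QuadrantProfile <- function(tonicBaseline, scrRate, scrAmpMedian,
                            tonicDriftSd = 0.02, scrAmpSigmaLog = 0.4,
                            scrRise = 3.5, scrDecay = 8, noiseSd = 0.01) {
  new("QuadrantProfile",
    tonicBaseline = tonicBaseline, tonicDriftSd = tonicDriftSd,
    scrRate = scrRate, scrAmpMedian = scrAmpMedian,
    scrAmpSigmaLog = scrAmpSigmaLog, scrRise = scrRise,
    scrDecay = scrDecay, noiseSd = noiseSd
  )
}

#' Default per-quadrant generation profiles
#'
#' Electrodermal activity predominantly tracks arousal, so the
#' high-arousal quadrants (Happy, Aggressive) get frequent, large SCRs
#' (6/min, median 0.3 µS) and the low-arousal quadrants (Sad, Relaxed)
#' sparse small ones (1.5/min, median 0.1 µS). Valence is expressed as a
#' mild tonic-baseline shift (Happy 6, Aggressive 4, Relaxed 3, Sad 2 µS)
#' — a modelling convenience that makes all four quadrants separable, not
#' a physiological claim. A `Relax` profile covers the opening relaxation
#' song and the inter-song pauses.
#'
#' @return Named list of [QuadrantProfile-class] for `Happy`, `Sad`,
#'   `Aggressive`, `Relaxed` and `Relax`.
#' @export
defaultProfiles <- function() {
  list(
    Happy = QuadrantProfile(6, scrRate = 6, scrAmpMedian = 0.3, scrRise = 3.5),
    Sad = QuadrantProfile(2, scrRate = 1.5, scrAmpMedian = 0.1, scrRise = 3.2),
    Aggressive = QuadrantProfile(4, scrRate = 6, scrAmpMedian = 0.3, scrRise = 3.5),
    Relaxed = QuadrantProfile(3, scrRate = 1.5, scrAmpMedian = 0.1, scrRise = 3.2),
    Relax = QuadrantProfile(2.5, scrRate = 1, scrAmpMedian = 0.1, scrRise = 3.2)
  )
}

## One generated interval at the native rate: returns the EDA values on
## the uniform grid plus the ground-truth SCR onset times (s, local clock).
simulateEDA <- function(profile, duration, rate, seed, baselineShift = 0) {
  stopifnot(duration > 0, rate > 0)
  withr::with_seed(seed, {
    n <- as.integer(floor(duration * rate)) + 1L
    tt <- (seq_len(n) - 1) / rate
    tonic <- profile@tonicBaseline + baselineShift +
      cumsum(stats::rnorm(n, 0, profile@tonicDriftSd / sqrt(rate)))
    nEvents <- stats::rpois(1L, profile@scrRate * duration / 60)
    onsets <- amps <- numeric(0)
    phasic <- numeric(n)
    if (nEvents > 0L) {
      onsets <- sort(stats::runif(
        nEvents, 0,
        max(duration - profile@scrRise, 1e-3)
      ))
      amps <- stats::rlnorm(
        nEvents, log(profile@scrAmpMedian),
        profile@scrAmpSigmaLog
      )
      for (i in seq_len(nEvents)) {
        rel <- tt - onsets[i]
        kernel <- ifelse(
          rel < 0, 0,
          ifelse(
            rel < profile@scrRise,
            amps[i] * rel / profile@scrRise,
            amps[i] * exp(-(rel - profile@scrRise) / profile@scrDecay)
          )
        )
        phasic <- phasic + kernel
      }
    }
    eda <- tonic + phasic + stats::rnorm(n, 0, profile@noiseSd)
    list(
      eda = pmax(eda, 0.12), t = tt,
      events = data.frame(onset = onsets, amplitude = amps)
    )
  })
}

#' Generate one raw-format segment
#'
#' Simulates the EDA of a single interval under a profile and emits it as
#' a raw resistance trace (`R = 10^6 / EDA`) with millisecond timestamps,
#' alongside the ground-truth injected SCR onsets.
#'
#' @param profile a [QuadrantProfile-class].
#' @param duration interval length, seconds.
#' @param rate native acquisition rate, Hz (default 8).
#' @param seed integer seed; the trace is a pure function of the inputs.
#' @param sessionId identifier for the emitted fragment.
#' @return A list: `session` (a [RawSession-class]) and `events`
#'   (data.frame of ground-truth `onset` seconds and `amplitude` µS).
#' @examples
#' g <- generateSegment(defaultProfiles()$Happy, duration = 60, seed = 7)
#' g$session
#' @export
generateSegment <- function(profile, duration, rate = 8, seed = 1L,
                            sessionId = "segment") {
  sim <- simulateEDA(profile, duration, rate, seed)
  RawSession(
    timestamp = sim$t * 1000,
    resistance = 1e6 / sim$eda,
    sessionId = sessionId, nominalRate = rate
  ) -> s
  list(session = s, events = sim$events)
}

#' Experiment specification
#'
#' The study design to simulate: number of participants, number of
#' sessions to corrupt so they fail validation, the song protocol, the
#' device rate and the master seed.
#'
#' @param nParticipants sessions to generate (default 32).
#' @param nInvalid sessions corrupted (default 7).
#' @param protocol a [ProtocolSpec-class] (default [defaultProtocol()]).
#' @param nativeRate device rate, Hz (default 8).
#' @param seed master seed.
#' @return A named list with class `ExperimentSpec`.
#' @export
experimentSpec <- function(nParticipants = 32L, nInvalid = 7L,
                           protocol = defaultProtocol(), nativeRate = 8,
                           seed = 1L) {
  stopifnot(nInvalid <= nParticipants, nParticipants >= 1L)
  structure(
    list(
      nParticipants = as.integer(nParticipants),
      nInvalid = as.integer(nInvalid),
      protocol = protocol, nativeRate = nativeRate,
      seed = as.integer(seed) %% 536870912L
    ),
    class = "ExperimentSpec"
  )
}

## Corruption modes cycle so each validation reason code occurs at least
## once in the default corpus (7 invalid sessions, 4 modes).
corruptSession <- function(session, mode, protocol, seed) {
  ts <- session@timestamp
  rs <- session@resistance
  n <- length(ts)
  withr::with_seed(seed, switch(mode,
    TRUNCATED = {
      keep <- seq_len(floor(n * 0.5))
      RawSession(ts[keep], rs[keep], session@sessionId, session@nominalRate)
    },
    NONMONOTONE_TIME = {
      i <- sample(seq(2L, n - 1L), 1L)
      ts[c(i, i + 1L)] <- ts[c(i + 1L, i)]
      RawSession(ts, rs, session@sessionId, session@nominalRate)
    },
    OUT_OF_RANGE = {
      i <- sample(seq_len(n - 20L), 1L)
      rs[i:(i + 19L)] <- 5e7 # electrode detachment burst
      RawSession(ts, rs, session@sessionId, session@nominalRate)
    },
    GAP = {
      t0 <- stats::runif(1, 0.2, 0.7) * max(ts)
      keep <- ts < t0 | ts > t0 + 8000 # 8 s dropout
      RawSession(ts[keep], rs[keep], session@sessionId, session@nominalRate)
    }
  ))
}

#' Simulate the full listening experiment
#'
#' Generates one session per participant following the protocol schedule
#' (each song and pause simulated under its label's profile, with a small
#' per-participant baseline offset), then corrupts `nInvalid` sessions —
#' cycling through truncation, timestamp scrambling, out-of-range bursts
#' and sample-dropout gaps so every validation reason code is exercised.
#'
#' @param spec an [experimentSpec()].
#' @param profiles named profile list as from [defaultProfiles()].
#' @return A list: `sessions` (list of [RawSession-class]), `manifest`
#'   (data.frame: `session`, `corrupted`, `mode`), `events` (data.frame of
#'   ground-truth SCR onsets: `session`, `songIndex`, `label`, `onset`
#'   seconds on the session clock, `amplitude`).
#' @export
generateExperiment <- function(spec = experimentSpec(),
                               profiles = defaultProfiles()) {
  need <- c(quadrantLabels(), relaxLabel())
  stopifnot(all(need %in% names(profiles)))
  sched <- protocolSchedule(spec$protocol)
  pause <- spec$protocol@pause
  rate <- spec$nativeRate
  modes <- c("TRUNCATED", "NONMONOTONE_TIME", "OUT_OF_RANGE", "GAP")
  corrupt <- withr::with_seed(
    spec$seed,
    sample(spec$nParticipants)[seq_len(spec$nInvalid)]
  )
  sessions <- vector("list", spec$nParticipants)
  manifest <- data.frame(
    session = character(spec$nParticipants),
    corrupted = logical(spec$nParticipants),
    mode = NA_character_, stringsAsFactors = FALSE
  )
  events <- list()
  for (p in seq_len(spec$nParticipants)) {
    sid <- sprintf("P%02d", p)
    pSeed <- spec$seed + 977L * p
    shift <- withr::with_seed(pSeed, stats::rnorm(1, 0, 0.3))
    tsAll <- numeric(0)
    rsAll <- numeric(0)
    for (i in seq_len(nrow(sched))) {
      prof <- profiles[[sched$label[i]]]
      sim <- simulateEDA(prof, sched$end[i] - sched$start[i], rate,
        seed = pSeed + 13L * i, baselineShift = shift
      )
      tsAll <- c(tsAll, (sched$start[i] + sim$t) * 1000)
      rsAll <- c(rsAll, 1e6 / sim$eda)
      if (nrow(sim$events) > 0L) {
        events[[length(events) + 1L]] <- data.frame(
          session = sid, songIndex = sched$songIndex[i],
          label = sched$label[i],
          onset = sched$start[i] + sim$events$onset,
          amplitude = sim$events$amplitude, stringsAsFactors = FALSE
        )
      }
      ## pause after every song but the last, under the relaxation profile
      if (i < nrow(sched) && pause > 0) {
        ps <- simulateEDA(profiles[[relaxLabel()]], pause, rate,
          seed = pSeed + 13L * i + 7L, baselineShift = shift
        )
        keep <- ps$t > 0 & ps$t < pause # avoid duplicate boundary stamps
        tsAll <- c(tsAll, (sched$end[i] + ps$t[keep]) * 1000)
        rsAll <- c(rsAll, 1e6 / ps$eda[keep])
      }
    }
    o <- order(tsAll)
    tsAll <- tsAll[o]
    rsAll <- rsAll[o]
    dup <- c(FALSE, diff(tsAll) <= 0)
    s <- RawSession(tsAll[!dup], rsAll[!dup], sid, rate)
    if (p %in% corrupt) {
      mode <- modes[(match(p, corrupt) - 1L) %% length(modes) + 1L]
      s <- corruptSession(s, mode, spec$protocol, pSeed + 499L)
      manifest$corrupted[p] <- TRUE
      manifest$mode[p] <- mode
    }
    manifest$session[p] <- sid
    sessions[[p]] <- s
  }
  list(
    sessions = sessions, manifest = manifest,
    events = if (length(events)) do.call(rbind, events) else
      data.frame(
        session = character(0), songIndex = integer(0),
        label = character(0), onset = numeric(0), amplitude = numeric(0)
      )
  )
}
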