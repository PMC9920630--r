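## End-to-end orchestration and the streaming recognition loop: every
## complete 30 s window of the incoming raw trace runs through the full
## conditioning + feature chain, the training-time scaler and the four
## binary models, producing one thresholded prediction per window.

#' Windowing configuration
#'
#' Tumbling (non-overlapping) windows by default: `step = windowLength`.
#'
#' @param windowLength window length in seconds (default 30).
#' @param step hop between window starts in seconds (default =
#'   `windowLength`).
#' @return A named list.
#' @export
windowConfig <- function(windowLength = 30, step = windowLength) {
  stopifnot(windowLength > 0, step > 0)
  list(windowLength = windowLength, step = step)
}

## One window's features -> normalised vector -> prediction.
predictWindow <- function(ts, rs, bundle) {
  frag <- RawSession(ts, rs,
    sessionId = "window",
    nominalRate = bundle$nativeRate
  )
  feats <- extractFeatures(frag, bundle$config)
  xn <- applyScaler(feats, bundle$scaler)
  xn <- pmin(pmax(xn, 0), 1) # clip out-of-training-range values
  predictEmotion(bundle$models, xn, threshold = bundle$threshold)
}

#' Windowed emotion recognition over a raw stream
#'
#' Splits the trace into complete windows (trailing partial window
#' dropped), runs each window through the full processing chain with the
#' bundle's training-time scaler and models, and returns one prediction
#' per window.
#'
#' @param stream a [RawSession-class] (or [LabeledSegment-class]).
#' @param bundle a recognition bundle from [runTrainingPipeline()] (fields
#'   `models`, `scaler`, `config`, `nativeRate`, `threshold`).
#' @param config a [windowConfig()].
#' @return A data.frame with one row per window: `t` (window start, s),
#'   `prob_<quadrant>` and `flag_<quadrant>` columns in Happy, Sad,
#'   Aggressive, Relaxed order. Empty (with a warning) when the stream
#'   holds no complete window.
#' @export
runWindowedRecognition <- function(stream, bundle, config = windowConfig()) {
  ts <- stream@timestamp / 1000
  t0 <- min(ts)
  dur <- max(ts) - t0
  starts <- seq(0, by = config$step, length.out = max(
    0L, floor((dur - config$windowLength) / config$step) + 1L
  ))
  qs <- quadrantLabels()
  empty <- stats::setNames(
    data.frame(matrix(numeric(0), ncol = 9)),
    c("t", paste0("prob_", qs), paste0("flag_", qs))
  )
  if (length(starts) == 0L) {
    warning("stream shorter than one window (", config$windowLength,
      " s); no predictions", call. = FALSE)
    return(empty)
  }
  rows <- lapply(starts, function(s) {
    keep <- ts >= t0 + s & ts < t0 + s + config$windowLength
    pr <- predictWindow(
      stream@timestamp[keep], stream@resistance[keep],
      bundle
    )
    data.frame(
      t = s,
      as.list(stats::setNames(predictionProbs(pr), paste0("prob_", qs))),
      as.list(stats::setNames(predictionFlags(pr), paste0("flag_", qs)))
    )
  })
  do.call(rbind, rows)
}

#' Incremental stream processor
#'
#' A stateful processor for live sources: feed raw samples in arbitrary
#' chunk sizes; every window completed by the data received so far is
#' classified immediately. Feeding samples one at a time or in bulk
#' yields identical results.
#'
#' @param bundle a recognition bundle (see [runWindowedRecognition()]).
#' @param config a [windowConfig()].
#' @return A list of functions: `feed(timestamp, resistance)` appends
#'   samples (ms, ohm) and processes completed windows; `results()`
#'   returns the prediction data.frame accumulated so far.
#' @export
newStreamProcessor <- function(bundle, config = windowConfig()) {
  ts <- numeric(0)
  rs <- numeric(0)
  nextStart <- NA_real_
  out <- list()
  feed <- function(timestamp, resistance) {
    ts <<- c(ts, timestamp)
    rs <<- c(rs, resistance)
    if (is.na(nextStart)) nextStart <<- min(ts) / 1000
    ## a window [s, s+L) is complete once a sample at/after its end arrived
    while (max(ts) / 1000 >= nextStart + config$windowLength) {
      keep <- ts / 1000 >= nextStart & ts / 1000 < nextStart + config$windowLength
      pr <- predictWindow(ts[keep], rs[keep], bundle)
      qs <- quadrantLabels()
      out[[length(out) + 1L]] <<- data.frame(
        t = nextStart - min(ts) / 1000,
        as.list(stats::setNames(predictionProbs(pr), paste0("prob_", qs))),
        as.list(stats::setNames(predictionFlags(pr), paste0("flag_", qs)))
      )
      nextStart <<- nextStart + config$step
    }
    invisible(length(out))
  }
  results <- function() {
    if (length(out) == 0L) {
      data.frame()
    } else {
      do.call(rbind, out)
    }
  }
  list(feed = feed, results = results)
}

#' Run the full training pipeline
#'
#' Orchestrates the whole chain on a synthetic corpus (or raw logs read
#' from a directory): session validation, per-song segmentation, feature
#' extraction, min-max normalisation, per-target feature ranking with
#' voting, and model tuning — four one-vs-rest binary models and
#' optionally the four-class model. A manifest records seeds and counts
#' at every stage.
#'
#' @param spec an [experimentSpec()] describing the corpus to generate,
#'   or `NULL` when `rawDir` is given.
#' @param profiles generation profiles (default [defaultProfiles()]).
#' @param rawDir optional directory of raw logs to use instead of the
#'   generator.
#' @param config an [extractionConfig()].
#' @param rules [validationRules()] applied before segmentation.
#' @param algorithms algorithm subset to search (default all five).
#' @param nFeaturesGrid,nConfigs,folds,repeats tuning parameters, see
#'   [trainAndTune()].
#' @param trainFourClass also tune the four-class model (default TRUE).
#' @param threshold classification threshold stored in the bundle.
#' @param outDir optional directory for artifacts (segments + manifest,
#'   feature CSV, ranking CSVs, report CSV, run manifest JSON).
#' @param seed master seed; defaults to the seed of the experiment
#'   specification.
#' @return A bundle list: `models` (4 binary `edaModel`s), `fourClass`
#'   (model or NULL), `scaler`, `config`, `nativeRate`, `threshold`,
#'   `rankings`, `reports` (data.frame, one row per tuned model),
#'   `manifest` (stage counts and seeds), `features` (the normalised
#'   [EDAFeatureSet-class]).
#' @export
runTrainingPipeline <- function(spec = experimentSpec(),
                                profiles = defaultProfiles(),
                                rawDir = NULL,
                                config = extractionConfig(),
                                rules = validationRules(),
                                algorithms = algorithmNames(),
                                nFeaturesGrid = c(5, 8, 10, 12, 15),
                                nConfigs = 50L, folds = 5L, repeats = 10L,
                                trainFourClass = TRUE, threshold = 0.5,
                                outDir = NULL, seed = NULL) {
  ## stage 1: corpus
  if (is.null(rawDir)) {
    if (is.null(seed)) seed <- spec$seed
    corpus <- generateExperiment(spec, profiles)
    sessions <- corpus$sessions
    protocol <- spec$protocol
    nativeRate <- spec$nativeRate
  } else {
    if (is.null(seed)) seed <- 1L
    files <- list.files(rawDir, pattern = "\\.csv$", full.names = TRUE)
    files <- files[!grepl("manifest", files)]
    if (length(files) == 0L) stop("pipeline stage 'corpus': no raw logs in ", rawDir)
    sessions <- lapply(files, readRawLog)
    protocol <- spec$protocol
    nativeRate <- sessions[[1]]@nominalRate
  }
  nSessions <- length(sessions)
  ## stage 2: validation
  reports <- lapply(sessions, validateSession, protocol = protocol, rules = rules)
  valid <- vapply(reports, isValid, TRUE)
  if (!any(valid))
    stop("pipeline stage 'training': no session passed validation")
  ## stage 3: segmentation
  segments <- unlist(
    lapply(sessions[valid], segmentSession, protocol = protocol),
    recursive = FALSE
  )
  labels <- vapply(segments, segmentLabel, "")
  ## stage 4: features + normalisation
  fs <- buildFeatureTable(segments, config)
  fs <- normalizeFeatures(fs)
  ## stage 5: rankings (one-vs-rest per quadrant, plus four-class)
  rankings <- lapply(stats::setNames(nm = quadrantLabels()), function(q) {
    rankFeatures(fs, oneVsRestLabels(segmentLabels(fs), q), seed = seed)
  })
  rankings$fourClass <- rankFeatures(fs, segmentLabels(fs), seed = seed)
  ## stage 6: model tuning
  models <- list()
  reportRows <- list()
  for (q in quadrantLabels()) {
    fit <- trainAndTune(fs, rankings[[q]]$vote,
      architecture = "BINARY",
      positive = q, algorithms = algorithms,
      nFeaturesGrid = nFeaturesGrid, nConfigs = nConfigs,
      folds = folds, repeats = repeats, seed = seed
    )
    models[[q]] <- fit$model
    r <- fit$report
    r$target <- q
    r$nSegments <- ncol(fs)
    reportRows[[q]] <- r
  }
  fourClass <- NULL
  fourClassPerClassF1 <- NULL
  if (trainFourClass) {
    fit4 <- trainAndTune(fs, rankings$fourClass$vote,
      architecture = "FOUR_CLASS", algorithms = algorithms,
      nFeaturesGrid = nFeaturesGrid, nConfigs = nConfigs,
      folds = folds, repeats = repeats, seed = seed
    )
    fourClass <- fit4$model
    r <- fit4$report
    perCols <- grep("^f1_", names(r), value = TRUE)
    fourClassPerClassF1 <- unlist(r[perCols])
    r <- r[setdiff(names(r), perCols)]
    r$target <- "4class"
    r$nSegments <- ncol(fs)
    reportRows$fourClass <- r
  }
  reportsDf <- do.call(rbind, reportRows)
  rownames(reportsDf) <- NULL
  manifest <- list(
    seed = seed,
    nSessions = nSessions,
    nValid = sum(valid),
    nInvalid = sum(!valid),
    nSegments = length(segments),
    perQuadrant = as.list(table(factor(labels, levels = quadrantLabels()))),
    nativeRate = nativeRate
  )
  bundle <- list(
    models = models, fourClass = fourClass,
    fourClassPerClassF1 = fourClassPerClassF1,
    scaler = featureScaler(fs), config = config,
    nativeRate = nativeRate, threshold = threshold,
    rankings = rankings, reports = reportsDf, manifest = manifest,
    features = fs
  )
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSegments(segments, file.path(outDir, "segments"))
    writeFeatureTable(fs, file.path(outDir, "features.csv"))
    for (q in names(rankings)) {
      writeRanking(rankings[[q]], file.path(outDir, paste0("ranking_", q, ".csv")))
    }
    utils::write.csv(reportsDf, file.path(outDir, "reports.csv"),
      row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  bundle
}
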