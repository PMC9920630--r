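## Raw-log dialect: comma-separated `timestamp_ms,resistance_ohm`, optional
## single header line. Header is recognised by a non-numeric first field.

#' Read a wearable raw log
#'
#' Parses the device's delimited RAW format: one `timestamp_ms,resistance_ohm`
#' record per line, with an optional single header line (detected by a
#' non-numeric first field). Samples are returned in timestamp order.
#'
#' @param path path to the log file.
#' @param sessionId identifier for the session; defaults to the file name
#'   without extension.
#' @param nominalRate device acquisition rate in Hz (default 8).
#' @return A [RawSession-class].
#' @seealso [writeRawLog()]
#' @export
readRawLog <- function(path, sessionId = NULL, nominalRate = 8) {
  if (!file.exists(path)) stop("raw log not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty raw log: ", path)
  first <- strsplit(lines[1], ",", fixed = TRUE)[[1]][1]
  offset <- 0L
  if (is.na(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1]
    offset <- 1L
    if (length(lines) == 0L) stop("empty raw log (header only): ", path)
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop("malformed raw-log line ", bad[1] + offset, " in ", path)
  ts <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  rs <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(ts) | is.na(rs))
  if (length(bad) > 0L)
    stop("malformed raw-log line ", bad[1] + offset, " in ", path)
  o <- order(ts)
  if (is.null(sessionId))
    sessionId <- sub("\\.[^.]*$", "", basename(path))
  RawSession(ts[o], rs[o], sessionId = sessionId, nominalRate = nominalRate)
}

#' Write a wearable raw log
#'
#' Serialises a session in the RAW dialect read by [readRawLog()]:
#' a `timestamp_ms,resistance_ohm` header followed by one record per
#' sample. Timestamps are written exactly; resistances with 6 significant
#' digits.
#'
#' @param session a [RawSession-class] (or [LabeledSegment-class]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRawLog <- function(session, path) {
  stopifnot(is(session, "RawSession"), length(session) > 0L)
  lines <- c(
    "timestamp_ms,resistance_ohm",
    paste(
      format(session@timestamp, trim = TRUE, scientific = FALSE, digits = 15),
      signif(session@resistance, 6),
      sep = ","
    )
  )
  ok <- tryCatch(
    {
      writeLines(lines, path)
      TRUE
    },
    error = function(e) stop("cannot write raw log to ", path, ": ",
      conditionMessage(e))
  )
  invisible(path)
}

#' Default session-validation rules
#'
#' Operational criteria for discarding sessions whose data contain errors
#' or are incomplete: the recording must cover at least `minCoverage` of
#' the protocol duration (`TRUNCATED`), timestamps must be strictly
#' increasing (`NONMONOTONE_TIME`), resistances must stay within
#' `resistanceRange` ohms (`OUT_OF_RANGE`), and no inter-sample gap may
#' exceed `maxGap` seconds (`GAP`).
#'
#' @param minCoverage minimum fraction of the protocol duration covered
#'   (default 0.9).
#' @param resistanceRange length-2 numeric, plausible resistance bounds in
#'   ohms (default 10 kOhm .. 10 MOhm).
#' @param maxGap maximum tolerated inter-sample gap in seconds (default 5).
#' @return A named list of rules.
#' @export
validationRules <- function(minCoverage = 0.9,
                            resistanceRange = c(1e4, 1e7),
                            maxGap = 5) {
  list(
    minCoverage = minCoverage, resistanceRange = resistanceRange,
    maxGap = maxGap
  )
}

#' Validate a session against a protocol
#'
#' Applies the [validationRules()] checks and reports, never raises, on bad
#' data. The report is a pure function of its inputs.
#'
#' @param session a [RawSession-class].
#' @param protocol the [ProtocolSpec-class] the session should cover.
#' @param rules a rule list from [validationRules()].
#' @return A [ValidationReport-class].
#' @examples
#' s <- RawSession(c(0, 500, 1000), rep(5e5, 3), nominalRate = 2)
#' validateSession(s, ProtocolSpec("Happy", 1, pause = 0))
#' @export
validateSession <- function(session, protocol, rules = validationRules()) {
  reasons <- character(0)
  ts <- session@timestamp / 1000
  if (any(diff(ts) <= 0)) reasons <- c(reasons, "NONMONOTONE_TIME")
  covered <- max(ts) - min(ts)
  need <- protocolDuration(protocol)
  if (need > 0 && covered < rules$minCoverage * need)
    reasons <- c(reasons, "TRUNCATED")
  r <- session@resistance
  if (any(r < rules$resistanceRange[1] | r > rules$resistanceRange[2]))
    reasons <- c(reasons, "OUT_OF_RANGE")
  ## gap check only meaningful on an ordered clock
  if (!"NONMONOTONE_TIME" %in% reasons && any(diff(ts) > rules$maxGap))
    reasons <- c(reasons, "GAP")
  ValidationReport(reasons)
}

#' Split a session into labelled per-song segments
#'
#' Cuts the trace at the protocol's cumulative song boundaries. Each
#' non-relaxation song yields one [LabeledSegment-class] carrying its
#' quadrant label; the relaxation song and the inter-song pauses are
#' discarded. Segment windows are half-open `[start, end)` on the schedule
#' clock.
#'
#' @param session a valid [RawSession-class].
#' @param protocol the [ProtocolSpec-class] describing the song schedule.
#' @return A list of [LabeledSegment-class], in schedule order.
#' @examples
#' p <- ProtocolSpec(c("Happy", "Sad"), c(10, 10), pause = 15)
#' ts <- seq(0, 35000, by = 500)
#' s <- RawSession(ts, rep(5e5, length(ts)), "s1", nominalRate = 2)
#' length(segmentSession(s, p)) # 2
#' @export
segmentSession <- function(session, protocol) {
  sched <- protocolSchedule(protocol)
  sched <- sched[sched$label != relaxLabel(), , drop = FALSE]
  if (nrow(sched) == 0L) return(list())
  ts <- session@timestamp / 1000
  covered <- max(ts)
  if (covered < max(sched$end) - 1 / session@nominalRate)
    stop(
      "session '", session@sessionId, "' (", round(covered, 1),
      " s) is shorter than the protocol schedule (", max(sched$end), " s)"
    )
  lapply(seq_len(nrow(sched)), function(i) {
    keep <- ts >= sched$start[i] & ts < sched$end[i]
    new("LabeledSegment",
      timestamp = session@timestamp[keep],
      resistance = session@resistance[keep],
      sessionId = paste0(session@sessionId, "_song", sched$songIndex[i]),
      nominalRate = session@nominalRate,
      label = sched$label[i],
      sourceSession = session@sessionId,
      songIndex = as.integer(sched$songIndex[i])
    )
  })
}

#' Write segments with a label manifest
#'
#' Writes each segment as a raw log in its own file plus a sidecar CSV
#' manifest (`segment_file,label,session_id,song_index`).
#'
#' @param segments list of [LabeledSegment-class].
#' @param dir output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
writeSegments <- function(segments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(segments, function(seg) {
    f <- paste0(seg@sessionId, ".csv")
    writeRawLog(seg, file.path(dir, f))
    data.frame(
      segment_file = f, label = seg@label,
      session_id = seg@sourceSession, song_index = seg@songIndex,
      stringsAsFactors = FALSE
    )
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "segments_manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
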