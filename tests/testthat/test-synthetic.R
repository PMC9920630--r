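test_that("a degenerate profile produces a constant resistance trace", {
  prof <- QuadrantProfile(4,
    scrRate = 0, scrAmpMedian = 0.3, tonicDriftSd = 0,
    noiseSd = 0
  )
  g <- generateSegment(prof, duration = 30, rate = 8, seed = 1)
  expect_equal(sessionResistances(g$session),
    rep(1e6 / 4, length(g$session)),
    tolerance = 1e-12
  )
  expect_equal(nrow(g$events), 0L)
})

test_that("generation is a pure function of profile, duration, rate and seed", {
  p <- defaultProfiles()$Aggressive
  a <- generateSegment(p, duration = 45, seed = 12)
  b <- generateSegment(p, duration = 45, seed = 12)
  expect_identical(sessionResistances(a$session), sessionResistances(b$session))
  expect_identical(a$events, b$events)
  c <- generateSegment(p, duration = 45, seed = 13)
  expect_false(identical(
    sessionResistances(a$session),
    sessionResistances(c$session)
  ))
})

test_that("injected SCR counts follow the configured Poisson rate", {
  prof <- QuadrantProfile(3, scrRate = 2, scrAmpMedian = 0.2)
  counts <- vapply(
    1:50,
    function(s) nrow(generateSegment(prof, duration = 300, seed = s)$events),
    numeric(1)
  )
  # total of 50 Poisson(10) draws: compare with the 99% interval
  total <- sum(counts)
  expect_gte(total, qpois(0.005, 50 * 10))
  expect_lte(total, qpois(0.995, 50 * 10))
})

test_that("profile invariants guard detectability of the median SCR", {
  expect_error(
    QuadrantProfile(3, scrRate = 2, scrAmpMedian = 0.05, scrRise = 3.5),
    "3x the slope threshold"
  )
  expect_error(
    QuadrantProfile(3, scrRate = 2, scrAmpMedian = 0.3, scrRise = 1),
    "minimum duration"
  )
})

test_that("default profiles encode the arousal axis", {
  p <- defaultProfiles()
  expect_gt(p$Happy@scrRate, p$Relaxed@scrRate)
  expect_gt(p$Aggressive@scrRate, p$Sad@scrRate)
  expect_gt(p$Happy@scrAmpMedian, p$Sad@scrAmpMedian)
})

test_that("contrast interpolation reaches the null at 0 and identity at 1", {
  p0 <- profilesAtContrast(0)
  for (q in c("Sad", "Aggressive", "Relaxed")) {
    expect_equal(p0[[q]]@tonicBaseline, p0$Happy@tonicBaseline)
    expect_equal(p0[[q]]@scrRate, p0$Happy@scrRate)
  }
  p1 <- profilesAtContrast(1)
  expect_equal(p1$Happy@tonicBaseline, defaultProfiles()$Happy@tonicBaseline)
})

test_that("experiment counts are conserved and corruption covers all reasons", {
  spec <- experimentSpec(
    nParticipants = 8, nInvalid = 4,
    protocol = defaultProtocol(songDuration = 40), nativeRate = 4, seed = 6
  )
  corpus <- generateExperiment(spec)
  expect_length(corpus$sessions, 8L)
  expect_equal(sum(corpus$manifest$corrupted), 4L)
  expect_setequal(
    na.omit(corpus$manifest$mode),
    c("TRUNCATED", "NONMONOTONE_TIME", "OUT_OF_RANGE", "GAP")
  )
  vr <- vapply(
    corpus$sessions,
    function(s) isValid(validateSession(s, spec$protocol)), TRUE
  )
  # corrupted sessions fail, clean sessions pass: valid + invalid = n
  expect_equal(sum(vr), 4L)
  expect_equal(vr, !corpus$manifest$corrupted)
  segs <- unlist(lapply(corpus$sessions[vr], segmentSession,
    protocol = spec$protocol
  ), recursive = FALSE)
  expect_length(segs, 8L * sum(vr))

  # same seed, identical manifest and ground truth
  corpus2 <- generateExperiment(spec)
  expect_identical(corpus2$manifest, corpus$manifest)
  expect_identical(corpus2$events, corpus$events)
})

test_that("injected SCRs are recovered from low-noise segments", {
  prof <- QuadrantProfile(3,
    scrRate = 3, scrAmpMedian = 0.2, scrAmpSigmaLog = 0.25,
    scrRise = 4, scrDecay = 10, noiseSd = 0.005, tonicDriftSd = 0.01
  )
  hits <- 0
  tot <- 0
  fp <- 0
  for (seed in 1:10) {
    g <- generateSegment(prof, duration = 120, seed = seed)
    sig <- removeArtifacts(downsampleSignal(gsrToEda(g$session), 2), 5)
    ev <- detectEvents(decomposeSignal(sig), detectionParams())
    pk <- ev[ev$kind == "PEAK", ]
    used <- logical(nrow(pk))
    for (i in seq_len(nrow(g$events))) {
      on <- g$events$onset[i]
      tot <- tot + 1
      ov <- which(pk$start / 2 < on + 5 & pk$end / 2 > on)
      if (length(ov) > 0) {
        hits <- hits + 1
        used[ov] <- TRUE
      }
    }
    fp <- fp + sum(!used)
  }
  expect_gte(hits / tot, 0.9)
  expect_lte(fp / (10 * 2), 1) # false peaks per minute
})
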