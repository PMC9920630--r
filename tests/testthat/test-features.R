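test_that("the feature vector covers exactly the fifteen canonical names", {
  expect_length(featureNames(), 15L)
  g <- generateSegment(defaultProfiles()$Happy, duration = 40, seed = 1)
  fv <- extractFeatures(g$session)
  expect_named(fv, featureNames())
})

test_that("statistical features match hand-computed values", {
  fv <- statisticalFeatures(EDASignal(c(1, 2, 3, 4), rate = 2))
  expect_equal(fv[["Mean"]], 2.5)
  expect_equal(fv[["Median"]], 2.5)
  expect_equal(fv[["Max"]], 4)
  expect_equal(fv[["Min"]], 1)
  expect_equal(fv[["Std"]], sqrt(1.25)) # population sd
  expect_equal(fv[["Skewness"]], 0)

  # degenerate conventions on a constant 2 uS segment
  fv <- statisticalFeatures(EDASignal(rep(2, 20), rate = 2))
  expect_equal(unname(fv[c("Mean", "Median", "Max", "Min")]), rep(2, 4))
  expect_equal(unname(fv[c("Std", "Skewness", "Kurtosis")]), rep(0, 3))
  expect_equal(fv[["AUC"]], 2) # uS-seconds per second of signal

  expect_equal(statisticalFeatures(EDASignal(c(1, 2, 3), 2))[["Skewness"]], 0)
  expect_error(statisticalFeatures(EDASignal(1, 2)), "2 samples")
})

test_that("statistical features agree with direct-formula oracles to 1e-9", {
  for (trial in 1:50) {
    v <- randomSignal(200, seed = trial)
    fv <- statisticalFeatures(EDASignal(v, rate = 2))
    want <- oracleStats(v, rate = 2)
    for (nm in names(want)) {
      expect_equal(fv[[nm]], want[[nm]], tolerance = 1e-9, label = nm)
    }
  }
})

test_that("PSD equals a directly computed single-segment periodogram", {
  # 32-sample signal: one Welch segment, so the estimate reduces to one
  # Hann-windowed periodogram, recomputed here from explicit DFT sums
  v <- randomSignal(32, seed = 5)
  rate <- 2
  got <- statisticalFeatures(EDASignal(v, rate), welchSegment = 64)[["PSD"]]
  n <- 32L
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  x <- (v - mean(v)) * w
  psd <- numeric(n %/% 2 + 1)
  for (k in 0:(n %/% 2)) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    psd[k + 1] <- (re^2 + im^2) / (rate * sum(w^2))
  }
  psd[2:(n %/% 2)] <- 2 * psd[2:(n %/% 2)]
  expect_equal(got, median(psd), tolerance = 1e-9)
})

test_that("event features summarise peak and offset amplitudes", {
  ev <- data.frame(
    kind = c("PEAK", "PEAK", "OFFSET"),
    start = c(1, 20, 40), end = c(8, 27, 47),
    duration = c(3.5, 3.5, 3.5), amplitude = c(0.1, 0.3, 0.2)
  )
  fv <- eventFeatures(ev, 60)
  expect_equal(fv[["MeanPA"]], 0.2)
  expect_equal(fv[["MaxPA"]], 0.3)
  expect_equal(fv[["MeanOA"]], 0.2)
  expect_equal(fv[["MaxOA"]], 0.2)

  ev3 <- ev[ev$kind == "PEAK", ][c(1, 1, 2), ] # 3 peaks, 0 offsets
  fv <- eventFeatures(ev3, 60)
  expect_equal(fv[["PPS"]], 0.05)
  expect_equal(fv[["OPS"]], 0)
  expect_equal(fv[["MeanOA"]], 0)

  fv <- eventFeatures(ev[0, ], 60)
  expect_equal(unname(fv), rep(0, 6))
  expect_error(eventFeatures(ev, -1), "positive")
})

test_that("full extraction is deterministic and honours known injections", {
  # flat tonic, zero noise, no SCRs: no variance, no events
  s <- sessionFromEda(rep(4, 60 * 8), rate = 8)
  fv <- extractFeatures(s)
  expect_equal(fv[["Std"]], 0)
  expect_equal(fv[["PPS"]], 0)
  expect_equal(fv[["OPS"]], 0)

  # two hand-placed SCR kernels in 120 s: PPS = 2/120
  rate <- 8
  tt <- seq(0, 120, by = 1 / rate)
  eda <- rep(3, length(tt))
  for (on in c(30, 80)) {
    rel <- tt - on
    eda <- eda + ifelse(rel < 0, 0,
      ifelse(rel < 4, 0.3 * rel / 4, 0.3 * exp(-(rel - 4) / 10))
    )
  }
  fv <- extractFeatures(sessionFromEda(eda, rate))
  expect_equal(fv[["PPS"]], 2 / 120, tolerance = 1e-3)

  g <- generateSegment(defaultProfiles()$Happy, duration = 60, seed = 3)
  expect_identical(extractFeatures(g$session), extractFeatures(g$session))
})

test_that("min-max normalisation maps each feature onto [0, 1]", {
  mat <- rbind(
    Mean = c(2, 4, 6),
    Std = c(5, 5, 5),
    PPS = c(0, 0.5, 1)
  )
  colnames(mat) <- paste0("s", 1:3)
  fs <- EDAFeatureSet(mat, c("Happy", "Sad", "Relaxed"))
  expect_false(isNormalized(fs))
  nf <- normalizeFeatures(fs)
  expect_true(isNormalized(nf))
  expect_equal(unname(assay(nf)["Mean", ]), c(0, 0.5, 1))
  expect_equal(unname(assay(nf)["Std", ]), c(0, 0, 0)) # constant column
  expect_equal(unname(assay(nf)["PPS", ]), c(0, 0.5, 1)) # endpoints kept

  # the fitted scaler transforms future rows consistently
  sc <- featureScaler(nf)
  expect_equal(
    unname(applyScaler(c(Mean = 4, Std = 5, PPS = 0.25), sc)),
    c(0.5, 0, 0.25)
  )
})

test_that("normalisation is invariant to positive affine feature maps", {
  withr::with_seed(11, {
    x <- runif(10)
    a <- 3.7
    b <- -1.2
    m1 <- matrix(x, nrow = 1, dimnames = list("Mean", paste0("s", 1:10)))
    m2 <- matrix(a * x + b, nrow = 1, dimnames = list("Mean", paste0("s", 1:10)))
    labs <- rep(quadrantLabels(), length.out = 10)
    n1 <- assay(normalizeFeatures(EDAFeatureSet(m1, labs)))
    n2 <- assay(normalizeFeatures(EDAFeatureSet(m2, labs)))
    expect_equal(n1, n2, tolerance = 1e-12)
  })
})

test_that("feature tables survive a CSV round trip", {
  g <- lapply(1:4, function(i) {
    seg <- generateSegment(defaultProfiles()[[quadrantLabels()[i]]],
      duration = 40, seed = i, sessionId = paste0("s", i)
    )$session
    new("LabeledSegment",
      timestamp = sessionTimestamps(seg), resistance = sessionResistances(seg),
      sessionId = paste0("s", i), nominalRate = 8,
      label = quadrantLabels()[i], sourceSession = "P1", songIndex = i
    )
  })
  fs <- buildFeatureTable(g)
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(fs, f)
  fs2 <- readFeatureTable(f)
  expect_equal(assay(fs2), assay(fs), tolerance = 1e-12)
  expect_equal(segmentLabels(fs2), segmentLabels(fs))
})
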