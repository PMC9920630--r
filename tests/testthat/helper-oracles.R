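# Independent oracles, deliberately written with different algorithms than
# the package implementation (explicit loops, O(n^2) scans, direct formula
# sums) so they can serve as cross-checks.

# Direct-formula statistical moments over a value vector.
oracleStats <- function(v, rate) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  srt <- sort(v)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  # trapezoid rule by explicit loop
  auc <- 0
  for (i in seq_len(n - 1)) auc <- auc + (v[i] + v[i + 1]) / 2 * (1 / rate)
  auc <- auc / ((n - 1) / rate)
  c(
    Mean = m, Median = med, Std = sqrt(m2), Max = max(v), Min = min(v),
    Kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    AUC = auc
  )
}

# Brute-force SCR event enumeration: explicit sample-by-sample scan for
# maximal constant-sign monotone stretches, qualified by mean slope and
# duration. `smooth` mirrors the detector's pre-smoothing contract but is
# computed here with a plain loop.
oracleEvents <- function(v, rate, slopeThreshold = 0.01, minDuration = 3,
                         smooth = 3L) {
  n <- length(v)
  if (smooth > 1L && n > smooth) {
    k <- (smooth - 1L) %/% 2L
    padded <- c(rev(v[2:(k + 1)]), v, rev(v[(n - k):(n - 1)]))
    u <- numeric(n)
    for (i in seq_len(n)) u[i] <- mean(padded[i:(i + 2 * k)])
    v <- u
  }
  sgn <- integer(n - 1)
  for (i in seq_len(n - 1)) {
    d <- v[i + 1] - v[i]
    sgn[i] <- if (d > 0) 1L else if (d < 0) -1L else 0L
  }
  out <- NULL
  i <- 1L
  while (i <= n - 1L) {
    if (sgn[i] == 0L) {
      i <- i + 1L
      next
    }
    j <- i
    while (j + 1L <= n - 1L && sgn[j + 1L] == sgn[i]) j <- j + 1L
    dur <- (j - i + 1L) / rate
    amp <- abs(v[j + 1L] - v[i])
    if (dur >= minDuration && amp >= slopeThreshold * dur) {
      out <- rbind(out, data.frame(
        kind = if (sgn[i] > 0) "PEAK" else "OFFSET",
        start = i, end = j + 1L, duration = dur, amplitude = amp,
        stringsAsFactors = FALSE
      ))
    }
    i <- j + 1L
  }
  if (is.null(out)) {
    data.frame(
      kind = character(0), start = integer(0), end = integer(0),
      duration = numeric(0), amplitude = numeric(0), stringsAsFactors = FALSE
    )
  } else {
    out
  }
}

# Confusion-matrix metrics oracle via explicit 2x2 table.
oracleBinaryMetrics <- function(pred, truth, positive) {
  tab <- matrix(0, 2, 2)
  for (i in seq_along(pred)) {
    r <- if (pred[i] == positive) 1 else 2
    c <- if (truth[i] == positive) 1 else 2
    tab[r, c] <- tab[r, c] + 1
  }
  tp <- tab[1, 1]; fp <- tab[1, 2]; fn <- tab[2, 1]; tn <- tab[2, 2]
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(
    accuracy = (tp + tn) / length(pred),
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
    precision = prec, recall = rec
  )
}

# A raw session whose uniform-grid conductance trace is given in uS.
sessionFromEda <- function(eda, rate, sessionId = "synthetic") {
  RawSession(
    timestamp = (seq_along(eda) - 1) / rate * 1000,
    resistance = 1e6 / eda, sessionId = sessionId, nominalRate = rate
  )
}

# Random test signals: smooth tonic + occasional ramps + noise, seeded.
randomSignal <- function(n, rate = 2, seed = 1) {
  withr::with_seed(seed, {
    base <- cumsum(rnorm(n, 0, 0.02))
    if (n > 20) {
      k <- sample(0:2, 1)
      for (b in seq_len(k)) {
        at <- sample(seq_len(n - 10), 1)
        len <- sample(4:10, 1)
        idx <- at:min(at + len, n)
        base[idx] <- base[idx] + seq(0, 0.2, length.out = length(idx))
      }
    }
    base + rnorm(n, 0, 0.005) + 2
  })
}

# A small trained recognition bundle, built once per test session.
tinyBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prot <- defaultProtocol(songDuration = 60)
      cache <<- runTrainingPipeline(
        spec = experimentSpec(
          nParticipants = 8, nInvalid = 0, protocol = prot,
          nativeRate = 4, seed = 77
        ),
        algorithms = "KNN", nFeaturesGrid = 5, nConfigs = 1L,
        repeats = 1L, trainFourClass = FALSE
      )
    }
    cache
  }
})
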