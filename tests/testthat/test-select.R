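# A toy normalised table where one feature is the class indicator, one is
# constant, and the rest are seeded noise.
toyTable <- function(n = 40, seed = 3) {
  labs <- rep(c("Happy", "Sad"), each = n / 2)
  withr::with_seed(seed, {
    mat <- rbind(
      Mean = as.numeric(labs == "Happy"),
      Std = rep(0.5, n),
      PPS = runif(n),
      MaxPA = runif(n)
    )
  })
  colnames(mat) <- paste0("s", seq_len(n))
  EDAFeatureSet(mat, labs, normalized = TRUE)
}

test_that("chi-square ranking rewards class-indicator features", {
  fs <- toyTable()
  r <- rankChi2(fs)
  expect_s4_class(r, "FeatureRanking")
  expect_equal(rankedFeatures(r)[1], "Mean")
  sc <- rankingScores(r)
  expect_equal(sc[["Std"]], 0) # no association for a constant feature

  # brute-force statistic over the class-summed 2x2 mass table
  x <- as.numeric(segmentLabels(fs) == "Happy")
  obs <- c(sum(x[1:20]), sum(x[21:40])) # class sums of the indicator
  expd <- sum(x) * c(0.5, 0.5)
  expect_equal(sc[["Mean"]], sum((obs - expd)^2 / expd))

  # permutation invariance of the scores
  perm <- withr::with_seed(1, sample(ncol(fs)))
  fsp <- EDAFeatureSet(assay(fs)[, perm], segmentLabels(fs)[perm],
    normalized = TRUE
  )
  expect_equal(rankingScores(rankChi2(fsp)), sc)

  neg <- EDAFeatureSet(assay(fs) - 1, segmentLabels(fs), normalized = TRUE)
  expect_error(rankChi2(neg), "non-negative")
})

test_that("ANOVA-F ranking behaves at its limit cases", {
  fs <- toyTable()
  r <- rankAnovaF(fs)
  # zero within-class variance with distinct means: infinite F, first
  expect_equal(rankedFeatures(r)[1], "Mean")
  expect_equal(rankingScores(r)[["Mean"]], Inf)

  # two-class F equals the squared pooled t statistic
  v <- assay(fs)["PPS", ]
  g <- factor(segmentLabels(fs))
  tstat <- t.test(v ~ g, var.equal = TRUE)$statistic
  expect_equal(rankingScores(r)[["PPS"]], unname(tstat^2), tolerance = 1e-9)

  one <- EDAFeatureSet(assay(fs)[, 1:3], c("Happy", "Happy", "Sad"))
  expect_error(rankAnovaF(one), "at least 2")
})

test_that("label-independent features have F near 1 in expectation", {
  fs <- toyTable()
  fhat <- withr::with_seed(8, {
    replicate(300, {
      labs <- sample(segmentLabels(fs))
      rankingScores(rankAnovaF(fs, labs))[["PPS"]]
    })
  })
  expect_gt(mean(fhat), 0.75)
  expect_lt(mean(fhat), 1.35)
})

test_that("mutual information separates informative from independent features", {
  fs <- toyTable(n = 200)
  r <- rankMutualInfo(fs, seed = 5)
  sc <- rankingScores(r)
  expect_equal(rankedFeatures(r)[1], "Mean") # deterministic function of label
  # single-draw estimates for independent features stay small...
  expect_lt(sc[["PPS"]], 0.15)
  expect_lt(sc[["MaxPA"]], 0.15)
  # ...and average to ~0 over label permutations (independence simulation)
  nullMI <- vapply(1:10, function(r) {
    labs <- withr::with_seed(500 + r, sample(segmentLabels(fs)))
    rankingScores(rankMutualInfo(fs, labs, seed = r))[["MaxPA"]]
  }, numeric(1))
  expect_lt(mean(nullMI), 0.05)
  # fixed seed gives an identical ranking
  expect_identical(
    rankedFeatures(rankMutualInfo(fs, seed = 5)),
    rankedFeatures(r)
  )
})

test_that("Borda voting aggregates rankings by rank sums", {
  r1 <- FeatureRanking(c("A", "B", "C"), 3:1, "CHI2")
  r2 <- FeatureRanking(c("B", "A", "C"), 3:1, "ANOVA_F")
  r3 <- FeatureRanking(c("A", "C", "B"), 3:1, "MI")
  v <- voteRankings(list(r1, r2, r3))
  expect_equal(rankedFeatures(v), c("A", "B", "C"))
  expect_equal(unname(rankingScores(v)), c(4, 6, 8))

  expect_equal(
    rankedFeatures(voteRankings(list(r1, r1, r1))),
    rankedFeatures(r1)
  )
  expect_equal(rankedFeatures(voteRankings(list(r2))), rankedFeatures(r2))

  # supply order must not matter
  expect_equal(
    rankedFeatures(voteRankings(list(r3, r1, r2))),
    rankedFeatures(v)
  )

  r4 <- FeatureRanking(c("A", "B"), 2:1, "MI")
  expect_error(voteRankings(list(r1, r4)), "same feature set")
})

test_that("a feature dominating all three tests wins the vote", {
  for (seed in 1:20) {
    labs <- rep(quadrantLabels(), each = 10)
    mat <- withr::with_seed(seed, rbind(
      Mean = (match(labs, quadrantLabels()) - 1) / 3, # tracks the class
      PPS = runif(40),
      MaxPA = runif(40),
      Std = runif(40)
    ))
    colnames(mat) <- paste0("s", 1:40)
    fs <- EDAFeatureSet(mat, labs, normalized = TRUE)
    rk <- rankFeatures(fs, seed = seed)
    expect_equal(rankedFeatures(rk$vote)[1], "Mean")
  }
})

test_that("one-vs-rest rankings may order features differently per quadrant", {
  g <- generateExperiment(experimentSpec(
    nParticipants = 4, nInvalid = 0,
    protocol = defaultProtocol(songDuration = 40), nativeRate = 4, seed = 2
  ))
  segs <- unlist(lapply(g$sessions, segmentSession,
    protocol = defaultProtocol(songDuration = 40)
  ), recursive = FALSE)
  fs <- normalizeFeatures(buildFeatureTable(segs))
  orders <- lapply(quadrantLabels(), function(q) {
    rankedFeatures(rankFeatures(
      fs, oneVsRestLabels(segmentLabels(fs), q),
      seed = 2
    )$vote)
  })
  for (o in orders) expect_setequal(o, featureNames())
})
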