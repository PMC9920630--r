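## Univariate feature relevance: three statistical tests, each producing a
## full ordering of the 15 features, combined by Borda rank-sum voting.

featureMatrix <- function(fs) {
  stopifnot(is(fs, "EDAFeatureSet"))
  t(assay(fs)) # segments x features
}

#' Rank features by the chi-square statistic
#'
#' The chi-square feature-screening statistic for non-negative feature
#' values: observed class-wise feature mass versus the mass expected under
#' the class frequencies. Requires a normalised (non-negative) table.
#'
#' @param fs a normalised [EDAFeatureSet-class].
#' @param labels class label per segment; defaults to the table's labels.
#' @return A [FeatureRanking-class] (source `"CHI2"`), descending score.
#' @export
rankChi2 <- function(fs, labels = segmentLabels(fs)) {
  x <- featureMatrix(fs)
  if (any(x < 0))
    stop("chi-square ranking requires non-negative (normalised) features")
  y <- stats::model.matrix(~ 0 + factor(labels)) # n x k one-hot
  observed <- t(x) %*% y # features x classes
  featMass <- rowSums(observed)
  classProb <- colSums(y) / nrow(y)
  expected <- outer(featMass, classProb)
  term <- (observed - expected)^2 / expected
  term[expected == 0] <- 0
  score <- rowSums(term)
  o <- order(-score, colnames(x))
  FeatureRanking(colnames(x)[o], score[o], "CHI2")
}

#' Rank features by the one-way ANOVA F statistic
#'
#' Between-class over within-class variance ratio per feature. A feature
#' with distinct class means and zero within-class variance scores `Inf`.
#'
#' @inheritParams rankChi2
#' @return A [FeatureRanking-class] (source `"ANOVA_F"`).
#' @export
rankAnovaF <- function(fs, labels = segmentLabels(fs)) {
  x <- featureMatrix(fs)
  g <- factor(labels)
  k <- nlevels(g)
  if (k < 2L) stop("ANOVA F ranking needs at least 2 classes")
  if (min(table(g)) < 2L)
    stop("every class needs at least 2 segments for the F statistic")
  n <- nrow(x)
  score <- apply(x, 2L, function(v) {
    gm <- tapply(v, g, mean)
    ns <- tabulate(g)
    between <- sum(ns * (gm - mean(v))^2) / (k - 1)
    within <- sum((v - gm[g])^2) / (n - k)
    if (within == 0) {
      if (between == 0) 0 else Inf
    } else {
      between / within
    }
  })
  o <- order(-score, colnames(x))
  FeatureRanking(colnames(x)[o], score[o], "ANOVA_F")
}

## Nearest-neighbour mutual information between a continuous variable and a
## discrete label (Ross 2014): for each point, the k-th neighbour distance
## within its own class defines a radius; counting all points inside that
## radius relates the conditional to the marginal density.
miContinuousDiscrete <- function(v, g, k = 3L) {
  n <- length(v)
  counts <- table(g)
  keep <- g %in% names(counts)[counts > 1L]
  v <- v[keep]
  g <- g[keep]
  n <- length(v)
  if (n < 2L) return(0)
  nc <- table(g)[as.character(g)]
  kk <- pmin(k, as.integer(nc) - 1L)
  d <- abs(outer(v, v, "-"))
  diag(d) <- Inf
  radius <- numeric(n)
  for (i in seq_len(n)) {
    same <- g == g[i]
    same[i] <- FALSE
    radius[i] <- sort(d[i, same], partial = kk[i])[kk[i]]
  }
  m <- vapply(seq_len(n), function(i) sum(d[i, ] <= radius[i]), numeric(1))
  m <- pmax(m, kk) # the k same-class neighbours are always inside
  mi <- digamma(n) - mean(digamma(as.numeric(nc))) +
    mean(digamma(kk)) - mean(digamma(m))
  max(mi, 0)
}

#' Rank features by estimated mutual information with the label
#'
#' Mutual information between each (continuous) feature and the discrete
#' class label, estimated with a k-nearest-neighbour estimator. A tiny
#' seeded jitter breaks ties between identical values, so the ranking is
#' deterministic for a fixed seed.
#'
#' @inheritParams rankChi2
#' @param seed integer seed for the tie-breaking jitter.
#' @param k neighbour count of the estimator (default 3).
#' @return A [FeatureRanking-class] (source `"MI"`).
#' @export
rankMutualInfo <- function(fs, labels = segmentLabels(fs), seed = 1L, k = 3L) {
  x <- featureMatrix(fs)
  g <- factor(labels)
  score <- withr::with_seed(seed, {
    apply(x, 2L, function(v) {
      scale <- max(abs(v), 1e-12)
      v <- v + stats::rnorm(length(v), sd = 1e-10 * scale)
      miContinuousDiscrete(v, g, k = k)
    })
  })
  o <- order(-score, colnames(x))
  FeatureRanking(colnames(x)[o], score[o], "MI")
}

#' Combine rankings by Borda voting
#'
#' Each test contributes its positional rank (1 = most relevant) per
#' feature; features are ordered by ascending rank sum. Ties are broken by
#' the ANOVA-F rank when an `ANOVA_F` ranking is among the inputs, then
#' lexicographically by name. The result does not depend on the order in
#' which the rankings are supplied.
#'
#' @param rankings list of [FeatureRanking-class] over the same feature set.
#' @return A [FeatureRanking-class] with source `"VOTE"`; its scores are
#'   the rank sums (smaller = more relevant).
#' @examples
#' r1 <- FeatureRanking(c("A", "B", "C"), 3:1, "CHI2")
#' r2 <- FeatureRanking(c("B", "A", "C"), 3:1, "ANOVA_F")
#' r3 <- FeatureRanking(c("A", "C", "B"), 3:1, "MI")
#' rankedFeatures(voteRankings(list(r1, r2, r3))) # A B C
#' @export
voteRankings <- function(rankings) {
  stopifnot(length(rankings) >= 1L)
  feats <- sort(rankings[[1]]@features)
  for (r in rankings) {
    if (!identical(sort(r@features), feats))
      stop("all rankings must cover the same feature set")
  }
  pos <- vapply(rankings, function(r) match(feats, r@features), numeric(length(feats)))
  pos <- matrix(pos, nrow = length(feats))
  rankSum <- rowSums(pos)
  fIdx <- which(vapply(rankings, function(r) r@source == "ANOVA_F", TRUE))
  fRank <- if (length(fIdx) > 0L) pos[, fIdx[1]] else rep(0, length(feats))
  o <- order(rankSum, fRank, feats)
  FeatureRanking(feats[o], rankSum[o], "VOTE")
}

#' Rank features by all three tests and vote
#'
#' Convenience wrapper running [rankChi2()], [rankAnovaF()] and
#' [rankMutualInfo()] on the same table and combining them with
#' [voteRankings()]. For a one-vs-rest quadrant ranking pass
#' `labels = oneVsRestLabels(segmentLabels(fs), "Happy")` etc.
#'
#' @inheritParams rankMutualInfo
#' @return A list with elements `chi2`, `anovaF`, `mi` and `vote`.
#' @export
rankFeatures <- function(fs, labels = segmentLabels(fs), seed = 1L) {
  r <- list(
    chi2 = rankChi2(fs, labels),
    anovaF = rankAnovaF(fs, labels),
    mi = rankMutualInfo(fs, labels, seed = seed)
  )
  r$vote <- voteRankings(r[c("chi2", "anovaF", "mi")])
  r
}

#' One-vs-rest label recoding
#'
#' @param labels character vector of quadrant labels.
#' @param positive the quadrant treated as the positive class.
#' @return character vector with values `positive` and `"Rest"`.
#' @export
oneVsRestLabels <- function(labels, positive) {
  stopifnot(positive %in% quadrantLabels())
  ifelse(labels == positive, positive, "Rest")
}

#' Write a ranking (or a voted set of rankings) as CSV
#'
#' @param rankings result of [rankFeatures()].
#' @param path output path; columns `rank`, `feature`, `score_chi2`,
#'   `score_f`, `score_mi`, `rank_sum`.
#' @return `path`, invisibly.
#' @export
writeRanking <- function(rankings, path) {
  feats <- rankedFeatures(rankings$vote)
  df <- data.frame(
    rank = seq_along(feats),
    feature = feats,
    score_chi2 = rankingScores(rankings$chi2)[feats],
    score_f = rankingScores(rankings$anovaF)[feats],
    score_mi = rankingScores(rankings$mi)[feats],
    rank_sum = rankingScores(rankings$vote)[feats]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
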