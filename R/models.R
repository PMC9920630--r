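## Classification architectures: one four-class model over the quadrants,
## or four one-vs-rest binary models. Five algorithm families (KNN, RF,
## MLP, LSVC, GB) behind a uniform fit/predict-probabilities wrapper so
## the tuning loop, metrics and the streaming recogniser are agnostic to
## the algorithm in use.

#' Supported algorithm identifiers
#' @return character(5): `"KNN"`, `"RF"`, `"MLP"`, `"LSVC"`, `"GB"`.
#' @export
algorithmNames <- function() c("KNN", "RF", "MLP", "LSVC", "GB")

## Sample n hyperparameter configurations for one algorithm (seeded).
sampleHyperparameters <- function(algorithm, n, seed, p) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      switch(algorithm,
        KNN = list(k = sample(c(1L, 3L, 5L, 7L, 9L, 11L), 1L)),
        RF = list(
          ntree = sample(c(100L, 200L, 300L), 1L),
          mtry = sample(seq_len(max(1L, p)), 1L),
          nodesize = sample(c(1L, 3L, 5L), 1L)
        ),
        MLP = list(
          size = sample(c(2L, 4L, 8L, 16L), 1L),
          decay = 10^stats::runif(1, -4, -1),
          maxit = 200L
        ),
        LSVC = list(cost = 10^stats::runif(1, -2, 2)),
        GB = list(
          nrounds = sample(c(50L, 100L), 1L),
          eta = sample(c(0.05, 0.1, 0.3), 1L),
          max_depth = sample(2:4, 1L)
        ),
        stop("unknown algorithm: ", algorithm)
      )
    })
  })
}

## Euclidean k-NN with full per-class vote fractions (needed because the
## prediction contract requires a probability for every quadrant).
knnProbs <- function(trainX, trainY, testX, k) {
  lv <- levels(trainY)
  k <- min(k, nrow(trainX))
  d2 <- outer(rowSums(testX^2), rowSums(trainX^2), "+") -
    2 * testX %*% t(trainX)
  probs <- t(apply(d2, 1L, function(di) {
    nb <- order(di)[seq_len(k)]
    tabulate(trainY[nb], nbins = length(lv)) / k
  }))
  colnames(probs) <- lv
  probs
}

#' Fit one classifier
#'
#' Uniform wrapper over the five algorithm families. All stochastic fits
#' are seeded; identical inputs and seed yield identical models.
#'
#' @param algorithm one of [algorithmNames()].
#' @param x numeric matrix, segments x features (normalised to \[0, 1\]).
#' @param y factor of class labels (2 levels for binary, 4 for the
#'   four-class architecture).
#' @param hyper named list of hyperparameters (see
#'   internal sampler defaults); missing entries take defaults.
#' @param seed integer seed.
#' @return An object of class `edaModel` supporting [predictProbs()].
#' @export
fitModel <- function(algorithm, x, y, hyper = list(), seed = 1L) {
  stopifnot(algorithm %in% algorithmNames(), is.matrix(x), nrow(x) == length(y))
  y <- droplevels(factor(y))
  lv <- levels(y)
  fit <- withr::with_seed(seed, switch(algorithm,
    KNN = list(trainX = x, trainY = y, k = hyper$k %||% 5L),
    RF = randomForest::randomForest(
      x = x, y = y,
      ntree = hyper$ntree %||% 200L,
      mtry = min(hyper$mtry %||% max(1L, floor(sqrt(ncol(x)))), ncol(x)),
      nodesize = hyper$nodesize %||% 1L
    ),
    MLP = nnet::nnet(
      x = x, y = nnet::class.ind(y),
      size = hyper$size %||% 8L, decay = hyper$decay %||% 1e-3,
      maxit = hyper$maxit %||% 200L, softmax = TRUE, trace = FALSE,
      MaxNWts = 10000L
    ),
    LSVC = lapply(stats::setNames(lv, lv), function(cl) {
      yy <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
      if (length(unique(yy)) < 2L) return(NULL)
      e1071::svm(
        x = x, y = yy, kernel = "linear",
        cost = hyper$cost %||% 1, scale = FALSE
      )
    }),
    GB = {
      par <- list(
        eta = hyper$eta %||% 0.1,
        max_depth = hyper$max_depth %||% 3L,
        nthread = 1L, seed = seed
      )
      if (length(lv) == 2L) {
        par$objective <- "binary:logistic"
      } else {
        par$objective <- "multi:softprob"
        par$num_class <- length(lv)
      }
      xgboost::xgb.train(
        params = par,
        data = xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L),
        nrounds = hyper$nrounds %||% 100L
      )
    }
  ))
  structure(
    list(
      algorithm = algorithm, fit = fit, levels = lv,
      features = colnames(x), hyper = hyper, seed = seed
    ),
    class = "edaModel"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Class-probability predictions from a fitted model
#'
#' @param model an `edaModel` from [fitModel()].
#' @param x numeric matrix (rows = cases) over the model's features.
#' @return Numeric matrix, rows = cases, one column per class level, rows
#'   summing to 1 (margin classifiers map decision scores through a
#'   logistic and renormalise).
#' @export
predictProbs <- function(model, x) {
  stopifnot(inherits(model, "edaModel"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- x[, model$features, drop = FALSE]
  lv <- model$levels
  probs <- switch(model$algorithm,
    KNN = knnProbs(model$fit$trainX, model$fit$trainY, x, model$fit$k),
    RF = stats::predict(model$fit, x, type = "prob")[, lv, drop = FALSE],
    MLP = {
      p <- stats::predict(model$fit, x)
      colnames(p) <- colnames(model$fit$fitted.values)
      p[, lv, drop = FALSE]
    },
    LSVC = {
      p <- vapply(lv, function(cl) {
        f <- model$fit[[cl]]
        if (is.null(f)) return(rep(0, nrow(x)))
        dv <- attr(stats::predict(f, x, decision.values = TRUE),
          "decision.values")
        d <- dv[, 1]
        ## orient so a positive score favours the "pos" class
        if (!startsWith(colnames(dv)[1], "pos")) d <- -d
        stats::plogis(d)
      }, numeric(nrow(x)))
      p <- matrix(p, nrow = nrow(x), dimnames = list(NULL, lv))
      p / rowSums(p)
    },
    GB = {
      p <- stats::predict(model$fit, xgboost::xgb.DMatrix(x))
      if (length(lv) == 2L) {
        cbind(1 - p, p) # xgboost reports P(label == 1), i.e. second level
      } else {
        matrix(as.numeric(p), ncol = length(lv))
      }
    }
  )
  probs <- matrix(as.numeric(probs), nrow = nrow(x), dimnames = list(NULL, lv))
  probs / pmax(rowSums(probs), 1e-12)
}

#' Classification metrics
#'
#' For binary evaluation (with `positive` given): precision TP/(TP+FP),
#' recall TP/(TP+FN), F1 their harmonic mean, accuracy (TP+TN)/N; empty
#' denominators yield 0 by convention. For multiclass evaluation: accuracy
#' is the fraction correct; precision, recall and F1 are per-class values
#' averaged with class-support weights.
#'
#' @param predicted character/factor of predicted labels.
#' @param truth character/factor of true labels, same length.
#' @param positive the positive-class label for binary evaluation, or
#'   `NULL` for multiclass.
#' @return Named numeric: `accuracy`, `f1`, `precision`, `recall`.
#' @examples
#' evaluateMetrics(
#'   rep(c("A", "B"), c(4, 6)), rep(c("A", "B", "A", "B"), c(3, 1, 1, 5)),
#'   positive = "A"
#' )
#' @export
evaluateMetrics <- function(predicted, truth, positive = NULL) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0L)
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  f1of <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  if (!is.null(positive)) {
    tp <- sum(predicted == positive & truth == positive)
    fp <- sum(predicted == positive & truth != positive)
    fn <- sum(predicted != positive & truth == positive)
    tn <- sum(predicted != positive & truth != positive)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    c(
      accuracy = (tp + tn) / length(truth), f1 = f1of(prec, rec),
      precision = prec, recall = rec
    )
  } else {
    classes <- sort(unique(truth))
    support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
    per <- vapply(classes, function(cl) {
      tp <- sum(predicted == cl & truth == cl)
      fp <- sum(predicted == cl & truth != cl)
      fn <- sum(predicted != cl & truth == cl)
      prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
      c(prec, rec, f1of(prec, rec))
    }, numeric(3))
    w <- support / sum(support)
    c(
      accuracy = mean(predicted == truth),
      f1 = sum(per[3, ] * w),
      precision = sum(per[1, ] * w),
      recall = sum(per[2, ] * w),
      stats::setNames(per[3, ], paste0("f1_", classes))
    )
  }
}

## Stratified fold assignment: within each class, shuffled indices are
## dealt round-robin into folds. One assignment per repeat.
stratifiedFolds <- function(y, folds, repeats, seed) {
  y <- factor(y)
  if (min(table(y)) < folds)
    stop(
      "stratification error: every class needs at least ", folds,
      " cases for ", folds, "-fold cross-validation"
    )
  withr::with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      fold <- integer(length(y))
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
      fold
    })
  })
}

## Mean CV metrics of one (algorithm, hyper, feature subset) configuration.
crossValidate <- function(x, y, algorithm, hyper, positive = NULL,
                          folds = 5L, repeats = 10L, seed = 1L) {
  y <- factor(y)
  assign <- stratifiedFolds(y, folds, repeats, seed)
  acc <- NULL
  for (r in seq_along(assign)) {
    for (f in seq_len(folds)) {
      test <- assign[[r]] == f
      model <- fitModel(algorithm, x[!test, , drop = FALSE], y[!test],
        hyper,
        seed = seed + 1000L * r + f
      )
      p <- predictProbs(model, x[test, , drop = FALSE])
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      acc <- rbind(acc, evaluateMetrics(pred, y[test], positive = positive))
    }
  }
  colMeans(acc)
}

#' Tune and train one recognition model
#'
#' Randomised search over sampled hyperparameter configurations crossed
#' with feature-count prefixes of a relevance ranking, scored by the mean
#' F1 of a repeated stratified 5-fold cross-validation; the winning
#' configuration is refit on all data. Fully seeded: identical inputs and
#' seed give an identical selected specification and metrics.
#'
#' @param fs a normalised [EDAFeatureSet-class].
#' @param ranking a [FeatureRanking-class] over the table's features
#'   (typically the voted ranking for the matching target).
#' @param architecture `"BINARY"` (one-vs-rest for `positive`) or
#'   `"FOUR_CLASS"`.
#' @param positive quadrant treated as positive (required for binary).
#' @param algorithms subset of [algorithmNames()] to search.
#' @param nFeaturesGrid feature-count prefixes to try (default
#'   `c(5, 8, 10, 12, 15)`).
#' @param nConfigs sampled hyperparameter configurations per algorithm
#'   (default 50).
#' @param folds,repeats cross-validation folds (5) and repeats (10).
#' @param seed integer seed driving all randomness.
#' @return A list: `spec` (architecture, algorithm, nFeatures, hyper,
#'   seed), `model` (refit on all data), `report` (one-row data.frame with
#'   mean CV accuracy/f1/precision/recall), `searchReports` (one row per
#'   evaluated configuration).
#' @export
trainAndTune <- function(fs, ranking,
                         architecture = c("BINARY", "FOUR_CLASS"),
                         positive = NULL,
                         algorithms = algorithmNames(),
                         nFeaturesGrid = c(5, 8, 10, 12, 15),
                         nConfigs = 50L, folds = 5L, repeats = 10L,
                         seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot(isNormalized(fs))
  if (architecture == "BINARY") {
    stopifnot(!is.null(positive))
    y <- oneVsRestLabels(segmentLabels(fs), positive)
  } else {
    y <- segmentLabels(fs)
    positive <- NULL
  }
  x <- featureMatrix(fs)
  feats <- rankedFeatures(ranking)
  stopifnot(all(feats %in% colnames(x)))
  nFeaturesGrid <- nFeaturesGrid[nFeaturesGrid <= length(feats)]
  rows <- list()
  best <- NULL
  for (ai in seq_along(algorithms)) {
    alg <- algorithms[ai]
    hypers <- sampleHyperparameters(alg, nConfigs, seed + ai, p = min(nFeaturesGrid))
    for (nf in nFeaturesGrid) {
      sub <- x[, feats[seq_len(nf)], drop = FALSE]
      for (hi in seq_along(hypers)) {
        m <- crossValidate(sub, y, alg, hypers[[hi]],
          positive = positive,
          folds = folds, repeats = repeats, seed = seed
        )
        row <- data.frame(
          architecture = architecture, algorithm = alg, nFeatures = nf,
          accuracy = m["accuracy"], f1 = m["f1"],
          precision = m["precision"], recall = m["recall"],
          row.names = NULL
        )
        perClass <- m[grep("^f1_", names(m))]
        if (length(perClass) > 0L) row <- cbind(row, as.data.frame(as.list(perClass)))
        rows[[length(rows) + 1L]] <- row
        if (is.null(best) || m["f1"] > best$f1 + 1e-12 ||
          (abs(m["f1"] - best$f1) <= 1e-12 && m["accuracy"] > best$accuracy)) {
          best <- list(
            f1 = unname(m["f1"]), accuracy = unname(m["accuracy"]),
            algorithm = alg, nFeatures = nf, hyper = hypers[[hi]], row = row
          )
        }
      }
    }
  }
  sub <- x[, feats[seq_len(best$nFeatures)], drop = FALSE]
  model <- fitModel(best$algorithm, sub, factor(y), best$hyper, seed = seed)
  list(
    spec = list(
      architecture = architecture, positive = positive,
      algorithm = best$algorithm, nFeatures = best$nFeatures,
      hyper = best$hyper, seed = seed, folds = folds, repeats = repeats
    ),
    model = model,
    report = best$row,
    searchReports = do.call(rbind, rows)
  )
}

#' Select the best report by F1
#'
#' Argmax over F1; ties broken by accuracy, then algorithm name.
#'
#' @param reports a data.frame of evaluation reports (columns `f1`,
#'   `accuracy`, `algorithm`, ...), e.g. rbind-ed rows from
#'   [trainAndTune()].
#' @return The selected single-row data.frame.
#' @export
selectBest <- function(reports) {
  stopifnot(nrow(reports) > 0L)
  o <- order(-reports$f1, -reports$accuracy, reports$algorithm)
  reports[o[1L], , drop = FALSE]
}

#' Predict an emotion from a normalised feature vector
#'
#' With four binary models (a named list over the quadrants), each model
#' contributes the probability of its own quadrant; with a single
#' four-class model the class-probability vector is used directly. Flags
#' are raised where the probability reaches the threshold; order is Happy,
#' Sad, Aggressive, Relaxed.
#'
#' @param models either a named list of 4 binary `edaModel`s (names =
#'   quadrants) or one four-class `edaModel`.
#' @param x named numeric feature vector (or 1-row matrix), already
#'   transformed with the training scaler.
#' @param threshold classification threshold (default 0.5).
#' @return An [EmotionPrediction-class].
#' @export
predictEmotion <- function(models, x, threshold = 0.5) {
  if (any(x < -0.5 | x > 1.5))
    stop("feature vector does not look min-max normalised; apply the training scaler")
  qs <- quadrantLabels()
  if (inherits(models, "edaModel")) {
    p <- predictProbs(models, x)[1L, ]
    probs <- p[qs]
  } else {
    stopifnot(all(qs %in% names(models)))
    probs <- vapply(qs, function(q) {
      predictProbs(models[[q]], x)[1L, q]
    }, numeric(1))
  }
  EmotionPrediction(pmin(pmax(probs, 0), 1), threshold = threshold)
}
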