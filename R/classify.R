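## Grid-searched SVM / decision-tree / random-forest evaluation of the
## three feature sets with a per-subject stratified 80/20 split and 5-fold
## cross-validated grid search on the training partition. Standardization
## statistics come from the training partition only.

# stratified fold assignment
stratifiedFolds <- function(y, nFolds) {
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    folds[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  folds
}

fitClassifier <- function(classifier, X, y, params, seed) {
  set.seed(seed)
  switch(classifier,
    svm = e1071::svm(X, y, kernel = "radial", cost = params$cost,
                     gamma = params$gamma, scale = FALSE),
    dt = {
      df <- data.frame(y = y, X, check.names = FALSE)
      rpart::rpart(y ~ ., data = df, method = "class",
                   parms = list(split = if (params$criterion == "entropy")
                     "information" else "gini"),
                   control = rpart::rpart.control(
                     maxdepth = min(params$maxdepth, 30),  # rpart hard limit
                     minsplit = params$minsplit, cp = 0, xval = 0))
    },
    rf = randomForest::randomForest(X, y, ntree = params$ntree),
    stop("unknown classifier: ", classifier))
}

predictClassifier <- function(classifier, fit, X) {
  if (classifier == "dt")
    stats::predict(fit, data.frame(X, check.names = FALSE), type = "class")
  else
    stats::predict(fit, X)
}

#' Stratified split, cross-validated grid search and final fit
#'
#' Splits the table into a stratified 80/20 train/test partition, runs a
#' 5-fold cross-validated grid search over the classifier's grid on the 80%
#' partition, refits the best parameter combination on the full training
#' partition and reports train and test accuracy. Features are z-scored
#' with statistics estimated on the training partition only.
#'
#' @param ft A single subject's [FeatureTable-class].
#' @param classifier `"svm"`, `"dt"` or `"rf"`.
#' @param spec A [GridSearchSpec-class] (default [gridSearchSpec()]).
#' @param seed Integer seed controlling the split, folds and stochastic
#'   fits; the same seed reproduces the identical result.
#' @param nFolds Cross-validation folds (default 5).
#' @param testFraction Held-out fraction (default 0.2).
#' @return A list with elements `classifier`, `params` (chosen
#'   combination), `cvAccuracy`, `trainAccuracy`, `testAccuracy` (percent),
#'   `model`, `testIdx`, `center`, `scale`.
#' @export
splitAndTune <- function(ft, classifier = c("svm", "dt", "rf"),
                         spec = gridSearchSpec(), seed = 1L,
                         nFolds = 5L, testFraction = 0.2) {
  classifier <- match.arg(classifier)
  stopifnot(is(ft, "FeatureTable"), is(spec, "GridSearchSpec"))
  X <- featureMatrix(ft)
  y <- factor(epochLevels(ft))
  set.seed(seed)
  testIdx <- stratifiedSplit(y, testFraction)
  trainIdx <- setdiff(seq_along(y), testIdx)
  if (min(table(y[trainIdx])) < nFolds)
    stop("fewer than ", nFolds, " training samples in some class")

  mu <- colMeans(X[trainIdx, , drop = FALSE])
  sd <- apply(X[trainIdx, , drop = FALSE], 2L, stats::sd)
  sd[sd == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sd, "/")
  Xtr <- Xs[trainIdx, , drop = FALSE]
  ytr <- y[trainIdx]

  grid <- slot(spec, classifier)
  folds <- stratifiedFolds(ytr, nFolds)
  cvAcc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    acc <- numeric(nFolds)
    for (f in seq_len(nFolds)) {
      hold <- folds == f
      fit <- fitClassifier(classifier, Xtr[!hold, , drop = FALSE],
                           ytr[!hold], params, seed + f)
      pred <- predictClassifier(classifier, fit, Xtr[hold, , drop = FALSE])
      acc[f] <- mean(pred == ytr[hold])
    }
    cvAcc[gi] <- mean(acc)
  }
  best <- as.list(grid[which.max(cvAcc), , drop = FALSE])
  fit <- fitClassifier(classifier, Xtr, ytr, best, seed)
  predTr <- predictClassifier(classifier, fit, Xtr)
  predTe <- predictClassifier(classifier, fit, Xs[testIdx, , drop = FALSE])
  list(classifier = classifier, params = best,
       cvAccuracy = 100 * max(cvAcc),
       trainAccuracy = 100 * mean(predTr == ytr),
       testAccuracy = 100 * mean(predTe == y[testIdx]),
       model = fit, testIdx = testIdx, center = mu, scale = sd)
}

#' Evaluate all feature sets with all classifiers
#'
#' For every feature set (`only_eeg`, `only_fnirs`, `fused`) and classifier
#' (`svm`, `dt`, `rf`), fits one model per subject via [splitAndTune()] and
#' collects per-subject train and test accuracies.
#'
#' @param perSubjectTables Named list, one entry per subject, each a named
#'   list of the three [FeatureTable-class] objects as returned by
#'   [assembleFeatureSets()].
#' @param spec A [GridSearchSpec-class].
#' @param seed Integer base seed; each (subject, set, classifier) cell gets
#'   a deterministic derived seed.
#' @param featureSets,classifiers Subsets to evaluate (defaults: all).
#' @return A named list of [EvaluationResult-class] objects
#'   (`<set>_<classifier>`).
#' @seealso [summaryTable()], [accuracyAnova()]
#' @export
evaluateAll <- function(perSubjectTables, spec = gridSearchSpec(), seed = 1L,
                        featureSets = c("only_eeg", "only_fnirs", "fused"),
                        classifiers = c("svm", "dt", "rf")) {
  subjects <- names(perSubjectTables)
  if (is.null(subjects))
    subjects <- sprintf("S%02d", seq_along(perSubjectTables))
  for (tabs in perSubjectTables)
    if (!all(featureSets %in% names(tabs)))
      stop("every subject needs all requested feature sets")
  out <- list()
  for (fs in featureSets) {
    for (cl in classifiers) {
      testAcc <- trainAcc <- stats::setNames(numeric(length(subjects)), subjects)
      params <- list()
      for (si in seq_along(subjects)) {
        cellSeed <- derivedSeed(seed, paste(subjects[si], fs, cl), 7L)
        r <- splitAndTune(perSubjectTables[[si]][[fs]], cl, spec, cellSeed)
        testAcc[si] <- r$testAccuracy
        trainAcc[si] <- r$trainAccuracy
        params[[subjects[si]]] <- r$params
      }
      out[[paste(fs, cl, sep = "_")]] <-
        new("EvaluationResult", featureSet = fs, classifier = cl,
            testAccuracy = testAcc, trainAccuracy = trainAcc,
            params = params)
    }
  }
  out
}

#' Summarize evaluation results as a feature-set x classifier table
#'
#' @param results List of [EvaluationResult-class] from [evaluateAll()].
#' @return A data.frame with one row per (feature set, classifier) and
#'   min/mean/max/sd of the per-subject test and train accuracies.
#' @export
summaryTable <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    te <- testAccuracy(r); tr <- trainAccuracy(r)
    data.frame(featureSet = r@featureSet, classifier = r@classifier,
               min = min(te), mean = mean(te), max = max(te),
               sd = stats::sd(te),
               trainMin = min(tr), trainMean = mean(tr),
               trainMax = max(tr), trainSd = stats::sd(tr),
               row.names = NULL)
  }))
}

#' Two-way ANOVA of accuracy on feature set and classifier
#'
#' Per-subject test accuracies are modeled as
#' `accuracy ~ featureSet * classifier`; returns main effects, interaction
#' and residual rows with F and p values.
#'
#' @param results List of [EvaluationResult-class] from [evaluateAll()].
#' @return A data.frame with columns `term`, `df`, `sumsq`, `meansq`,
#'   `F`, `p`.
#' @export
accuracyAnova <- function(results) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(subject = names(testAccuracy(r)),
               featureSet = r@featureSet, classifier = r@classifier,
               accuracy = as.numeric(testAccuracy(r)), row.names = NULL)))
  if (length(unique(df$subject)) < 2)
    stop("at least 2 subjects are required")
  fit <- stats::aov(accuracy ~ featureSet * classifier, data = df)
  tab <- summary(fit)[[1]]
  data.frame(term = trimws(rownames(tab)), df = tab[["Df"]],
             sumsq = tab[["Sum Sq"]], meansq = tab[["Mean Sq"]],
             F = tab[["F value"]], p = tab[["Pr(>F)"]], row.names = NULL)
}
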