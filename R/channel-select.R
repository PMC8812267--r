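## Channel-importance ranking: per-subject linear SVM-RFE over the
## per-channel band-power features, cross-subject aggregation of the top-k
## sets into feature and channel weights, the accuracy-vs-channel-count
## curve and the plateau-based montage selection.

# squared linear-SVM weights per feature, summed over all one-vs-one class
# pairs; X must already be standardized
pairwiseSVMWeights <- function(X, y, cost = 1) {
  lev <- levels(y)
  w2 <- numeric(ncol(X))
  for (i in seq_along(lev)[-length(lev)]) {
    for (j in (i + 1):length(lev)) {
      sel <- y %in% lev[c(i, j)]
      fit <- e1071::svm(X[sel, , drop = FALSE], droplevels(y[sel]),
                        kernel = "linear", cost = cost, scale = FALSE)
      w <- as.numeric(t(fit$coefs) %*% fit$SV)
      w2 <- w2 + w^2
    }
  }
  w2
}

#' Per-subject SVM-RFE top-k band-power features
#'
#' Restricts the table to the per-channel band-power features
#' (`<channel>_<band>_psd`), then iteratively trains linear-kernel SVMs and
#' eliminates the lowest-weight 10% of the remaining features until `k`
#' remain. Feature weights are squared linear weights summed over the
#' one-vs-one class pairs.
#'
#' @param ft A single subject's [FeatureTable-class] with at least 2
#'   classes.
#' @param k Number of features to keep (default 100).
#' @param step Fraction of remaining features eliminated per iteration
#'   (default 0.1).
#' @param cost Linear SVM cost (default 1).
#' @return Character vector of `min(k, n_features)` feature names.
#' @export
rfeTopFeatures <- function(ft, k = 100, step = 0.1, cost = 1) {
  stopifnot(is(ft, "FeatureTable"))
  nm <- rownames(ft)[grepl("_psd$", rownames(ft))]
  if (!length(nm)) stop("no per-channel band-power features in the table")
  X <- featureMatrix(ft)[, nm, drop = FALSE]
  y <- factor(epochLevels(ft))
  if (nlevels(y) < 2) stop("at least 2 classes are required for RFE")
  X <- scale(X)
  X[, attr(X, "scaled:scale") == 0] <- 0
  remaining <- nm
  while (length(remaining) > k) {
    w2 <- pairwiseSVMWeights(X[, remaining, drop = FALSE], y, cost)
    nDrop <- min(max(1L, floor(step * length(remaining))),
                 length(remaining) - k)
    remaining <- remaining[order(w2)][-seq_len(nDrop)]
  }
  remaining
}

#' Aggregate per-subject feature sets into channel importance
#'
#' A feature's importance weight counts the subjects whose top-k set
#' contains it; a channel's weight is the sum of its four band-feature
#' weights. Channels are ranked by weight, descending; ties are broken by
#' montage order, so the result is invariant to the order of subjects.
#'
#' @param perSubjectSets List of character vectors from [rfeTopFeatures()],
#'   one per subject.
#' @param channels Scalp channel labels to score (the universe of the
#'   ranking).
#' @param bands Band definitions (default [bandDefinitions()]).
#' @return A [ChannelImportanceReport-class].
#' @export
aggregateImportance <- function(perSubjectSets, channels,
                                bands = bandDefinitions()) {
  universe <- as.vector(outer(channels, bands$name,
                              function(ch, b) paste0(ch, "_", b, "_psd")))
  for (s in perSubjectSets) {
    unknown <- setdiff(s, universe)
    if (length(unknown))
      stop("unknown feature label(s): ", paste(utils::head(unknown, 3), collapse = ", "))
  }
  fw <- vapply(universe, function(f)
    sum(vapply(perSubjectSets, function(s) f %in% s, logical(1))),
    integer(1))
  cw <- vapply(channels, function(ch)
    sum(fw[paste0(ch, "_", bands$name, "_psd")]), integer(1))
  ranking <- channels[order(-cw, seq_along(channels))]
  new("ChannelImportanceReport",
      featureWeights = fw, channelWeights = cw, ranking = ranking,
      nSubjects = length(perSubjectSets))
}

# stratified train/test split indices
stratifiedSplit <- function(y, testFraction = 0.2) {
  testIdx <- integer()
  for (lv in levels(y)) {
    idx <- which(y == lv)
    nTest <- max(1L, round(testFraction * length(idx)))
    testIdx <- c(testIdx, sample(idx, nTest))
  }
  sort(testIdx)
}

#' Accuracy as a function of channel count
#'
#' For n = 1 ... length(ranking), trains one RBF SVM per subject on the
#' band-power features of the top-n ranked channels (stratified 80/20
#' split) and records the test accuracy, returning the mean and SD across
#' subjects per n.
#'
#' @param tables List of per-subject [FeatureTable-class] objects holding
#'   the per-channel band-power features.
#' @param ranking Channel labels in importance order (covers all scored
#'   channels).
#' @param seed Integer seed for the per-subject splits.
#' @param cost,gamma RBF SVM parameters; `gamma = NULL` uses 1/n_features.
#' @param maxChannels Upper limit on n (default: full ranking).
#' @return A data.frame with columns `nChannels`, `mean`, `sd` (accuracy
#'   in percent).
#' @export
incrementalAccuracyCurve <- function(tables, ranking, seed = 1L,
                                     cost = 1, gamma = NULL,
                                     maxChannels = length(ranking)) {
  if (!length(ranking)) stop("empty ranking")
  perN <- matrix(NA_real_, nrow = maxChannels, ncol = length(tables))
  for (si in seq_along(tables)) {
    ft <- tables[[si]]
    X <- featureMatrix(ft)
    y <- factor(epochLevels(ft))
    set.seed(derivedSeed(seed, as.character(subjectID(ft))[1], 5L))
    testIdx <- stratifiedSplit(y)
    for (n in seq_len(maxChannels)) {
      cols <- rownames(ft)[grepl("_psd$", rownames(ft)) &
                             sub("_(theta|alpha|beta1|beta2)_psd$", "",
                                 rownames(ft)) %in% ranking[seq_len(n)]]
      Xs <- X[, cols, drop = FALSE]
      mu <- colMeans(Xs[-testIdx, , drop = FALSE])
      sd <- apply(Xs[-testIdx, , drop = FALSE], 2L, stats::sd)
      sd[sd == 0] <- 1
      Xs <- sweep(sweep(Xs, 2L, mu), 2L, sd, "/")
      g <- if (is.null(gamma)) 1 / ncol(Xs) else gamma
      fit <- e1071::svm(Xs[-testIdx, , drop = FALSE], y[-testIdx],
                        kernel = "radial", cost = cost, gamma = g,
                        scale = FALSE)
      pred <- stats::predict(fit, Xs[testIdx, , drop = FALSE])
      perN[n, si] <- 100 * mean(pred == y[testIdx])
    }
  }
  data.frame(nChannels = seq_len(maxChannels),
             mean = rowMeans(perN),
             sd = apply(perN, 1L, stats::sd))
}

#' Select the reduced montage from the accuracy curve
#'
#' Chooses the smallest channel count n at which the 3-point moving average
#' of the accuracy gain falls below `plateau` percentage points, and returns
#' the top-n channels of the ranking. With `plateau <= 0` the argmax of the
#' mean accuracy is used instead. If the curve never plateaus the full
#' ranking is returned with a message.
#'
#' @param report A [ChannelImportanceReport-class].
#' @param curve The data.frame from [incrementalAccuracyCurve()].
#' @param plateau Gain threshold in accuracy points (default 0.5).
#' @param window Moving-average window over the gains (default 3).
#' @return Character vector of selected channel labels.
#' @export
selectMontage <- function(report, curve, plateau = 0.5, window = 3) {
  ranking <- channelRanking(report)
  acc <- curve$mean
  if (length(acc) < 2) return(ranking[seq_len(length(acc))])
  if (plateau <= 0) return(ranking[seq_len(which.max(acc))])
  gains <- diff(acc)
  ma <- vapply(seq_along(gains), function(i)
    mean(gains[i:min(i + window - 1, length(gains))]), numeric(1))
  hit <- which(ma < plateau)
  if (!length(hit)) {
    message("accuracy curve never plateaus; returning the full montage")
    return(ranking[seq_along(acc)])
  }
  ranking[seq_len(hit[1])]
}
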