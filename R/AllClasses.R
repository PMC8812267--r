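#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------- SessionConfig

#' SessionConfig: parameters of the synthetic MATB-like session generator
#'
#' Holds every constant that governs a synthetic hybrid EEG-fNIRS session.
#' A session consists of `nBlocks` blocks; each block contains one
#' `blockDuration`-second task segment per difficulty level (the four
#' segments appear in a per-subject random order), so the default
#' configuration yields 4 blocks x 4 levels x 180 s = 48 min of signal and
#' 16 behavioral records per subject.
#'
#' @slot nBlocks integer, number of blocks (default 4).
#' @slot blockDuration numeric, duration in seconds of one difficulty
#'   segment (default 180; must be a multiple of the 3-s epoch length).
#' @slot levels integer vector of difficulty labels, ascending
#'   (default `c(1, 3, 5, 7)`).
#' @slot eegRate numeric, EEG sampling rate in Hz (default 500).
#' @slot fnirsRate numeric, fNIRS sampling rate in Hz (default 50).
#' @slot montage character, EEG electrode labels including the mastoids
#'   M1 and M2 (default [defaultMontage()], 64 labels).
#' @slot ocularLabel character, label of the auxiliary ocular channel
#'   recorded alongside the montage (default `"VEOG"`).
#' @slot effectSize numeric >= 0, dimensionless scale of all
#'   difficulty-dependent modulation (default 1; 0 produces null data).
#' @slot noiseSd numeric >= 0, scale of all stochastic components: the pink
#'   background EEG noise SD in microvolts, and (via fixed multipliers) the
#'   fNIRS sensor noise and behavioral-record noise (default 1).
#' @slot modulation named list, one entry per band name, each
#'   `list(channels =, slope =)`: the channels whose band amplitude is
#'   modulated by difficulty and the fractional amplitude change between the
#'   lowest and highest level (signed; negative = decreasing). Defaults:
#'   theta +0.5 on frontal channels, alpha -0.4 and beta1/beta2 +0.5 on
#'   parieto-occipital channels.
#' @slot eegBaseAmp named numeric, baseline oscillation amplitude per band in
#'   microvolts (default theta 4, alpha 6, beta1 2.5, beta2 2).
#' @slot fnirsBaseline named numeric, task-plateau concentration change at
#'   the lowest difficulty, micromol/L (default O2Hb 0.5, HHb -0.2).
#' @slot fnirsSlope named numeric, additional plateau change between lowest
#'   and highest difficulty at `effectSize = 1` (default O2Hb +0.8,
#'   HHb -0.3), so O2Hb increases and HHb decreases with difficulty.
#' @slot ocularRate numeric, expected blink-like transients per second on
#'   the ocular channel (default 0.25; 0 disables artifacts).
#' @slot ocularAmp numeric, ocular transient amplitude in microvolts
#'   (default 100).
#' @slot seed integer, base random seed; together with the subject ID it
#'   fully determines a session.
#'
#' @seealso [sessionConfig()], [generateSession()], [generateBehavioral()]
#' @export
setClass("SessionConfig", representation(
  nBlocks = "integer",
  blockDuration = "numeric",
  levels = "integer",
  eegRate = "numeric",
  fnirsRate = "numeric",
  montage = "character",
  ocularLabel = "character",
  effectSize = "numeric",
  noiseSd = "numeric",
  modulation = "list",
  eegBaseAmp = "numeric",
  fnirsBaseline = "numeric",
  fnirsSlope = "numeric",
  ocularRate = "numeric",
  ocularAmp = "numeric",
  seed = "integer"
))

setValidity("SessionConfig", function(object) {
  msg <- character()
  if (object@nBlocks < 1L) msg <- c(msg, "nBlocks must be >= 1")
  if (object@blockDuration <= 0) msg <- c(msg, "blockDuration must be > 0")
  if (abs(object@blockDuration %% 3) > 1e-9)
    msg <- c(msg, "blockDuration must be a multiple of the 3-s epoch length")
  if (is.unsorted(object@levels, strictly = TRUE))
    msg <- c(msg, "levels must be strictly ascending")
  if (object@eegRate <= 60)
    msg <- c(msg, "eegRate must exceed twice the highest synthesized frequency (30 Hz)")
  if (object@fnirsRate <= 0) msg <- c(msg, "fnirsRate must be > 0")
  if (anyDuplicated(object@montage)) msg <- c(msg, "montage labels must be unique")
  if (!all(c("M1", "M2") %in% object@montage))
    msg <- c(msg, "montage must contain the mastoid labels M1 and M2")
  if (object@ocularLabel %in% object@montage)
    msg <- c(msg, "ocularLabel must not be part of the montage")
  if (length(object@effectSize) != 1L || is.na(object@effectSize) ||
      object@effectSize < 0)
    msg <- c(msg, "effectSize must be a single non-negative number")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  bad <- setdiff(names(object@modulation), bandDefinitions()$name)
  if (length(bad))
    msg <- c(msg, paste("unknown modulation band(s):", paste(bad, collapse = ", ")))
  for (b in names(object@modulation)) {
    m <- object@modulation[[b]]
    if (!is.list(m) || !all(c("channels", "slope") %in% names(m)))
      msg <- c(msg, sprintf("modulation$%s must be list(channels=, slope=)", b))
    else if (length(setdiff(m$channels, scalpChannels(object@montage))))
      msg <- c(msg, sprintf("modulation$%s references channels outside the scalp montage", b))
  }
  if (!all(bandDefinitions()$name %in% names(object@eegBaseAmp)))
    msg <- c(msg, "eegBaseAmp must name all four bands")
  if (length(msg)) msg else TRUE
})

#' Create a session generator configuration
#'
#' Constructor for [SessionConfig-class] with the study's default
#' conditions: 4 blocks of four 3-min segments at difficulty levels
#' 1, 3, 5, 7, 64-channel EEG at 500 Hz, two-site prefrontal fNIRS at 50 Hz,
#' frontal theta increasing and occipital alpha decreasing / beta increasing
#' with difficulty, O2Hb increasing and HHb decreasing with difficulty.
#'
#' @param nBlocks,blockDuration,levels,eegRate,fnirsRate,montage,ocularLabel
#'   See [SessionConfig-class].
#' @param effectSize,noiseSd,modulation,eegBaseAmp,fnirsBaseline,fnirsSlope
#'   See [SessionConfig-class].
#' @param ocularRate,ocularAmp,seed See [SessionConfig-class].
#' @return A validated [SessionConfig-class] object.
#' @examples
#' cfg <- sessionConfig(nBlocks = 1, blockDuration = 30, seed = 1)
#' cfg
#' @export
sessionConfig <- function(nBlocks = 4L,
                          blockDuration = 180,
                          levels = c(1L, 3L, 5L, 7L),
                          eegRate = 500,
                          fnirsRate = 50,
                          montage = defaultMontage(),
                          ocularLabel = "VEOG",
                          effectSize = 1,
                          noiseSd = 1,
                          modulation = NULL,
                          eegBaseAmp = c(theta = 4, alpha = 6, beta1 = 2.5, beta2 = 2),
                          fnirsBaseline = c(O2Hb = 0.5, HHb = -0.2),
                          fnirsSlope = c(O2Hb = 0.8, HHb = -0.3),
                          ocularRate = 0.25,
                          ocularAmp = 100,
                          seed = 20220202L) {
  if (is.null(modulation)) {
    frontal <- intersect(
      c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8", "F3", "F1", "Fz", "F2", "F4"),
      montage)
    occipital <- intersect(
      c("O1", "Oz", "O2", "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
        "P7", "P5", "P3", "Pz", "P4", "P6", "P8"),
      montage)
    modulation <- list(
      theta = list(channels = frontal, slope = 0.5),
      alpha = list(channels = occipital, slope = -0.4),
      beta1 = list(channels = occipital, slope = 0.5),
      beta2 = list(channels = occipital, slope = 0.5)
    )
  }
  new("SessionConfig",
      nBlocks = as.integer(nBlocks), blockDuration = blockDuration,
      levels = as.integer(levels), eegRate = eegRate, fnirsRate = fnirsRate,
      montage = montage, ocularLabel = ocularLabel,
      effectSize = effectSize, noiseSd = noiseSd, modulation = modulation,
      eegBaseAmp = eegBaseAmp, fnirsBaseline = fnirsBaseline,
      fnirsSlope = fnirsSlope, ocularRate = ocularRate, ocularAmp = ocularAmp,
      seed = as.integer(seed))
}

setMethod("show", "SessionConfig", function(object) {
  cat("SessionConfig:",
      sprintf("%d block(s) x %d levels x %gs", object@nBlocks,
              length(object@levels), object@blockDuration), "\n")
  cat("  levels:", paste(object@levels, collapse = ", "),
      "| EEG", length(object@montage), "ch @", object@eegRate, "Hz",
      "| fNIRS @", object@fnirsRate, "Hz\n")
  cat("  effectSize:", object@effectSize, " noiseSd:", object@noiseSd,
      " seed:", object@seed, "\n")
})

## ------------------------------------------------------------------ RawSession

#' RawSession: one subject's synchronized EEG + fNIRS recording
#'
#' Raw multichannel signals for one synthetic (or imported) session,
#' together with the event markers (one per difficulty segment) and, for
#' generated sessions, the ground-truth modulation parameters used, retained
#' for recovery tests.
#'
#' @slot subjectID character.
#' @slot eeg numeric matrix, channels x samples, microvolts; rownames are
#'   channel labels (montage plus the auxiliary ocular channel).
#' @slot eegRate numeric, Hz.
#' @slot fnirs numeric matrix, 4 x samples, micromol/L; rownames
#'   `left_O2Hb`, `left_HHb`, `right_O2Hb`, `right_HHb`.
#' @slot fnirsRate numeric, Hz.
#' @slot events data.frame with columns `onset` (s), `level`, `block`; one
#'   row per difficulty segment.
#' @slot blockDuration numeric, segment duration in seconds.
#' @slot montage character, EEG montage labels (excluding the ocular channel).
#' @slot ocularLabel character.
#' @slot groundTruth list of generator internals (empty for imported data).
#' @seealso [generateSession()]
#' @export
setClass("RawSession", representation(
  subjectID = "character",
  eeg = "matrix",
  eegRate = "numeric",
  fnirs = "matrix",
  fnirsRate = "numeric",
  events = "data.frame",
  blockDuration = "numeric",
  montage = "character",
  ocularLabel = "character",
  groundTruth = "list"
))

setValidity("RawSession", function(object) {
  msg <- character()
  if (is.null(rownames(object@eeg))) msg <- c(msg, "eeg must have channel rownames")
  if (!all(object@montage %in% rownames(object@eeg)))
    msg <- c(msg, "all montage channels must be rows of eeg")
  spanE <- ncol(object@eeg) / object@eegRate
  spanF <- ncol(object@fnirs) / object@fnirsRate
  if (abs(spanE - spanF) > 1 / min(object@eegRate, object@fnirsRate) + 1e-9)
    msg <- c(msg, "eeg and fnirs must cover the same wall-clock span")
  if (nrow(object@events)) {
    if (!all(c("onset", "level", "block") %in% names(object@events)))
      msg <- c(msg, "events needs columns onset, level, block")
    else if (any(object@events$onset + 3 > spanE + 1e-9))
      msg <- c(msg, "every event onset + 3 s must fit inside the recording")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RawSession", function(object) {
  cat("RawSession", object@subjectID, "\n")
  cat(sprintf("  EEG: %d ch x %d samples @ %g Hz (%.0f s)\n",
              nrow(object@eeg), ncol(object@eeg), object@eegRate,
              ncol(object@eeg) / object@eegRate))
  cat(sprintf("  fNIRS: %d traces x %d samples @ %g Hz\n",
              nrow(object@fnirs), ncol(object@fnirs), object@fnirsRate))
  cat(sprintf("  events: %d segments, levels {%s}\n", nrow(object@events),
              paste(sort(unique(object@events$level)), collapse = ",")))
})

setMethod("subjectID", "RawSession", function(x) x@subjectID)
setMethod("montage", "RawSession", function(x) x@montage)
setMethod("eegData", "RawSession", function(x) x@eeg)
setMethod("fnirsData", "RawSession", function(x) x@fnirs)
setMethod("sessionEvents", "RawSession", function(x) x@events)
setMethod("groundTruth", "RawSession", function(x) x@groundTruth)

## -------------------------------------------------------------------- EpochSet

#' EpochSet: fixed-length labeled analysis windows
#'
#' A collection of 3-s windows cut from a [RawSession-class], each labeled
#' with its segment's difficulty level. EEG epoch sets hold scalp channels
#' only (no mastoids, no ocular channel); fNIRS epoch sets hold the four
#' chromophore traces.
#'
#' @slot data numeric array, channels x samples x epochs; dimnames hold the
#'   channel labels.
#' @slot info data.frame, one row per epoch: `subject`, `level`, `block`,
#'   `onset` (s).
#' @slot rate numeric, sampling rate in Hz.
#' @slot modality character, `"eeg"` or `"fnirs"`.
#' @seealso [epochEEG()], [epochFNIRS()]
#' @export
setClass("EpochSet", representation(
  data = "array",
  info = "data.frame",
  rate = "numeric",
  modality = "character"
))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be channels x samples x epochs")
  else if (d[3] != nrow(object@info))
    msg <- c(msg, "info must have one row per epoch")
  if (!all(c("subject", "level", "block", "onset") %in% names(object@info)))
    msg <- c(msg, "info needs columns subject, level, block, onset")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet (%s): %d epochs x %d channels x %d samples @ %g Hz\n",
              object@modality, d[3], d[1], d[2], object@rate))
  if (d[3]) {
    tab <- table(object@info$level)
    cat("  per level:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  }
})

setMethod("epochData", "EpochSet", function(x) x@data)
setMethod("epochInfo", "EpochSet", function(x) x@info)
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[3])
setMethod("samplingRate", "EpochSet", function(x) x@rate)
setMethod("epochLevels", "EpochSet", function(x) x@info$level)

## ---------------------------------------------------------------- FeatureTable

#' FeatureTable: epochs x named features with difficulty labels
#'
#' The unit all downstream stages consume. Extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with features as rows and epochs as columns; `colData` carries `subject`,
#' `level`, `block` and `onset` per epoch. Feature names follow the schemes
#' `<channel>_<band>_psd`, `<a>-<b>_<band>_diff`, `<site>_<chromophore>_<stat>`
#' and `nvc_<site>_<chromophore>`, which keeps the unimodal and fused sets
#' disjoint by construction.
#'
#' @seealso [featureTable()], [assembleFeatureSets()]
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (anyDuplicated(rownames(object))) msg <- c(msg, "feature names must be unique")
  if (!all(c("subject", "level") %in% names(colData(object))))
    msg <- c(msg, "colData needs subject and level")
  if (length(SummarizedExperiment::assays(object)) &&
      anyNA(assay(object)))
    msg <- c(msg, "feature values must not be missing")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix, features x epochs, with unique rownames.
#' @param info data.frame with one row per epoch; must contain `subject` and
#'   `level` (plus optionally `block`, `onset`).
#' @return A [FeatureTable-class].
#' @export
featureTable <- function(values, info) {
  stopifnot(is.matrix(values), nrow(info) == ncol(values))
  se <- SummarizedExperiment(assays = list(features = values),
                             colData = DataFrame(info))
  new("FeatureTable", se)
}

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d epochs x %d features\n",
              ncol(object), nrow(object)))
  if (ncol(object)) {
    tab <- table(colData(object)$level)
    cat("  subjects:", paste(unique(colData(object)$subject), collapse = ", "), "\n")
    cat("  per level:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  }
})

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) t(assay(x, "features")))

setMethod("epochLevels", "FeatureTable", function(x) colData(x)$level)
setMethod("epochInfo", "FeatureTable", function(x) as.data.frame(colData(x)))
setMethod("subjectID", "FeatureTable", function(x) unique(colData(x)$subject))

## --------------------------------------------------- ChannelImportanceReport

#' ChannelImportanceReport: cross-subject channel-importance weights
#'
#' A feature's importance weight is the number of subjects whose per-subject
#' SVM-RFE top-k feature set contains it; a channel's weight is the sum of
#' its four band-feature weights. The ranking sorts channels by weight,
#' descending, with ties broken by montage order.
#'
#' @slot featureWeights named integer, per `<channel>_<band>_psd` feature,
#'   in `[0, nSubjects]`.
#' @slot channelWeights named integer, per channel, in `[0, 4 * nSubjects]`.
#' @slot ranking character, channels sorted by weight descending.
#' @slot nSubjects integer.
#' @seealso [aggregateImportance()]
#' @export
setClass("ChannelImportanceReport", representation(
  featureWeights = "integer",
  channelWeights = "integer",
  ranking = "character",
  nSubjects = "integer"
))

setValidity("ChannelImportanceReport", function(object) {
  msg <- character()
  if (any(object@featureWeights < 0L) ||
      any(object@featureWeights > object@nSubjects))
    msg <- c(msg, "feature weights must lie in [0, nSubjects]")
  if (any(object@channelWeights < 0L) ||
      any(object@channelWeights > 4L * object@nSubjects))
    msg <- c(msg, "channel weights must lie in [0, 4 * nSubjects]")
  if (!setequal(object@ranking, names(object@channelWeights)))
    msg <- c(msg, "ranking must be a permutation of the scored channels")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChannelImportanceReport", function(object) {
  cat(sprintf("ChannelImportanceReport: %d channels, %d subjects\n",
              length(object@channelWeights), object@nSubjects))
  top <- utils::head(object@ranking, 10)
  cat("  top channels:", paste(top, collapse = ", "), "\n")
})

setMethod("featureWeights", "ChannelImportanceReport", function(x) x@featureWeights)
setMethod("channelWeights", "ChannelImportanceReport", function(x) x@channelWeights)
setMethod("channelRanking", "ChannelImportanceReport", function(x) x@ranking)

## ------------------------------------------------------------- GridSearchSpec

#' GridSearchSpec: hyperparameter grids for the three classifiers
#'
#' Default grids: SVM (RBF kernel) cost in
#' \{0.0001, 0.001, 0.01, 0.1, 1, 10, 20, 30\} crossed with gamma in
#' \{0.1, 0.2, 0.25, 0.4, 0.8, 1.6, 3.2, 6.4\}; decision tree split
#' criterion \{entropy, gini\} x max depth \{10, 30, 60, 100\} x minimum
#' split size \{2, 5, 10, 15\}; random forest \{100, 200, 500\} trees.
#'
#' @slot svm data.frame grid with columns `cost`, `gamma`.
#' @slot dt data.frame grid with columns `criterion`, `maxdepth`, `minsplit`.
#' @slot rf data.frame grid with column `ntree`.
#' @seealso [gridSearchSpec()], [splitAndTune()]
#' @export
setClass("GridSearchSpec", representation(
  svm = "data.frame", dt = "data.frame", rf = "data.frame"
))

#' Build a classifier grid-search specification
#'
#' @param svmCost,svmGamma numeric vectors for the RBF SVM grid.
#' @param dtCriterion character vector of split criteria.
#' @param dtMaxDepth,dtMinSplit numeric vectors for the decision tree grid.
#' @param rfTrees numeric vector of forest sizes.
#' @return A [GridSearchSpec-class].
#' @export
gridSearchSpec <- function(svmCost = c(0.0001, 0.001, 0.01, 0.1, 1, 10, 20, 30),
                           svmGamma = c(0.1, 0.2, 0.25, 0.4, 0.8, 1.6, 3.2, 6.4),
                           dtCriterion = c("entropy", "gini"),
                           dtMaxDepth = c(10, 30, 60, 100),
                           dtMinSplit = c(2, 5, 10, 15),
                           rfTrees = c(100, 200, 500)) {
  new("GridSearchSpec",
      svm = expand.grid(cost = svmCost, gamma = svmGamma,
                        KEEP.OUT.ATTRS = FALSE),
      dt = expand.grid(criterion = dtCriterion, maxdepth = dtMaxDepth,
                       minsplit = dtMinSplit, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE),
      rf = data.frame(ntree = rfTrees))
}

setMethod("show", "GridSearchSpec", function(object) {
  cat(sprintf("GridSearchSpec: svm %d combos, dt %d, rf %d\n",
              nrow(object@svm), nrow(object@dt), nrow(object@rf)))
})

## ----------------------------------------------------------- EvaluationResult

#' EvaluationResult: per-subject accuracies for one (feature set, classifier)
#'
#' @slot featureSet character, one of `only_eeg`, `only_fnirs`, `fused`.
#' @slot classifier character, one of `svm`, `dt`, `rf`.
#' @slot testAccuracy named numeric, percent, one entry per subject.
#' @slot trainAccuracy named numeric, percent.
#' @slot params list of chosen hyperparameters per subject.
#' @seealso [evaluateAll()], [summaryTable()]
#' @export
setClass("EvaluationResult", representation(
  featureSet = "character",
  classifier = "character",
  testAccuracy = "numeric",
  trainAccuracy = "numeric",
  params = "list"
))

setValidity("EvaluationResult", function(object) {
  msg <- character()
  acc <- c(object@testAccuracy, object@trainAccuracy)
  if (length(acc) && (any(acc < 0) || any(acc > 100)))
    msg <- c(msg, "accuracies must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvaluationResult", function(object) {
  s <- c(min = min(object@testAccuracy), mean = mean(object@testAccuracy),
         max = max(object@testAccuracy), sd = stats::sd(object@testAccuracy))
  cat(sprintf("EvaluationResult %s / %s (n=%d subjects)\n",
              object@featureSet, object@classifier, length(object@testAccuracy)))
  cat(sprintf("  test acc: min %.2f mean %.2f max %.2f sd %.2f\n",
              s[1], s[2], s[3], s[4]))
})

setMethod("testAccuracy", "EvaluationResult", function(x) x@testAccuracy)
setMethod("trainAccuracy", "EvaluationResult", function(x) x@trainAccuracy)
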