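## End-to-end pipeline: generate -> preprocess -> features -> (optional
## channel selection) -> classification -> statistical reports, with a JSON
## run manifest recording configuration, seeds and output checksums.

# per-subject feature extraction from a raw session
extractSubjectFeatures <- function(session, stride = 3,
                                   montageMode = "optimized",
                                   channels = optimizedMontage(),
                                   pairs = defaultChannelPairs(),
                                   nvcChannel = "AF3",
                                   removeOutliers = TRUE) {
  eegEp <- preprocessEEG(session, stride = stride)
  fnirsEp <- preprocessFNIRS(session, stride = stride)
  eegFT <- eegFeatures(eegEp, pairs = pairs)
  fnirsFT <- fnirsStatFeatures(fnirsEp)
  nvcFT <- nvcFeatures(eegEp, fnirsEp, channel = nvcChannel)
  sets <- assembleFeatureSets(eegFT, fnirsFT, nvcFT,
                              montageMode = montageMode, channels = channels)
  if (removeOutliers) sets <- lapply(sets, zscoreOutlierRemoval)
  c(sets, list(eeg_full = eegFT, fnirs_epochs = fnirsEp))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates `nSubjects` synthetic sessions, preprocesses both modalities,
#' extracts the three feature sets, optionally computes the cross-subject
#' channel-importance ranking, evaluates all (feature set, classifier)
#' combinations and writes the statistical reports. All outputs are written
#' under `outDir` (created if missing) as CSV/JSON; the run manifest
#' records the configuration, seeds and MD5 checksums of every file, so a
#' rerun with the same configuration reproduces identical checksums.
#'
#' @param config A [SessionConfig-class].
#' @param outDir Output directory.
#' @param nSubjects Number of synthetic subjects (default 2).
#' @param stride Epoch stride in seconds (default 3).
#' @param montageMode `"optimized"` or `"full"`.
#' @param channels Optimized montage (default [optimizedMontage()]).
#' @param spec A [GridSearchSpec-class].
#' @param selectChannels If `TRUE`, run the per-subject SVM-RFE ranking and
#'   write the channel-importance report (default `FALSE`; the packaged
#'   optimized montage is used either way for the feature sets).
#' @param removeOutliers Apply the per-subject z-score outlier filter to the
#'   assembled feature sets (default `TRUE`).
#' @param seed Integer seed for the evaluation stage.
#' @return The manifest, invisibly (a list).
#' @export
runPipeline <- function(config, outDir, nSubjects = 2L, stride = 3,
                        montageMode = "optimized",
                        channels = optimizedMontage(),
                        spec = gridSearchSpec(),
                        selectChannels = FALSE, removeOutliers = TRUE,
                        seed = 1L) {
  if (!dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
    message("created output directory ", outDir)
  }
  subjects <- sprintf("S%02d", seq_len(nSubjects))
  perSubject <- list()
  behavioral <- list()
  for (s in subjects) {
    session <- generateSession(config, s)
    perSubject[[s]] <- extractSubjectFeatures(
      session, stride = stride, montageMode = montageMode,
      channels = channels, removeOutliers = removeOutliers)
    behavioral[[s]] <- generateBehavioral(config, s)
  }
  files <- character()

  for (s in subjects)
    for (fs in c("only_eeg", "only_fnirs", "fused")) {
      f <- file.path(outDir, sprintf("features_%s_%s.csv", s, fs))
      writeFeatureTable(perSubject[[s]][[fs]], f)
      files <- c(files, f, paste0(f, ".json"))
    }

  if (selectChannels) {
    sets <- lapply(perSubject, function(p) rfeTopFeatures(p$eeg_full))
    report <- aggregateImportance(sets, scalpChannels(config@montage))
    f <- file.path(outDir, "channel_importance.csv")
    utils::write.csv(data.frame(feature = names(featureWeights(report)),
                                weight = featureWeights(report)),
                     f, row.names = FALSE)
    jf <- file.path(outDir, "channel_ranking.json")
    jsonlite::write_json(list(ranking = channelRanking(report),
                              channelWeights = as.list(channelWeights(report))),
                         jf, auto_unbox = TRUE)
    files <- c(files, f, jf)
  }

  results <- evaluateAll(lapply(perSubject, function(p)
    p[c("only_eeg", "only_fnirs", "fused")]), spec = spec, seed = seed)
  f <- file.path(outDir, "evaluation.csv")
  utils::write.csv(summaryTable(results), f, row.names = FALSE)
  files <- c(files, f)
  if (nSubjects >= 2) {
    f <- file.path(outDir, "accuracy_anova.csv")
    utils::write.csv(accuracyAnova(results), f, row.names = FALSE)
    files <- c(files, f)
  }

  behav <- do.call(rbind, behavioral)
  f <- file.path(outDir, "behavioral.csv")
  utils::write.csv(behav, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(outDir, "behavioral_composites.csv")
  utils::write.csv(compositeScores(behav), f, row.names = FALSE)
  files <- c(files, f)

  pooledEEG <- do.call(bindColumns, lapply(perSubject, `[[`, "only_eeg"))
  f <- file.path(outDir, "scalp_anova.csv")
  utils::write.csv(scalpAnovaMap(pooledEEG), f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(outDir, "band_contrast.csv")
  utils::write.csv(bandContrastMap(pooledEEG,
                                   levelHi = max(config@levels),
                                   levelLo = min(config@levels)),
                   f, row.names = FALSE)
  files <- c(files, f)

  manifest <- list(
    package_version = as.character(utils::packageVersion("neuroload")),
    config = configAsList(config),
    n_subjects = nSubjects, stride = stride, montage_mode = montageMode,
    evaluation_seed = seed,
    grids = list(svm = spec@svm, dt = spec@dt, rf = spec@rf),
    n_results = length(results),
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))))
  mf <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# pool per-subject feature tables column-wise (same feature rows)
bindColumns <- function(...) {
  fts <- list(...)
  vals <- do.call(cbind, lapply(fts, function(f) assay(f, "features")))
  info <- do.call(rbind, lapply(fts, epochInfo))
  featureTable(vals, info)
}

configAsList <- function(config) {
  list(nBlocks = config@nBlocks, blockDuration = config@blockDuration,
       levels = config@levels, eegRate = config@eegRate,
       fnirsRate = config@fnirsRate, montage = config@montage,
       ocularLabel = config@ocularLabel, effectSize = config@effectSize,
       noiseSd = config@noiseSd,
       modulation = lapply(config@modulation, function(m)
         list(channels = m$channels, slope = m$slope)),
       eegBaseAmp = as.list(config@eegBaseAmp),
       fnirsBaseline = as.list(config@fnirsBaseline),
       fnirsSlope = as.list(config@fnirsSlope),
       ocularRate = config@ocularRate, ocularAmp = config@ocularAmp,
       seed = config@seed)
}

#' Read a session configuration from YAML or JSON
#'
#' The file may set any argument of [sessionConfig()]; unset fields keep
#' their defaults. The configuration round-trips losslessly through
#' [writeRunConfig()].
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A [SessionConfig-class].
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$modulation))
    raw$modulation <- lapply(raw$modulation, function(m)
      list(channels = unlist(m$channels), slope = m$slope))
  for (nm in c("eegBaseAmp", "fnirsBaseline", "fnirsSlope"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(sessionConfig, raw)
}

#' @rdname readRunConfig
#' @param config A [SessionConfig-class].
#' @export
writeRunConfig <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(configAsList(config), path)
  else jsonlite::write_json(configAsList(config), path, auto_unbox = TRUE,
                            digits = NA)
  invisible(path)
}
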