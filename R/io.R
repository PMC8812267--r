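## Plain-text serialization: feature tables as CSV + JSON sidecar schema,
## raw sessions as delimited signal tables with a JSON manifest.

#' Write / read a FeatureTable as CSV with a JSON sidecar
#'
#' The CSV holds one row per epoch (`subject`, `level`, `block`, `onset`
#' followed by the feature columns); the sidecar (`<path>.json`) records
#' the feature names and their provenance class (band power, pair
#' difference, chromophore statistic, neurovascular coupling).
#'
#' @param ft A [FeatureTable-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(ft, path) {
  stopifnot(is(ft, "FeatureTable"))
  info <- epochInfo(ft)
  df <- cbind(info, as.data.frame(featureMatrix(ft), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  nm <- rownames(ft)
  prov <- ifelse(grepl("_psd$", nm), "band_power",
          ifelse(grepl("_diff$", nm), "pair_difference",
          ifelse(grepl("^nvc_", nm), "neurovascular_coupling",
                 "chromophore_statistic")))
  jsonlite::write_json(list(features = nm, provenance = prov,
                            n_epochs = ncol(ft)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  metaCols <- intersect(c("subject", "level", "block", "onset"), names(df))
  vals <- t(as.matrix(df[, setdiff(names(df), metaCols), drop = FALSE]))
  featureTable(vals, df[, metaCols, drop = FALSE])
}

#' Write / read a raw session as delimited tables
#'
#' Writes, under `dir`: one EEG CSV per block (`eeg_block<k>.csv`, columns
#' `time` then one column per channel), a long-format fNIRS table
#' (`fnirs.csv`: `time`, `site`, `chromophore`, `value`), the event table
#' and a JSON manifest with rates, montage and labels. Signals are large;
#' intended for archival of small sessions and round-trip tests.
#'
#' @param session A [RawSession-class].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
writeSessionSignals <- function(session, dir) {
  stopifnot(is(session, "RawSession"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  segPerBlock <- table(session@events$block)
  files <- character()
  for (b in sort(unique(session@events$block))) {
    segs <- session@events[session@events$block == b, ]
    i0 <- round(min(segs$onset) * session@eegRate)
    n <- round(nrow(segs) * session@blockDuration * session@eegRate)
    idx <- i0 + seq_len(n)
    df <- data.frame(time = (idx - 1) / session@eegRate,
                     t(session@eeg[, idx, drop = FALSE]),
                     check.names = FALSE)
    f <- file.path(dir, sprintf("eeg_block%d.csv", b))
    utils::write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  tF <- (seq_len(ncol(session@fnirs)) - 1) / session@fnirsRate
  long <- do.call(rbind, lapply(rownames(session@fnirs), function(tr) {
    parts <- strsplit(tr, "_")[[1]]
    data.frame(time = tF, site = parts[1], chromophore = parts[2],
               value = session@fnirs[tr, ])
  }))
  fn <- file.path(dir, "fnirs.csv")
  utils::write.csv(long, fn, row.names = FALSE)
  ev <- file.path(dir, "events.csv")
  utils::write.csv(session@events, ev, row.names = FALSE)
  manifest <- file.path(dir, "session.json")
  jsonlite::write_json(list(
    subject = session@subjectID, eeg_rate = session@eegRate,
    fnirs_rate = session@fnirsRate, block_duration = session@blockDuration,
    montage = session@montage, ocular_label = session@ocularLabel,
    files = c(basename(files), basename(fn), basename(ev))),
    manifest, auto_unbox = TRUE)
  invisible(manifest)
}

#' @rdname writeSessionSignals
#' @param dir Directory written by [writeSessionSignals()].
#' @export
readSessionSignals <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  eegFiles <- sort(list.files(dir, "^eeg_block[0-9]+\\.csv$",
                              full.names = TRUE))
  eeg <- do.call(cbind, lapply(eegFiles, function(f) {
    df <- utils::read.csv(f, check.names = FALSE)
    t(as.matrix(df[, setdiff(names(df), "time"), drop = FALSE]))
  }))
  long <- utils::read.csv(file.path(dir, "fnirs.csv"))
  traces <- unique(paste0(long$site, "_", long$chromophore))
  fnirs <- do.call(rbind, lapply(traces, function(tr) {
    parts <- strsplit(tr, "_")[[1]]
    long$value[long$site == parts[1] & long$chromophore == parts[2]]
  }))
  rownames(fnirs) <- traces
  events <- utils::read.csv(file.path(dir, "events.csv"))
  new("RawSession", subjectID = meta$subject, eeg = eeg,
      eegRate = meta$eeg_rate, fnirs = fnirs, fnirsRate = meta$fnirs_rate,
      events = events, blockDuration = meta$block_duration,
      montage = meta$montage, ocularLabel = meta$ocular_label,
      groundTruth = list())
}
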