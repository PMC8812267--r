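# Shared fixtures: a small montage that retains every channel the default
# pair list and NVC feature need, plus builders for hand-crafted sessions.

suppressPackageStartupMessages(library(SummarizedExperiment))

smallMontage <- function() {
  c("Fp1", "AF3", "F3", "C1", "C2", "P3", "P4", "P7", "P8", "Pz",
    "O1", "O2", "Oz", "M1", "M2")
}

smallPairs <- function() {
  data.frame(a = c("P8", "O2", "C2", "P4"),
             b = c("P7", "O1", "C1", "P3"))
}

smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(nBlocks = 1L, blockDuration = 30, montage = smallMontage(),
                   seed = 123L)
  do.call(sessionConfig, utils::modifyList(defaults, args))
}

# minimal hand-built session: eeg is channels x samples at `rate`, one
# 4-level event grid covering the whole recording
manualSession <- function(eeg, rate = 500, fnirs = NULL, fnirsRate = 50,
                          levels = c(1, 3, 5, 7), ocularLabel = "VEOG") {
  dur <- ncol(eeg) / rate
  segDur <- dur / length(levels)
  if (is.null(fnirs)) {
    fnirs <- matrix(0, 4, round(dur * fnirsRate),
                    dimnames = list(c("left_O2Hb", "left_HHb",
                                      "right_O2Hb", "right_HHb"), NULL))
  }
  mont <- setdiff(rownames(eeg), ocularLabel)
  new("RawSession", subjectID = "SX", eeg = eeg, eegRate = rate,
      fnirs = fnirs, fnirsRate = fnirsRate,
      events = data.frame(onset = (seq_along(levels) - 1) * segDur,
                          level = levels, block = 1L),
      blockDuration = segDur, montage = mont, ocularLabel = ocularLabel,
      groundTruth = list())
}

# feature table with arbitrary named features and levels
manualFeatureTable <- function(values, levels, subject = "SX") {
  featureTable(values,
               data.frame(subject = subject, level = levels,
                          block = 1L, onset = seq_along(levels) * 3 - 3))
}

sineMatrix <- function(freqs, rate, seconds, labels = names(freqs)) {
  t <- (seq_len(round(rate * seconds)) - 1) / rate
  out <- t(vapply(freqs, function(f) sin(2 * pi * f * t), t))
  rownames(out) <- labels
  out
}
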