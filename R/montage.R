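#' Standard electrode montages
#'
#' `defaultMontage()` returns the 64-label extended 10-20 electrode set used
#' by the session generator: 62 scalp electrodes plus the two mastoid
#' reference electrodes M1 and M2. The auxiliary ocular channel (default
#' label `"VEOG"`) is recorded alongside but is not part of the montage.
#' `optimizedMontage()` returns the reduced 26-channel acquisition montage,
#' concentrated over parietal-occipital cortex with a few frontal and central
#' sites, shipped as a packaged constant for reproduction of the optimized
#' configuration.
#'
#' @return A character vector of channel labels.
#' @examples
#' length(defaultMontage())   # 64
#' length(optimizedMontage()) # 26
#' @export
defaultMontage <- function() {
  c(
    "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "O1", "Oz", "O2",
    "M1", "M2"
  )
}

#' @rdname defaultMontage
#' @export
optimizedMontage <- function() {
  c(
    "P4", "PO6", "O1", "P6", "PO5", "P8", "PO8", "P7", "PO7", "PO4",
    "P5", "P1", "O2", "CP2", "P2", "AF3", "C1", "P3", "Pz", "C2",
    "PO3", "TP8", "Oz", "CP4", "TP7", "CP6"
  )
}

#' Default channel pairs for lateral/antero-posterior power differences
#'
#' Seven left-right and front-back electrode pairs whose band-power
#' differences are appended to the EEG feature battery.
#'
#' @return A data.frame with columns `a` and `b`.
#' @export
defaultChannelPairs <- function() {
  data.frame(
    a = c("P8", "O2", "C2", "P4", "Pz", "Pz", "O1"),
    b = c("P7", "O1", "C1", "P3", "O1", "O2", "AF3"),
    stringsAsFactors = FALSE
  )
}

#' Frequency band definitions
#'
#' The four canonical workload-sensitive EEG bands: theta (3-8 Hz),
#' alpha (8-13 Hz), beta1 (13-20 Hz) and beta2 (20-30 Hz). Band power is
#' integrated over `[lo, hi)`.
#'
#' @return A data.frame with columns `name`, `lo`, `hi`.
#' @export
bandDefinitions <- function() {
  data.frame(
    name = c("theta", "alpha", "beta1", "beta2"),
    lo = c(3, 8, 13, 20),
    hi = c(8, 13, 20, 30),
    stringsAsFactors = FALSE
  )
}

# scalp channels of a montage = montage minus mastoids
scalpChannels <- function(montage) {
  setdiff(montage, c("M1", "M2"))
}
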