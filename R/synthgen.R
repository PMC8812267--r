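## Synthetic MATB-like session generation.
##
## EEG model: per 3-s cell, per channel and band, one sinusoid with random
## frequency inside the band, random phase and lognormal amplitude jitter;
## the band amplitude on modulated channels is a linear function of
## difficulty. 1/f (pink) background noise and blink-like ocular transients
## are added on top. fNIRS model: per-segment concentration plateau whose
## height is linear in difficulty, approached through a smooth
## gamma-CDF-shaped hemodynamic rise, plus Mayer-wave / respiratory
## oscillations and sensor noise.

EPOCH_SECONDS <- 3

# deterministic 32-bit seed from (base seed, subject id, stage salt)
derivedSeed <- function(seed, subjectID, salt) {
  h <- sum(utf8ToInt(subjectID) * seq_along(utf8ToInt(subjectID)))
  as.integer((abs(seed) * 7919 + h * 131 + salt * 104729) %% 2147483629)
}

# difficulty mapped to [0, 1] over the configured level range
levelScale <- function(levels) {
  if (length(levels) == 1L) return(stats::setNames(0, levels))
  stats::setNames((levels - min(levels)) / (max(levels) - min(levels)),
                  levels)
}

# per-subject segment layout: each block presents every level once, in a
# subject- and block-specific random order
sessionLayout <- function(config, subjectID) {
  set.seed(derivedSeed(config@seed, subjectID, 1L))
  segs <- do.call(rbind, lapply(seq_len(config@nBlocks), function(b) {
    data.frame(block = b, level = sample(config@levels))
  }))
  segs$onset <- (seq_len(nrow(segs)) - 1L) * config@blockDuration
  segs
}

# pink (1/f) noise, unit SD, length n
pinkNoise <- function(n) {
  nfft <- n
  white <- stats::rnorm(nfft)
  spec <- stats::fft(white)
  f <- c(1, seq_len(nfft - 1))          # avoid DC blow-up
  f <- pmin(f, nfft - f + 1)            # mirror for the negative frequencies
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / nfft
  x / stats::sd(x)
}

# blink-like kernel: sharp rise, exponential decay, ~1 s support
ocularKernel <- function(rate, tau = 0.15) {
  t <- seq(0, 1, by = 1 / rate)
  (t / tau) * exp(1 - t / tau)
}

# amplitude of band b on channel ch at difficulty scale g in [0,1]
bandAmplitude <- function(config, band, channels, g) {
  amp <- rep(config@eegBaseAmp[[band]], length(channels))
  names(amp) <- channels
  mod <- config@modulation[[band]]
  if (!is.null(mod) && length(mod$channels)) {
    fac <- 1 + config@effectSize * mod$slope * g
    amp[mod$channels] <- amp[mod$channels] * max(fac, 0)
  }
  amp
}

# smooth hemodynamic rise, 0 -> 1, most of the transition inside ~15 s
hemodynamicRise <- function(t) stats::pgamma(t, shape = 4, rate = 0.5)

#' Generate one synthetic hybrid EEG-fNIRS session
#'
#' Produces a [RawSession-class] whose band-limited EEG amplitudes and
#' chromophore plateaus are monotone functions of difficulty exactly as set
#' in the configuration's `modulation` and `fnirsSlope`: by default frontal
#' theta, occipital beta1/beta2 and prefrontal O2Hb increase with difficulty
#' while occipital alpha and HHb decrease. The generated session is
#' bit-identical for a fixed `(seed, subjectID)` pair. The ground-truth
#' modulation parameters (band amplitudes per level, ocular artifact trace
#' and mixing weights, chromophore plateau means) are retained in
#' `groundTruth()` for recovery tests.
#'
#' @param config A [SessionConfig-class].
#' @param subjectID Character label, e.g. `"S01"`.
#' @return A [RawSession-class].
#' @examples
#' cfg <- sessionConfig(nBlocks = 1L, blockDuration = 12, eegRate = 200,
#'                      montage = c("Fz", "Pz", "O1", "M1", "M2"),
#'                      modulation = list(theta = list(channels = "Fz", slope = 0.5)),
#'                      seed = 7)
#' generateSession(cfg, "S01")
#' @seealso [generateBehavioral()], [sessionConfig()]
#' @export
generateSession <- function(config, subjectID) {
  stopifnot(is(config, "SessionConfig"))
  validObject(config)
  layout <- sessionLayout(config, subjectID)
  set.seed(derivedSeed(config@seed, subjectID, 2L))

  bands <- bandDefinitions()
  gmap <- levelScale(config@levels)
  channels <- c(config@montage, config@ocularLabel)
  scalp <- scalpChannels(config@montage)
  fsE <- config@eegRate
  segDur <- config@blockDuration
  nSeg <- nrow(layout)
  nPerSeg <- round(segDur * fsE)
  nE <- nSeg * nPerSeg
  cellN <- round(EPOCH_SECONDS * fsE)
  cellsPerSeg <- segDur / EPOCH_SECONDS

  eeg <- matrix(0, nrow = length(channels), ncol = nE,
                dimnames = list(channels, NULL))
  tCell <- (seq_len(cellN) - 1) / fsE

  # ground truth: amplitude of each band on each scalp channel at each level
  gtAmp <- array(NA_real_,
                 dim = c(nrow(bands), length(scalp), length(config@levels)),
                 dimnames = list(bands$name, scalp, as.character(config@levels)))
  for (bi in seq_len(nrow(bands)))
    for (li in seq_along(config@levels))
      gtAmp[bi, , li] <- bandAmplitude(config, bands$name[bi], scalp,
                                       gmap[[as.character(config@levels[li])]])

  # oscillatory content, built one 3-s cell at a time
  for (si in seq_len(nSeg)) {
    g <- gmap[[as.character(layout$level[si])]]
    amps <- vapply(bands$name,
                   function(b) bandAmplitude(config, b, scalp, g),
                   numeric(length(scalp)))   # scalp x band
    for (ci in seq_len(cellsPerSeg)) {
      idx <- (si - 1L) * nPerSeg + (ci - 1L) * cellN + seq_len(cellN)
      cell <- matrix(0, length(scalp), cellN)
      for (bi in seq_len(nrow(bands))) {
        freq <- stats::runif(length(scalp), bands$lo[bi] + 0.5, bands$hi[bi] - 0.5)
        phase <- stats::runif(length(scalp), 0, 2 * pi)
        jitter <- exp(stats::rnorm(length(scalp), 0, 0.1 * config@noiseSd))
        a <- amps[, bi] * jitter
        cell <- cell + a * sin(2 * pi * outer(freq, tCell) + phase)
      }
      eeg[scalp, idx] <- cell
    }
  }

  # pink background noise on all channels (mastoids and ocular included)
  if (config@noiseSd > 0)
    for (ch in channels)
      eeg[ch, ] <- eeg[ch, ] + config@noiseSd * pinkNoise(nE)

  # ocular transients: full weight on the ocular channel, decaying mixing
  # weights over frontal rows
  mixing <- stats::setNames(numeric(length(channels)), channels)
  mixing[config@ocularLabel] <- 1
  mixing[grep("^Fp", channels)] <- 0.4
  mixing[grep("^AF", channels)] <- 0.25
  mixing[grep("^F[0-9z]", channels)] <- 0.12
  artifact <- numeric(nE)
  if (config@ocularRate > 0) {
    nBlinks <- stats::rpois(1, config@ocularRate * nE / fsE)
    if (nBlinks > 0) {
      kern <- ocularKernel(fsE)
      onsets <- sort(stats::runif(nBlinks, 0, nE / fsE - 1.5))
      ampsB <- config@ocularAmp * stats::runif(nBlinks, 0.7, 1.3)
      for (i in seq_len(nBlinks)) {
        j <- round(onsets[i] * fsE) + seq_along(kern)
        artifact[j] <- artifact[j] + ampsB[i] * kern
      }
      eeg <- eeg + outer(mixing, artifact)
    }
  }

  # fNIRS traces
  fsF <- config@fnirsRate
  nF <- nSeg * round(segDur * fsF)
  traces <- c("left_O2Hb", "left_HHb", "right_O2Hb", "right_HHb")
  fnirs <- matrix(0, length(traces), nF, dimnames = list(traces, NULL))
  siteGain <- c(left = 1, right = 0.9)
  gtMeans <- array(NA_real_,
                   dim = c(length(config@levels), 2, 2),
                   dimnames = list(as.character(config@levels),
                                   c("left", "right"), c("O2Hb", "HHb")))
  tSeg <- (seq_len(round(segDur * fsF)) - 1) / fsF
  for (tr in traces) {
    parts <- strsplit(tr, "_")[[1]]
    site <- parts[1]; chromo <- parts[2]
    prev <- NULL
    x <- numeric(nF)
    for (si in seq_len(nSeg)) {
      g <- gmap[[as.character(layout$level[si])]]
      mu <- siteGain[[site]] *
        (config@fnirsBaseline[[chromo]] +
           config@effectSize * config@fnirsSlope[[chromo]] * g)
      if (is.null(prev)) prev <- mu   # session starts on the first plateau
      idx <- (si - 1L) * length(tSeg) + seq_along(tSeg)
      x[idx] <- prev + (mu - prev) * hemodynamicRise(tSeg)
      prev <- mu
    }
    if (config@noiseSd > 0) {
      tAll <- (seq_len(nF) - 1) / fsF
      physScale <- if (chromo == "HHb") 0.5 else 1
      x <- x + physScale * (0.05 * sin(2 * pi * 0.1 * tAll + stats::runif(1, 0, 2 * pi)) +
                            0.03 * sin(2 * pi * 0.3 * tAll + stats::runif(1, 0, 2 * pi)))
      x <- x + 0.02 * config@noiseSd * stats::rnorm(nF)
    }
    fnirs[tr, ] <- x
    for (li in seq_along(config@levels)) {
      g <- gmap[[as.character(config@levels[li])]]
      gtMeans[li, site, chromo] <- siteGain[[site]] *
        (config@fnirsBaseline[[chromo]] +
           config@effectSize * config@fnirsSlope[[chromo]] * g)
    }
  }

  events <- data.frame(onset = layout$onset, level = layout$level,
                       block = layout$block)
  new("RawSession",
      subjectID = subjectID, eeg = eeg, eegRate = fsE,
      fnirs = fnirs, fnirsRate = fsF, events = events,
      blockDuration = segDur, montage = config@montage,
      ocularLabel = config@ocularLabel,
      groundTruth = list(
        bandAmplitude = gtAmp,
        modulation = config@modulation,
        ocularArtifact = artifact,
        ocularMixing = mixing,
        fnirsMeans = gtMeans,
        layout = layout))
}

#' Generate synthetic behavioral records for one subject
#'
#' One record per (block, level) segment: six NASA-TLX dimension scores
#' (0-100, expected value increasing with difficulty) and six performance
#' indicators (system-monitoring response time and accuracy, tracking X/Y
#' deviations, tank A/B deviations; expected task quality decreasing with
#' difficulty). Noise scales with `noiseSd`; with `effectSize = 0` all
#' levels share the same expected scores.
#'
#' @param config A [SessionConfig-class].
#' @param subjectID Character label.
#' @return A data.frame with columns `subject`, `block`, `level`, six
#'   `tlx_*` columns and six `perf_*` columns.
#' @export
generateBehavioral <- function(config, subjectID) {
  stopifnot(is(config, "SessionConfig"))
  validObject(config)
  layout <- sessionLayout(config, subjectID)
  set.seed(derivedSeed(config@seed, subjectID, 3L))
  gmap <- levelScale(config@levels)
  e <- config@effectSize
  ns <- config@noiseSd
  n <- nrow(layout)
  g <- vapply(as.character(layout$level), function(l) gmap[[l]], numeric(1))

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  tlxNames <- c("mental", "physical", "temporal", "performance", "effort",
                "frustration")
  tlx <- vapply(tlxNames, function(d)
    clamp(20 + 55 * e * g + stats::rnorm(n, 0, 8 * ns), 0, 100),
    numeric(n))
  colnames(tlx) <- paste0("tlx_", tlxNames)

  perf <- cbind(
    perf_monitor_rt  = clamp(0.6 + 0.8 * e * g + stats::rnorm(n, 0, 0.10 * ns), 0.1, Inf),
    perf_monitor_acc = clamp(98 - 25 * e * g + stats::rnorm(n, 0, 3 * ns), 0, 100),
    perf_dev_x       = clamp(10 + 30 * e * g + stats::rnorm(n, 0, 3 * ns), 0, Inf),
    perf_dev_y       = clamp(10 + 30 * e * g + stats::rnorm(n, 0, 3 * ns), 0, Inf),
    perf_dev_tank_a  = clamp(40 + 100 * e * g + stats::rnorm(n, 0, 10 * ns), 0, Inf),
    perf_dev_tank_b  = clamp(40 + 100 * e * g + stats::rnorm(n, 0, 10 * ns), 0, Inf))

  out <- data.frame(subject = subjectID, block = layout$block,
                    level = layout$level, tlx, perf,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
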