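## The per-epoch feature battery: EEG band powers and channel-pair power
## differences; eleven statistical descriptors per chromophore trace;
## neurovascular-coupling correlations; feature-set assembly and the
## per-subject z-score outlier filter.

#' Channel-pair band-power differences
#'
#' For every pair (a, b) and band, the difference power(a) - power(b).
#'
#' @param powers Array channels x bands x epochs from [welchBandPower()].
#' @param pairs A data.frame with columns `a`, `b`
#'   (default [defaultChannelPairs()]).
#' @return Array pairs x bands x epochs; pair dimnames are `"a-b"`.
#' @export
pairBandDifference <- function(powers, pairs = defaultChannelPairs()) {
  chans <- dimnames(powers)[[1]]
  missing <- setdiff(unique(c(pairs$a, pairs$b)), chans)
  if (length(missing))
    stop("pair channels not present: ", paste(missing, collapse = ", "))
  d <- dim(powers)
  out <- array(0, dim = c(nrow(pairs), d[2], d[3]),
               dimnames = list(paste0(pairs$a, "-", pairs$b),
                               dimnames(powers)[[2]], NULL))
  for (i in seq_len(nrow(pairs)))
    out[i, , ] <- powers[pairs$a[i], , ] - powers[pairs$b[i], , ]
  out
}

# flatten a channels x bands x epochs array into a (channel_band) x epochs
# feature matrix with `<name>_<band>_<suffix>` rownames
flattenBandArray <- function(arr, suffix) {
  d <- dim(arr)
  nm <- as.vector(outer(dimnames(arr)[[1]], dimnames(arr)[[2]],
                        function(ch, b) paste0(ch, "_", b, "_", suffix)))
  matrix(arr, nrow = d[1] * d[2], ncol = d[3], dimnames = list(nm, NULL))
}

#' EEG feature table: band powers plus pair differences
#'
#' Per epoch: one Welch band power per (channel, band) named
#' `<channel>_<band>_psd`, plus one power difference per (pair, band) named
#' `<a>-<b>_<band>_diff`. For an m-channel montage and the default 7 pairs
#' and 4 bands this yields 4m + 28 features (276 for the full 62-channel
#' scalp montage).
#'
#' @param epochs An EEG [EpochSet-class].
#' @param bands Band definitions (default [bandDefinitions()]).
#' @param pairs Channel pairs (default [defaultChannelPairs()]).
#' @param ... Passed to [welchBandPower()].
#' @return A [FeatureTable-class].
#' @export
eegFeatures <- function(epochs, bands = bandDefinitions(),
                        pairs = defaultChannelPairs(), ...) {
  bp <- welchBandPower(epochs, bands, ...)
  vals <- rbind(flattenBandArray(bp, "psd"),
                flattenBandArray(pairBandDifference(bp, pairs), "diff"))
  featureTable(vals, epochs@info)
}

# the eleven per-trace statistical descriptors; ratio descriptors of an
# all-zero trace are defined as 0
statDescriptors <- function(x) {
  m <- mean(x)
  rms <- sqrt(mean(x^2))
  peak <- max(abs(x))
  absMean <- mean(abs(x))
  sqrtMean <- mean(sqrt(abs(x)))^2
  sk <- if (stats::sd(x) == 0) 0 else e1071::skewness(x)
  ku <- if (stats::sd(x) == 0) 0 else e1071::kurtosis(x)
  c(mean = m,
    sd = stats::sd(x),
    mse = mean((x - m)^2),
    skewness = if (is.finite(sk)) sk else 0,
    rms = rms,
    peak = peak,
    crest = if (rms > 0) peak / rms else if (peak == 0) 1 else 0,
    kurtosis = if (is.finite(ku)) ku else 0,
    shape = if (absMean > 0) rms / absMean else 0,
    impulse = if (absMean > 0) peak / absMean else 0,
    margin = if (sqrtMean > 0) peak / sqrtMean else 0)
}

#' fNIRS statistical feature table
#'
#' Eleven descriptors per (site, chromophore) trace and epoch: mean,
#' standard deviation, mean squared deviation from the mean (`mse`),
#' skewness, root mean square, peak (max absolute value), crest factor
#' (peak/RMS), kurtosis, waveform/shape factor (RMS over mean absolute),
#' impulse factor (peak over mean absolute) and margin factor
#' (peak over squared mean root-absolute). 2 sites x 2 chromophores x 11
#' descriptors = 44 features named `<site>_<chromophore>_<stat>`.
#'
#' @param epochs An fNIRS [EpochSet-class].
#' @return A [FeatureTable-class] with 44 features.
#' @export
fnirsStatFeatures <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  d <- dim(epochs@data)
  if (d[2] < 2) stop("traces need at least 2 samples")
  statNames <- names(statDescriptors(c(0, 1)))
  traces <- dimnames(epochs@data)[[1]]
  nm <- as.vector(vapply(traces, function(tr) paste0(tr, "_", statNames),
                         character(length(statNames))))
  vals <- matrix(0, length(nm), d[3], dimnames = list(nm, NULL))
  for (e in seq_len(d[3]))
    vals[, e] <- as.vector(vapply(traces, function(tr)
      statDescriptors(epochs@data[tr, , e]), numeric(length(statNames))))
  featureTable(vals, epochs@info)
}

# band power of short sub-windows of a single series, averaged over bands;
# plain single-taper periodogram per sub-window
subWindowBandPower <- function(x, fs, bands, winSeconds, strideSeconds) {
  L <- round(winSeconds * fs)
  step <- max(1L, round(strideSeconds * fs))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- hannWindow(L)
  nf <- floor(L / 2) + 1L
  freq <- (seq_len(nf) - 1) * fs / L
  sel <- lapply(seq_len(nrow(bands)), function(bi)
    freq >= bands$lo[bi] & freq < bands$hi[bi])
  tc <- vapply(starts, function(s) {
    p <- Mod(stats::fft(x[s + 0:(L - 1)] * w)[seq_len(nf)])^2
    mean(vapply(sel, function(si) sum(p[si]), numeric(1)))
  }, numeric(1))
  list(time = (starts - 1 + L / 2) / fs, power = tc)
}

#' Neurovascular-coupling features
#'
#' For each prefrontal site, the zero-lag Pearson correlation between a
#' chromophore's amplitude time-course and the frontal EEG band-power
#' time-course within the epoch, giving one oxy- and one deoxy-coupling
#' value per site (4 features, each in \[-1, 1\]). The band-power
#' time-course is the mean power over the four bands of the frontal channel
#' `channel`, computed in sliding `winSeconds` sub-windows and interpolated
#' onto the fNIRS sample grid. Constant series yield a correlation of 0.
#'
#' @param eegEpochs EEG [EpochSet-class]; must be epoch-aligned with
#'   `fnirsEpochs` (same window grid).
#' @param fnirsEpochs fNIRS [EpochSet-class].
#' @param channel Frontal EEG channel for the power time-course
#'   (default `"AF3"`).
#' @param bands Band definitions (default [bandDefinitions()]).
#' @param winSeconds,strideSeconds Sub-window length and stride in seconds
#'   (defaults 0.5 and 0.1).
#' @return A [FeatureTable-class] with 4 features
#'   `nvc_<site>_<chromophore>`.
#' @export
nvcFeatures <- function(eegEpochs, fnirsEpochs, channel = "AF3",
                        bands = bandDefinitions(),
                        winSeconds = 0.5, strideSeconds = 0.1) {
  stopifnot(is(eegEpochs, "EpochSet"), is(fnirsEpochs, "EpochSet"))
  if (nEpochs(eegEpochs) != nEpochs(fnirsEpochs) ||
      any(abs(eegEpochs@info$onset - fnirsEpochs@info$onset) > 1e-9))
    stop("EEG and fNIRS epoch grids are not aligned")
  if (!channel %in% dimnames(eegEpochs@data)[[1]])
    stop("frontal channel '", channel, "' not present in the EEG epochs")
  traces <- dimnames(fnirsEpochs@data)[[1]]
  nm <- paste0("nvc_", traces)
  nE <- nEpochs(eegEpochs)
  vals <- matrix(0, length(nm), nE, dimnames = list(nm, NULL))
  fsF <- fnirsEpochs@rate
  nF <- dim(fnirsEpochs@data)[2]
  tF <- (seq_len(nF) - 1) / fsF
  safeCor <- function(a, b)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  for (e in seq_len(nE)) {
    tc <- subWindowBandPower(eegEpochs@data[channel, , e], eegEpochs@rate,
                             bands, winSeconds, strideSeconds)
    bpF <- stats::approx(tc$time, tc$power, xout = tF, rule = 2)$y
    for (i in seq_along(traces))
      vals[i, e] <- safeCor(bpF, fnirsEpochs@data[traces[i], , e])
  }
  featureTable(vals, fnirsEpochs@info)
}

# row-bind feature tables that share an epoch grid
bindFeatureTables <- function(...) {
  fts <- list(...)
  info <- epochInfo(fts[[1]])
  for (ft in fts[-1])
    if (ncol(ft) != nrow(info) ||
        !isTRUE(all.equal(epochInfo(ft)$onset, info$onset)) ||
        !identical(as.character(epochInfo(ft)$subject), as.character(info$subject)))
      stop("feature tables are not epoch-aligned")
  featureTable(do.call(rbind, lapply(fts, function(f) assay(f, "features"))),
               info)
}

# restrict an EEG feature table to the psd features of `channels`
# (pair-difference features are kept in full)
restrictEEGFeatures <- function(eegFT, channels) {
  nm <- rownames(eegFT)
  psd <- grepl("_psd$", nm)
  chOf <- sub("_(theta|alpha|beta1|beta2)_psd$", "", nm)
  keep <- !psd | chOf %in% channels
  featureTable(assay(eegFT, "features")[keep, , drop = FALSE],
               epochInfo(eegFT))
}

#' Assemble the three analysis feature sets
#'
#' Builds the only-EEG, only-fNIRS and fused feature tables from the
#' modality feature tables of one subject. With the default montage,
#' pairs and bands: full-montage only-EEG has 62 x 4 + 7 x 4 = 276 columns,
#' optimized-montage only-EEG has 26 x 4 + 28 = 132, only-fNIRS has
#' 2 x 2 x 11 = 44 (statistical descriptors only), and the fused set has
#' 132 + 44 + 4 = 180 (optimized EEG + fNIRS statistics + the 4
#' neurovascular-coupling features, which require both modalities and are
#' therefore kept out of the unimodal sets).
#'
#' @param eegFT EEG [FeatureTable-class] from [eegFeatures()].
#' @param fnirsFT fNIRS [FeatureTable-class] from [fnirsStatFeatures()].
#' @param nvcFT NVC [FeatureTable-class] from [nvcFeatures()].
#' @param montageMode `"optimized"` (default) restricts the EEG per-channel
#'   features to `channels`; `"full"` keeps all channels.
#' @param channels The optimized montage (default [optimizedMontage()]).
#' @return A named list of three [FeatureTable-class] objects:
#'   `only_eeg`, `only_fnirs`, `fused`.
#' @export
assembleFeatureSets <- function(eegFT, fnirsFT, nvcFT,
                                montageMode = c("optimized", "full"),
                                channels = optimizedMontage()) {
  montageMode <- match.arg(montageMode)
  onlyEEG <- if (montageMode == "full") eegFT
             else restrictEEGFeatures(eegFT, channels)
  list(only_eeg = onlyEEG,
       only_fnirs = fnirsFT,
       fused = bindFeatureTables(onlyEEG, fnirsFT, nvcFT))
}

#' Per-subject z-score outlier removal
#'
#' Within each subject, every feature column is z-scored and any epoch
#' containing a |z| greater than `thresh` in any feature is dropped.
#' Subjects with fewer than 2 epochs are passed through with a message.
#'
#' @param ft A [FeatureTable-class].
#' @param thresh z threshold (default 3).
#' @return The filtered [FeatureTable-class] (row count non-increasing).
#' @export
zscoreOutlierRemoval <- function(ft, thresh = 3) {
  stopifnot(is(ft, "FeatureTable"))
  vals <- assay(ft, "features")
  subj <- as.character(colData(ft)$subject)
  keep <- logical(ncol(vals))
  for (s in unique(subj)) {
    idx <- which(subj == s)
    if (length(idx) < 2) {
      message("subject ", s, " has fewer than 2 epochs; passed through")
      keep[idx] <- TRUE
      next
    }
    v <- vals[, idx, drop = FALSE]
    mu <- rowMeans(v)
    sd <- apply(v, 1L, stats::sd)
    sd[sd == 0] <- Inf                   # constant feature: z = 0
    z <- abs((v - mu) / sd)
    keep[idx] <- apply(z, 2L, max) <= thresh
  }
  featureTable(vals[, keep, drop = FALSE],
               epochInfo(ft)[keep, , drop = FALSE])
}
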