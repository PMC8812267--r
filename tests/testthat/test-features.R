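# Feature battery: Welch band powers, pair differences, the eleven
# statistical descriptors, neurovascular coupling, assembly and the
# z-score outlier filter.

# brute-force single-taper periodogram band integral, the independent
# reference for welchBandPower on noiseless sinusoids
periodogramBandPower <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / (n * fs)
  nf <- floor(n / 2) + 1
  p <- p[1:nf]
  p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  f <- (0:(nf - 1)) * fs / n
  sum(p[f >= lo & f < hi]) * fs / n
}

epochSetFromMatrix <- function(mat, rate, nEpochs = 1, modality = "eeg",
                               levels = rep(1, nEpochs)) {
  arr <- array(rep(mat, nEpochs), dim = c(nrow(mat), ncol(mat), nEpochs),
               dimnames = list(rownames(mat), NULL, NULL))
  new("EpochSet", data = arr,
      info = data.frame(subject = "SX", level = levels, block = 1L,
                        onset = (seq_len(nEpochs) - 1) * 3),
      rate = rate, modality = modality)
}

test_that("Welch band power localizes sinusoids and scales quadratically", {
  t <- (0:599) / 200
  mat <- rbind(a10 = sin(2 * pi * 10 * t),
               zero = rep(0, 600),
               scaled = 3 * sin(2 * pi * 10 * t))
  ep <- epochSetFromMatrix(mat, 200)
  bp <- welchBandPower(ep)
  expect_gte(bp["a10", "alpha", 1], 20 * bp["a10", "theta", 1])
  expect_equal(unname(bp["zero", , 1]), rep(0, 4))
  expect_equal(bp["scaled", "alpha", 1], 9 * bp["a10", "alpha", 1],
               tolerance = 1e-9)
  # agreement with the brute-force periodogram on a noiseless sinusoid
  ref <- periodogramBandPower(mat["a10", ], 200, 8, 13)
  expect_equal(bp["a10", "alpha", 1], ref, tolerance = 0.05)
  expect_error(welchBandPower(ep, bands = data.frame(name = "x", lo = 90,
                                                     hi = 120)), "Nyquist")
})

test_that("pair differences are signed power differences", {
  powers <- array(0, dim = c(2, 4, 1),
                  dimnames = list(c("P8", "P7"), bandDefinitions()$name, NULL))
  powers["P8", "theta", 1] <- 4
  powers["P7", "theta", 1] <- 1
  d <- pairBandDifference(powers, data.frame(a = "P8", b = "P7"))
  expect_equal(d["P8-P7", "theta", 1], 3)
  expect_equal(d["P8-P7", "alpha", 1], 0)
  expect_error(pairBandDifference(powers, data.frame(a = "P8", b = "Oz")),
               "not present")
})

test_that("the EEG feature table has 4m + 4*pairs features with scheme names", {
  cfg <- smallConfig(blockDuration = 12)
  ep <- preprocessEEG(generateSession(cfg, "S01"))
  ft <- eegFeatures(ep, pairs = smallPairs())
  m <- length(smallMontage()) - 2
  expect_equal(nrow(ft), 4 * m + 4 * nrow(smallPairs()))
  expect_true(all(grepl("_(psd|diff)$", rownames(ft))))
  expect_equal(sum(grepl("_psd$", rownames(ft))), 4 * m)
})

test_that("the eleven descriptors match closed forms", {
  s <- neuroload:::statDescriptors(c(3, -3))
  expect_equal(unname(s[c("mean", "rms", "peak", "crest", "mse", "skewness")]),
               c(0, 3, 3, 1, 9, 0))
  expect_equal(s[["sd"]], sqrt(18))
  sc <- neuroload:::statDescriptors(rep(2, 10))
  expect_equal(unname(sc[c("mean", "sd", "rms", "peak", "crest",
                           "skewness", "kurtosis")]),
               c(2, 0, 2, 2, 1, 0, 0))
  expect_equal(sc[["shape"]], 1)   # RMS / mean|x|
  sz <- neuroload:::statDescriptors(rep(0, 10))
  expect_equal(unname(sz[c("crest", "shape", "impulse", "margin")]),
               c(1, 0, 0, 0))
  # symmetric trace has zero skewness
  expect_equal(neuroload:::statDescriptors(c(-2, -1, 0, 1, 2))[["skewness"]], 0)
})

test_that("fNIRS statistical features are 44 named descriptors per epoch", {
  cfg <- smallConfig(blockDuration = 12)
  ep <- preprocessFNIRS(generateSession(cfg, "S01"))
  ft <- fnirsStatFeatures(ep)
  expect_equal(nrow(ft), 44)
  expect_equal(ncol(ft), nEpochs(ep))
  expect_true("left_O2Hb_crest" %in% rownames(ft))
  expect_true(all(assay(ft)[grep("_sd$", rownames(ft)), ] >= 0))
})

test_that("neurovascular coupling hits +/-1 on identical/negated series and stays null on noise", {
  t <- (0:599) / 200
  eegMat <- rbind(AF3 = sin(2 * pi * 10 * t) * (1 + t))
  epE <- epochSetFromMatrix(eegMat, 200)
  tc <- neuroload:::subWindowBandPower(eegMat["AF3", ], 200,
                                       bandDefinitions(), 0.5, 0.1)
  bpF <- stats::approx(tc$time, tc$power, xout = (0:149) / 50, rule = 2)$y
  fnMat <- rbind(left_O2Hb = bpF, left_HHb = -bpF,
                 right_O2Hb = bpF + 100, right_HHb = rep(1, 150))
  epF <- epochSetFromMatrix(fnMat, 50, modality = "fnirs")
  nv <- nvcFeatures(epE, epF)
  expect_equal(unname(assay(nv)["nvc_left_O2Hb", 1]), 1)
  expect_equal(unname(assay(nv)["nvc_left_HHb", 1]), -1)
  expect_equal(unname(assay(nv)["nvc_right_O2Hb", 1]), 1)   # shift-invariant
  expect_equal(unname(assay(nv)["nvc_right_HHb", 1]), 0)    # constant -> 0

  # independent white noise: |r| stays small
  set.seed(42)
  for (i in 1:20) {
    epEn <- epochSetFromMatrix(rbind(AF3 = rnorm(600)), 200)
    epFn <- epochSetFromMatrix(
      matrix(rnorm(4 * 150), 4, dimnames = list(rownames(fnMat), NULL)), 50,
      modality = "fnirs")
    expect_true(all(abs(assay(nvcFeatures(epEn, epFn))) < 0.4))
  }
})

test_that("feature sets assemble to disjoint unions with the stated widths", {
  cfg <- smallConfig(blockDuration = 12)
  s <- generateSession(cfg, "S01")
  epE <- preprocessEEG(s)
  epF <- preprocessFNIRS(s)
  eegFT <- eegFeatures(epE, pairs = smallPairs())
  fnFT <- fnirsStatFeatures(epF)
  nvFT <- nvcFeatures(epE, epF)
  m <- length(smallMontage()) - 2
  sets <- assembleFeatureSets(eegFT, fnFT, nvFT, montageMode = "full")
  expect_equal(nrow(sets$only_eeg), 4 * m + 16)
  expect_equal(nrow(sets$only_fnirs), 44)
  expect_equal(nrow(sets$fused), 4 * m + 16 + 44 + 4)
  expect_equal(length(intersect(rownames(sets$only_eeg),
                                rownames(sets$only_fnirs))), 0)
  sub <- c("P3", "P4", "O1")
  opt <- assembleFeatureSets(eegFT, fnFT, nvFT, montageMode = "optimized",
                             channels = sub)
  expect_equal(nrow(opt$only_eeg), 4 * 3 + 16)
  expect_equal(nrow(opt$fused), 12 + 16 + 44 + 4)
  # misaligned epochs are refused
  bad <- featureTable(assay(fnFT)[, -1, drop = FALSE],
                      epochInfo(fnFT)[-1, ])
  expect_error(assembleFeatureSets(eegFT, bad, nvFT), "aligned")
})

test_that("z-score outlier removal drops exactly the injected outlier row", {
  set.seed(9)
  vals <- matrix(rnorm(3 * 101), 3, 101,
                 dimnames = list(c("a_theta_psd", "b_theta_psd", "c_theta_psd"), NULL))
  vals[2, 51] <- 10 * sd(vals[2, -51])     # one epoch at ~10 SD
  ft <- manualFeatureTable(vals, levels = rep(c(1, 3, 5, 7), length.out = 101))
  # brute-force oracle: which epochs contain any |z| > 3?
  z <- abs((vals - rowMeans(vals)) / apply(vals, 1, sd))
  expectKeep <- apply(z, 2, max) <= 3
  out <- zscoreOutlierRemoval(ft)
  expect_equal(ncol(out), sum(expectKeep))
  expect_false(51 %in% which(expectKeep))
  # identical rows: nothing removed
  same <- manualFeatureTable(matrix(5, 2, 10, dimnames = list(c("x_psd", "y_psd"), NULL)),
                             levels = rep(1, 10))
  expect_equal(ncol(zscoreOutlierRemoval(same)), 10)
})
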