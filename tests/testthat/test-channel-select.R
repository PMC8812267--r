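# SVM-RFE channel importance: feature selection, cross-subject aggregation,
# the accuracy curve and plateau-based montage selection.

test_that("RFE keeps a perfectly separating feature and drops pure noise", {
  set.seed(3)
  n <- 80
  lv <- rep(c(1, 7), each = n / 2)
  vals <- rbind(Cz_theta_psd = lv + rnorm(n, 0, 0.05),  # separates classes
                Cz_alpha_psd = rnorm(n))                # pure noise
  ft <- manualFeatureTable(vals, levels = lv)
  # sanity: the informative feature alone separates, the noise one does not
  expect_true(max(vals[1, lv == 1]) < min(vals[1, lv == 7]))
  expect_false(max(vals[2, lv == 1]) < min(vals[2, lv == 7]))
  expect_equal(rfeTopFeatures(ft, k = 1), "Cz_theta_psd")
  # k = n_features returns everything
  expect_setequal(rfeTopFeatures(ft, k = 2), rownames(vals))
  # single-class tables are refused
  expect_error(rfeTopFeatures(manualFeatureTable(vals, levels = rep(1, n))),
               "2 classes")
})

test_that("importance aggregation counts subjects and sums band weights", {
  channels <- c("Cz", "Pz")
  sets <- list(
    c("Cz_theta_psd", "Cz_alpha_psd"),
    c("Cz_theta_psd", "Pz_beta1_psd"),
    c("Cz_theta_psd")
  )
  rep <- aggregateImportance(sets, channels)
  fw <- featureWeights(rep)
  expect_equal(unname(fw["Cz_theta_psd"]), 3)
  expect_equal(unname(fw["Cz_alpha_psd"]), 1)
  expect_equal(unname(fw["Pz_beta2_psd"]), 0)
  cw <- channelWeights(rep)
  expect_equal(unname(cw["Cz"]), 4)     # 3 + 1 + 0 + 0
  expect_equal(unname(cw["Pz"]), 1)
  expect_equal(channelRanking(rep), c("Cz", "Pz"))
  # invariant to subject order
  rep2 <- aggregateImportance(rev(sets), channels)
  expect_identical(channelWeights(rep2), cw)
  # empty sets: zero weights, montage-order ranking
  rep0 <- aggregateImportance(list(character(), character()), channels)
  expect_true(all(channelWeights(rep0) == 0))
  expect_equal(channelRanking(rep0), channels)
  expect_error(aggregateImportance(list("Xx_theta_psd"), channels), "unknown")
})

test_that("difficulty-modulated channels rise to the top of the ranking", {
  target <- c("P3", "P4")
  mod <- list(theta = list(channels = target, slope = 0.8),
              alpha = list(channels = target, slope = -0.5),
              beta1 = list(channels = target, slope = 0.8),
              beta2 = list(channels = target, slope = 0.8))
  sets <- lapply(c("S01", "S02", "S03"), function(s) {
    cfg <- smallConfig(blockDuration = 30, modulation = mod, seed = 31L)
    ep <- epochEEG(generateSession(cfg, s))
    rfeTopFeatures(eegFeatures(ep, pairs = smallPairs()), k = 10)
  })
  rep <- aggregateImportance(sets, setdiff(smallMontage(), c("M1", "M2")))
  expect_setequal(channelRanking(rep)[1:2], target)
})

test_that("the accuracy curve is bounded and montage selection follows the plateau rule", {
  rep <- new("ChannelImportanceReport",
             featureWeights = setNames(integer(8), paste0("c", 1:8)),
             channelWeights = setNames(c(5L, 4L, 3L, 2L), c("a", "b", "c", "d")),
             ranking = c("a", "b", "c", "d"), nSubjects = 5L)
  flat <- data.frame(nChannels = 1:4, mean = c(80, 80, 80, 80), sd = 0)
  expect_equal(selectMontage(rep, flat), "a")
  rising <- data.frame(nChannels = 1:4, mean = c(50, 70, 70.3, 70.5), sd = 0)
  expect_equal(selectMontage(rep, rising, plateau = 0.5), c("a", "b"))
  peaked <- data.frame(nChannels = 1:4, mean = c(50, 70, 90, 85), sd = 0)
  expect_equal(selectMontage(rep, peaked, plateau = 0), c("a", "b", "c"))
  steep <- data.frame(nChannels = 1:4, mean = c(10, 40, 70, 100), sd = 0)
  expect_message(got <- selectMontage(rep, steep, plateau = 0.5), "plateau")
  expect_equal(got, c("a", "b", "c", "d"))
})

test_that("the packaged optimized montage has 26 scalp channels", {
  opt <- optimizedMontage()
  expect_equal(length(opt), 26)
  expect_false(anyDuplicated(opt) > 0)
  expect_true(all(opt %in% setdiff(defaultMontage(), c("M1", "M2"))))
})

test_that("the incremental curve recovers signal-bearing channels early", {
  target <- c("P3", "P4")
  mod <- list(theta = list(channels = target, slope = 1),
              alpha = list(channels = target, slope = -0.5),
              beta1 = list(channels = target, slope = 1),
              beta2 = list(channels = target, slope = 1))
  cfg <- smallConfig(blockDuration = 30, modulation = mod, seed = 57L)
  tables <- lapply(c("S01", "S02"), function(s) {
    ep <- epochEEG(generateSession(cfg, s))
    eegFeatures(ep, pairs = smallPairs())
  })
  ranking <- c(target, setdiff(setdiff(smallMontage(), c("M1", "M2")), target))
  curve <- incrementalAccuracyCurve(tables, ranking, seed = 2, maxChannels = 4)
  expect_true(all(curve$mean >= 0 & curve$mean <= 100))
  expect_equal(nrow(curve), 4)
  # with both informative channels in, accuracy is far above 4-class chance
  expect_gt(curve$mean[2], 50)
})
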