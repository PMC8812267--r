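# Classification: stratified split sizes, grid search determinism,
# leakage-free standardization, evaluation summaries and the two-way ANOVA.

separableTable <- function(n = 200, p = 6, gap = 4, seed = 11) {
  set.seed(seed)
  lv <- rep(c(1, 3, 5, 7), length.out = n)
  vals <- matrix(rnorm(p * n), p, n,
                 dimnames = list(paste0("f", seq_len(p), "_theta_psd"), NULL))
  vals[1, ] <- vals[1, ] + gap * lv
  vals[2, ] <- vals[2, ] - gap * lv
  manualFeatureTable(vals, levels = lv)
}

test_that("the default grids match the stated search spaces", {
  spec <- gridSearchSpec()
  expect_equal(nrow(spec@svm), 64)        # 8 costs x 8 gammas
  expect_setequal(unique(spec@svm$cost),
                  c(0.0001, 0.001, 0.01, 0.1, 1, 10, 20, 30))
  expect_setequal(unique(spec@svm$gamma),
                  c(0.1, 0.2, 0.25, 0.4, 0.8, 1.6, 3.2, 6.4))
  expect_equal(nrow(spec@dt), 2 * 4 * 4)
  expect_setequal(unique(spec@dt$maxdepth), c(10, 30, 60, 100))
  expect_setequal(unique(spec@dt$minsplit), c(2, 5, 10, 15))
  expect_setequal(spec@rf$ntree, c(100, 200, 500))
})

test_that("the split is stratified 80/20 and reproducible under a seed", {
  ft <- separableTable(n = 200)
  spec <- gridSearchSpec(svmCost = 1, svmGamma = 0.01)
  r1 <- splitAndTune(ft, "svm", spec, seed = 4)
  r2 <- splitAndTune(ft, "svm", spec, seed = 4)
  expect_equal(length(r1$testIdx), 40)                     # 0.2 x 200
  expect_equal(unname(table(epochLevels(ft)[r1$testIdx])), rep(10L, 4),
               ignore_attr = TRUE)
  expect_identical(r1$testIdx, r2$testIdx)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$testAccuracy, r2$testAccuracy)
  r3 <- splitAndTune(ft, "svm", spec, seed = 5)
  expect_false(identical(r1$testIdx, r3$testIdx))
})

test_that("standardization statistics come from the training partition only", {
  ft <- separableTable(n = 100)
  r <- splitAndTune(ft, "rf", gridSearchSpec(rfTrees = 50), seed = 2)
  X <- featureMatrix(ft)
  trainIdx <- setdiff(seq_len(nrow(X)), r$testIdx)
  expect_equal(r$center, colMeans(X[trainIdx, ]))
  expect_equal(r$scale, apply(X[trainIdx, ], 2, sd))
  # canary: corrupting the held-out rows must not move the learned statistics
  vals <- assay(ft)
  vals[, r$testIdx] <- vals[, r$testIdx] + 1e6
  ftLeak <- manualFeatureTable(vals, levels = epochLevels(ft))
  rLeak <- splitAndTune(ftLeak, "rf", gridSearchSpec(rfTrees = 50), seed = 2)
  expect_equal(rLeak$center, r$center)
  expect_equal(rLeak$scale, r$scale)
})

test_that("separable data reach 100% and train tracks above test", {
  ft <- separableTable(n = 160, gap = 10)
  for (cl in c("rf", "dt", "svm")) {
    spec <- gridSearchSpec(svmCost = 10, svmGamma = 0.1, rfTrees = 100,
                           dtCriterion = "gini", dtMaxDepth = 10,
                           dtMinSplit = 2)
    r <- splitAndTune(ft, cl, spec, seed = 8)
    expect_equal(r$testAccuracy, 100)
    expect_gte(r$trainAccuracy, r$testAccuracy - 1e-9)
  }
})

test_that("evaluateAll returns 9 results whose summaries are internally consistent", {
  tabs <- list(
    S01 = list(only_eeg = separableTable(seed = 1), only_fnirs = separableTable(seed = 2),
               fused = separableTable(seed = 3)),
    S02 = list(only_eeg = separableTable(seed = 4), only_fnirs = separableTable(seed = 5),
               fused = separableTable(seed = 6)))
  spec <- gridSearchSpec(svmCost = 10, svmGamma = 0.1, rfTrees = 50,
                         dtCriterion = "gini", dtMaxDepth = 10, dtMinSplit = 2)
  res <- evaluateAll(tabs, spec, seed = 1)
  expect_length(res, 9)
  st <- summaryTable(res)
  expect_true(all(st$mean >= st$min & st$mean <= st$max))
  expect_true(all(st$min >= 0 & st$max <= 100))
  expect_setequal(unique(st$featureSet), c("only_eeg", "only_fnirs", "fused"))
  # determinism of the whole evaluation
  res2 <- evaluateAll(tabs, spec, seed = 1)
  expect_equal(summaryTable(res2), st)
})

test_that("the two-way accuracy ANOVA isolates feature-set effects", {
  mk <- function(fs, cl, acc)
    new("EvaluationResult", featureSet = fs, classifier = cl,
        testAccuracy = acc, trainAccuracy = acc, params = list())
  subjects <- c(S1 = 70, S2 = 80, S3 = 75)
  # pure subject effect: between-cell variance is exactly zero
  flat <- unlist(lapply(c("only_eeg", "only_fnirs", "fused"), function(fs)
    lapply(c("svm", "dt", "rf"), function(cl) mk(fs, cl, subjects))),
    recursive = FALSE)
  tab <- accuracyAnova(flat)
  expect_equal(tab$F[tab$term == "featureSet"], 0, tolerance = 1e-12)
  expect_gt(tab$p[tab$term == "featureSet"], 0.99)
  # injected fused advantage: strong feature-set main effect
  boosted <- unlist(lapply(c("only_eeg", "only_fnirs", "fused"), function(fs)
    lapply(c("svm", "dt", "rf"), function(cl)
      mk(fs, cl, subjects + if (fs == "fused") 15 else 0))),
    recursive = FALSE)
  tab2 <- accuracyAnova(boosted)
  expect_lt(tab2$p[tab2$term == "featureSet"], 0.01)
  expect_error(accuracyAnova(list(mk("fused", "rf", c(S1 = 70)))), "2 subjects")
})
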