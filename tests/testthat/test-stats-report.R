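# Statistical reporting: composites, level ANOVA against a brute-force F,
# scalp maps with FDR, band contrasts and chromophore level effects.

test_that("composite scores min-max normalize and sign-align components", {
  rec <- data.frame(subject = "S", block = 1, level = c(1, 3, 5))
  for (d in c("mental", "physical", "temporal", "performance", "effort",
              "frustration"))
    rec[[paste0("tlx_", d)]] <- c(2, 4, 6)
  rec$perf_monitor_rt <- c(0.5, 0.7, 0.9)     # lower is better
  rec$perf_monitor_acc <- c(99, 94.5, 90)     # higher is better
  rec$perf_dev_x <- c(5, 10, 15)
  rec$perf_dev_y <- c(5, 10, 15)
  rec$perf_dev_tank_a <- c(10, 30, 50)
  rec$perf_dev_tank_b <- c(10, 30, 50)
  cs <- compositeScores(rec)
  expect_equal(cs$composite_tlx, c(0, 0.5, 1))         # {2,4,6} -> {0,.5,1}
  expect_equal(cs$composite_perf, c(1, 0.5, 0))        # quality decreases
  expect_true(all(cs$composite_tlx >= 0 & cs$composite_tlx <= 1))
  # constant component logs and normalizes to 0
  rec$perf_dev_x <- 7
  expect_message(cs2 <- compositeScores(rec), "constant")
  expect_true(all(cs2$composite_perf >= 0 & cs2$composite_perf <= 1))
})

test_that("level ANOVA matches a brute-force F and separates clusters post hoc", {
  values <- c(0.01, -0.02, 0.00, 0.02, -0.01, 0.01,
              10.01, 9.99, 10.02, 10.00, 9.98, 10.01)
  labels <- rep(c(1, 3, 5, 7), each = 3)
  # brute-force F from sums of squares
  gm <- mean(values)
  groups <- split(values, labels)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  fRef <- (ssb / 3) / (ssw / 8)
  a <- levelAnova(values, labels)
  expect_equal(a$F, fRef, tolerance = 1e-9)
  expect_lt(a$p, 0.001)
  ph <- a$posthoc
  key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  across <- ph$p_adj[key(ph$a, ph$b) %in% c("1 5", "1 7", "3 5", "3 7")]
  within <- ph$p_adj[key(ph$a, ph$b) %in% c("1 3", "5 7")]
  expect_true(all(across < 0.01))
  expect_true(all(within > 0.05))
  # identical group means: F ~ 0
  a0 <- levelAnova(rep(c(1, 2, 3), 4), rep(c(1, 3, 5, 7), each = 3))
  expect_lt(a0$F, 1e-9)
  # a level with < 2 values is dropped with a message
  expect_message(levelAnova(c(values, 99), c(labels, 9)), "dropping")
})

test_that("scalp maps test every channel-band cell in one FDR family", {
  target <- c("P3", "P4")
  mod <- list(theta = list(channels = target, slope = 1),
              alpha = list(channels = target, slope = -0.6),
              beta1 = list(channels = target, slope = 1),
              beta2 = list(channels = target, slope = 1))
  cfg <- smallConfig(blockDuration = 30, modulation = mod, seed = 91L)
  ep <- epochEEG(generateSession(cfg, "S01"))
  ft <- eegFeatures(ep, pairs = smallPairs())
  map <- scalpAnovaMap(ft)
  m <- length(smallMontage()) - 2
  expect_equal(nrow(map), 4 * m)                  # one cell per channel-band
  expect_true(all(map$p_adj >= map$p))
  expect_true(all(map$tier[map$p_adj < 0.01] == "p<0.01"))
  sigTarget <- map$p_adj[map$channel %in% target] < 0.05
  expect_gte(mean(sigTarget), 0.8)                # modulated cells recovered
})

test_that("null data stay null through the FDR scalp map", {
  cfg <- smallConfig(blockDuration = 30, effectSize = 0, seed = 17L)
  ep <- epochEEG(generateSession(cfg, "S01"))
  map <- scalpAnovaMap(eegFeatures(ep, pairs = smallPairs()))
  expect_lte(mean(map$p_adj < 0.05), 0.05)
})

test_that("band contrasts are zero on identical levels and antisymmetric", {
  vals <- matrix(rnorm(8 * 40), 8, 40,
                 dimnames = list(as.vector(outer(c("P3", "O1"),
                   paste0(bandDefinitions()$name, "_psd"),
                   function(a, b) paste(a, b, sep = "_"))), NULL))
  lv <- rep(c(1, 7), each = 20)
  valsSame <- vals
  valsSame[, lv == 7] <- vals[, lv == 1]          # identical distributions
  ftSame <- manualFeatureTable(valsSame, levels = lv)
  expect_true(all(abs(bandContrastMap(ftSame)$contrast) < 1e-12))
  ft <- manualFeatureTable(vals, levels = lv)
  up <- bandContrastMap(ft, levelHi = 7, levelLo = 1)
  down <- bandContrastMap(ft, levelHi = 1, levelLo = 7)
  expect_equal(up$contrast, -down$contrast)
  expect_error(bandContrastMap(ft, levelHi = 5), "present")
})

test_that("the generated contrast pattern matches the configured modulation", {
  cfg <- smallConfig(blockDuration = 30, seed = 29L)
  ep <- epochEEG(generateSession(cfg, "S01"))
  ft <- eegFeatures(ep, pairs = smallPairs())
  cm <- bandContrastMap(ft)
  pick <- function(ch, b) cm$contrast[cm$channel == ch & cm$band == b]
  expect_gt(pick("AF3", "theta"), 0)      # frontal theta rises
  expect_lt(pick("O1", "alpha"), 0)       # occipital alpha falls
  expect_gt(pick("O1", "beta1"), 0)
  expect_gt(pick("O1", "beta2"), 0)
})

test_that("chromophore level effects recover the configured monotone trends", {
  cfg <- smallConfig(nBlocks = 2L, blockDuration = 30, seed = 41L)
  epF <- preprocessFNIRS(generateSession(cfg, "S01"))
  fx <- fnirsLevelEffects(epF)
  expect_equal(dim(fx$timeCourses)[2], 150)       # 3 s x 50 Hz
  for (site in c("left", "right")) {
    o2 <- fx$levelMeans$mean[fx$levelMeans$site == site &
                               fx$levelMeans$chromophore == "O2Hb"]
    hh <- fx$levelMeans$mean[fx$levelMeans$site == site &
                               fx$levelMeans$chromophore == "HHb"]
    expect_true(all(diff(o2) > 0))
    expect_true(all(diff(hh) < 0))
  }
  expect_true(all(fx$anova$p < 0.05))
})

test_that("null chromophore data yield non-significant level effects mostly", {
  ps <- vapply(1:5, function(i) {
    cfg <- smallConfig(blockDuration = 30, effectSize = 0, seed = 100L + i)
    fx <- fnirsLevelEffects(preprocessFNIRS(generateSession(cfg, sprintf("S%02d", i))))
    fx$anova$p
  }, numeric(4))
  expect_gte(mean(ps > 0.05), 0.75)
})
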