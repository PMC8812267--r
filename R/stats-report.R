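## Statistical reporting: behavioral composites, one-way level ANOVA with
## FDR-corrected post hoc comparisons, per-channel ANOVA scalp maps,
## high-minus-low band-power contrasts and chromophore level effects.

#' Behavioral composite scores
#'
#' Each of the six NASA-TLX dimensions and six performance indicators is
#' min-max normalized across the input records and the normalized
#' components averaged into a composite subjective-workload score and a
#' composite performance score, both in \[0, 1\]. Performance components
#' where lower is better (response time, tracking and tank deviations) are
#' sign-aligned before normalization so that a larger composite always
#' means better performance; the performance composite therefore decreases
#' with difficulty while the TLX composite increases. Constant components
#' normalize to 0 with a message.
#'
#' @param records A behavioral data.frame from [generateBehavioral()]
#'   (columns `subject`, `block`, `level`, `tlx_*`, `perf_*`).
#' @return A data.frame with columns `subject`, `block`, `level`,
#'   `composite_tlx`, `composite_perf`.
#' @export
compositeScores <- function(records) {
  tlxCols <- grep("^tlx_", names(records), value = TRUE)
  perfCols <- grep("^perf_", names(records), value = TRUE)
  stopifnot(length(tlxCols) == 6, length(perfCols) == 6)
  lowerBetter <- c(perf_monitor_rt = TRUE, perf_monitor_acc = FALSE,
                   perf_dev_x = TRUE, perf_dev_y = TRUE,
                   perf_dev_tank_a = TRUE, perf_dev_tank_b = TRUE)
  minmax <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) {
      message("constant behavioral component; normalized to 0")
      return(rep(0, length(x)))
    }
    (x - rng[1]) / diff(rng)
  }
  tlxN <- vapply(tlxCols, function(cn) minmax(records[[cn]]),
                 numeric(nrow(records)))
  perfN <- vapply(perfCols, function(cn) {
    x <- records[[cn]]
    if (isTRUE(lowerBetter[[cn]])) x <- -x    # align so larger = better
    minmax(x)
  }, numeric(nrow(records)))
  data.frame(subject = records$subject, block = records$block,
             level = records$level,
             composite_tlx = rowMeans(tlxN),
             composite_perf = rowMeans(perfN))
}

#' One-way level ANOVA with post hoc pairwise comparisons
#'
#' One-way ANOVA of `values` on the difficulty `labels`, followed by all
#' pairwise post hoc t-tests with multiplicity-adjusted p values
#' (Benjamini-Hochberg FDR by default; `"bonferroni"` available). Levels
#' with fewer than 2 values are dropped with a message.
#'
#' @param values Numeric vector of per-sample scalars.
#' @param labels Difficulty labels, same length.
#' @param adjust p-adjustment method for the post hoc family
#'   (default `"fdr"`).
#' @return A list: `F`, `p`, `df` (numerator/denominator degrees of
#'   freedom), and `posthoc` (data.frame `a`, `b`, `p_adj`).
#' @export
levelAnova <- function(values, labels, adjust = c("fdr", "bonferroni")) {
  adjust <- match.arg(adjust)
  labels <- factor(labels)
  counts <- table(labels)
  drop <- names(counts)[counts < 2]
  if (length(drop)) {
    message("dropping level(s) with < 2 values: ", paste(drop, collapse = ", "))
    keep <- !labels %in% drop
    values <- values[keep]
    labels <- droplevels(labels[keep])
  }
  if (nlevels(labels) < 2) stop("at least 2 levels with >= 2 values required")
  fit <- stats::aov(values ~ labels)
  tab <- summary(fit)[[1]]
  ph <- stats::pairwise.t.test(values, labels, p.adjust.method = adjust)
  phm <- ph$p.value
  pairs <- do.call(rbind, lapply(rownames(phm), function(a)
    do.call(rbind, lapply(colnames(phm), function(b)
      if (!is.na(phm[a, b])) data.frame(a = b, b = a, p_adj = phm[a, b])))))
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df = c(tab[["Df"]][1], tab[["Df"]][2]),
       posthoc = pairs)
}

# split "<channel>_<band>_psd" names
parsePSDNames <- function(nm) {
  sel <- grepl("_(theta|alpha|beta1|beta2)_psd$", nm)
  data.frame(name = nm[sel],
             channel = sub("_(theta|alpha|beta1|beta2)_psd$", "", nm[sel]),
             band = sub("^.*_(theta|alpha|beta1|beta2)_psd$", "\\1", nm[sel]),
             stringsAsFactors = FALSE)
}

#' Per-channel, per-band ANOVA scalp map with FDR correction
#'
#' Runs a one-way level ANOVA for every `<channel>_<band>_psd` feature and
#' adjusts the raw p values by Benjamini-Hochberg FDR across the whole
#' family (all channel x band tests, 248 for the 62-channel montage).
#' Cells are assigned a significance tier from the adjusted p value.
#'
#' @param ft An EEG [FeatureTable-class] (typically after
#'   [zscoreOutlierRemoval()]).
#' @return A data.frame with columns `channel`, `band`, `F`, `p`, `p_adj`,
#'   `tier` (`"ns"`, `"p<0.05"`, `"p<0.01"`).
#' @export
scalpAnovaMap <- function(ft) {
  stopifnot(is(ft, "FeatureTable"))
  psd <- parsePSDNames(rownames(ft))
  if (!nrow(psd)) stop("no band-power features in the table")
  vals <- assay(ft, "features")
  labels <- factor(epochLevels(ft))
  res <- do.call(rbind, lapply(seq_len(nrow(psd)), function(i) {
    v <- vals[psd$name[i], ]
    fit <- stats::aov(v ~ labels)
    tab <- summary(fit)[[1]]
    data.frame(channel = psd$channel[i], band = psd$band[i],
               F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1])
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "fdr")
  res$tier <- ifelse(res$p_adj < 0.01, "p<0.01",
                     ifelse(res$p_adj < 0.05, "p<0.05", "ns"))
  res
}

#' High-minus-low band-power contrast map
#'
#' For every `<channel>_<band>_psd` feature, the within-subject mean power
#' difference between the highest and lowest difficulty level, averaged
#' across subjects.
#'
#' @param ft An EEG [FeatureTable-class].
#' @param levelHi,levelLo The two levels contrasted (defaults 7 and 1).
#' @return A data.frame with columns `channel`, `band`, `contrast`.
#' @export
bandContrastMap <- function(ft, levelHi = 7, levelLo = 1) {
  stopifnot(is(ft, "FeatureTable"))
  lv <- epochLevels(ft)
  if (!all(c(levelHi, levelLo) %in% lv))
    stop("both contrast levels must be present")
  psd <- parsePSDNames(rownames(ft))
  vals <- assay(ft, "features")
  subj <- as.character(colData(ft)$subject)
  perSubject <- vapply(unique(subj), function(s) {
    hi <- subj == s & lv == levelHi
    lo <- subj == s & lv == levelLo
    rowMeans(vals[psd$name, hi, drop = FALSE]) -
      rowMeans(vals[psd$name, lo, drop = FALSE])
  }, numeric(nrow(psd)))
  data.frame(channel = psd$channel, band = psd$band,
             contrast = rowMeans(as.matrix(perSubject)))
}

#' Chromophore level effects
#'
#' For each (site, chromophore) trace: a one-way level ANOVA on the
#' epoch-mean amplitudes, the per-level mean amplitudes, and the per-level
#' mean 3-s time-courses for plotting.
#'
#' @param fnirsEpochs An fNIRS [EpochSet-class].
#' @param adjust Post hoc p-adjustment (default `"fdr"`).
#' @return A list: `anova` (data.frame `site`, `chromophore`, `F`, `p`),
#'   `levelMeans` (data.frame `site`, `chromophore`, `level`, `mean`),
#'   `timeCourses` (array trace x sample x level).
#' @export
fnirsLevelEffects <- function(fnirsEpochs, adjust = "fdr") {
  stopifnot(is(fnirsEpochs, "EpochSet"))
  traces <- dimnames(fnirsEpochs@data)[[1]]
  lv <- epochLevels(fnirsEpochs)
  levelsPresent <- sort(unique(lv))
  d <- dim(fnirsEpochs@data)
  epochMeans <- t(apply(fnirsEpochs@data, 1L, colMeans))  # trace x epoch
  if (d[3] == 1L) epochMeans <- matrix(epochMeans, nrow = d[1])
  anovaTab <- do.call(rbind, lapply(traces, function(tr) {
    a <- levelAnova(epochMeans[match(tr, traces), ], lv, adjust = adjust)
    parts <- strsplit(tr, "_")[[1]]
    data.frame(site = parts[1], chromophore = parts[2], F = a$F, p = a$p)
  }))
  levelMeans <- do.call(rbind, lapply(traces, function(tr) {
    parts <- strsplit(tr, "_")[[1]]
    data.frame(site = parts[1], chromophore = parts[2], level = levelsPresent,
               mean = vapply(levelsPresent, function(l)
                 mean(epochMeans[match(tr, traces), lv == l]), numeric(1)))
  }))
  tc <- array(0, dim = c(d[1], d[2], length(levelsPresent)),
              dimnames = list(traces, NULL, as.character(levelsPresent)))
  for (li in seq_along(levelsPresent))
    tc[, , li] <- apply(fnirsEpochs@data[, , lv == levelsPresent[li],
                                         drop = FALSE], c(1, 2), mean)
  list(anova = anovaTab, levelMeans = levelMeans, timeCourses = tc)
}
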