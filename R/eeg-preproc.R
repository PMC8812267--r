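## EEG preprocessing: mastoid re-reference -> band-pass + notch filter ->
## downsample -> ocular-artifact removal -> 3-s epoching. The stage order is
## fixed; preprocessEEG() chains the stages.

# RBJ second-order IIR notch
notchCoefficients <- function(freq, fs, Q = 30) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Re-reference EEG to the mastoid average
#'
#' Subtracts the sample-wise mean of the two mastoid channels (M1, M2) from
#' every scalp channel, then drops M1 and M2. The auxiliary ocular channel
#' is left untouched.
#'
#' @param session A [RawSession-class].
#' @return A [RawSession-class] without the mastoid rows.
#' @export
rereferenceMastoids <- function(session) {
  stopifnot(is(session, "RawSession"))
  chans <- rownames(session@eeg)
  if (!all(c("M1", "M2") %in% chans))
    stop("mastoid channels M1 and M2 are required for re-referencing")
  ref <- (session@eeg["M1", ] + session@eeg["M2", ]) / 2
  scalp <- setdiff(session@montage, c("M1", "M2"))
  eeg <- session@eeg[setdiff(chans, c("M1", "M2")), , drop = FALSE]
  eeg[scalp, ] <- sweep(eeg[scalp, , drop = FALSE], 2L, ref, "-")
  session@eeg <- eeg
  session@montage <- scalp
  validObject(session)
  session
}

#' Band-pass and notch filter the EEG
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass followed by
#' a second-order IIR notch to every EEG row, ocular channel included.
#'
#' @param session A [RawSession-class].
#' @param low,high Band-pass corner frequencies in Hz (default 0.5-45).
#' @param notch Notch frequency in Hz (default 50, mains interference);
#'   `NA` disables the notch.
#' @param order Butterworth order (default 4), applied forward-backward.
#' @param notchQ Quality factor of the notch (default 30).
#' @return The filtered [RawSession-class].
#' @export
filterEEG <- function(session, low = 0.5, high = 45, notch = 50,
                      order = 4, notchQ = 30) {
  stopifnot(is(session, "RawSession"))
  nyq <- session@eegRate / 2
  if (high >= nyq || low <= 0)
    stop("band-pass corners must satisfy 0 < low < high < Nyquist")
  bp <- signal::butter(order, c(low, high) / nyq, type = "pass")
  session@eeg <- filtfiltRows(bp$b, bp$a, session@eeg)
  if (!is.na(notch)) {
    if (notch >= nyq) stop("notch frequency must be below Nyquist")
    nc <- notchCoefficients(notch, session@eegRate, notchQ)
    session@eeg <- filtfiltRows(nc$b, nc$a, session@eeg)
  }
  rownames(session@eeg) <- rownames(session@eeg)
  session
}

#' Downsample the EEG
#'
#' Anti-alias low-pass (zero-phase Butterworth, corner at 80% of the target
#' Nyquist) followed by cubic-spline resampling onto the target grid.
#'
#' @param session A [RawSession-class].
#' @param targetRate Target rate in Hz (default 200).
#' @return The downsampled [RawSession-class].
#' @export
downsampleEEG <- function(session, targetRate = 200) {
  stopifnot(is(session, "RawSession"))
  fs <- session@eegRate
  if (targetRate > fs) stop("target rate must not exceed the source rate")
  if (targetRate == fs) return(session)
  aa <- signal::butter(8, 0.8 * (targetRate / 2) / (fs / 2), type = "low")
  x <- filtfiltRows(aa$b, aa$a, session@eeg)
  session@eeg <- resampleRows(x, fs, targetRate)
  session@eegRate <- targetRate
  session
}

#' Remove ocular artifacts by reference-channel regression
#'
#' Regresses the auxiliary ocular channel out of every scalp channel
#' (per-channel least squares), which removes the blink transients mixed
#' into frontal electrodes. Deterministic; the scalp channel count is
#' unchanged and the ocular channel is retained for inspection (it is
#' dropped at epoching).
#'
#' @param session A [RawSession-class] whose EEG still contains the ocular
#'   channel.
#' @return The cleaned [RawSession-class].
#' @export
removeOcular <- function(session) {
  stopifnot(is(session, "RawSession"))
  eog <- session@ocularLabel
  if (!eog %in% rownames(session@eeg))
    stop("ocular reference channel '", eog, "' not present")
  if (ncol(session@eeg) <= nrow(session@eeg))
    stop("fewer samples than channels; regression is underdetermined")
  r <- session@eeg[eog, ]
  vr <- stats::var(r)
  if (vr > 0) {
    scalp <- setdiff(session@montage, c("M1", "M2"))
    beta <- as.numeric(session@eeg[scalp, , drop = FALSE] %*%
                         (r - mean(r))) / (vr * (length(r) - 1))
    session@eeg[scalp, ] <- session@eeg[scalp, , drop = FALSE] -
      outer(beta, r)
  }
  session
}

# shared epoch grid: windows of `length` seconds every `stride` seconds
# inside each difficulty segment
epochStarts <- function(events, segDur, length, stride) {
  do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    nWin <- floor((segDur - length) / stride) + 1
    if (nWin < 1) return(NULL)
    data.frame(onset = events$onset[i] + (seq_len(nWin) - 1) * stride,
               level = events$level[i], block = events$block[i])
  }))
}

epochSignal <- function(x, rate, grid, length, subject, modality) {
  nSamp <- round(length * rate)
  nEp <- if (is.null(grid)) 0L else nrow(grid)
  arr <- array(0, dim = c(nrow(x), nSamp, nEp),
               dimnames = list(rownames(x), NULL, NULL))
  keep <- logical(nEp)
  for (i in seq_len(nEp)) {
    j <- round(grid$onset[i] * rate) + seq_len(nSamp)
    if (max(j) <= ncol(x)) {
      arr[, , i] <- x[, j]
      keep[i] <- TRUE
    } else {
      message("epoch at ", grid$onset[i], " s exceeds the recording; skipped")
    }
  }
  info <- if (nEp) data.frame(subject = subject, level = grid$level,
                              block = grid$block, onset = grid$onset)[keep, , drop = FALSE]
  else data.frame(subject = character(), level = integer(),
                  block = integer(), onset = numeric())
  rownames(info) <- NULL
  new("EpochSet", data = arr[, , keep, drop = FALSE], info = info,
      rate = rate, modality = modality)
}

#' Cut the EEG into labeled 3-s epochs
#'
#' Segments each difficulty segment into windows of `length` seconds every
#' `stride` seconds, starting at the segment's stimulus onset marker. Each
#' epoch is labeled with its segment's difficulty level. Mastoid and ocular
#' channels are excluded; windows that would run past the recording are
#' skipped with a message.
#'
#' @param session A [RawSession-class] (typically already re-referenced,
#'   filtered, downsampled and artifact-cleaned).
#' @param length Window length in seconds (default 3).
#' @param stride Window stride in seconds (default 3, non-overlapping).
#' @return An [EpochSet-class] with modality `"eeg"`.
#' @export
epochEEG <- function(session, length = 3, stride = 3) {
  stopifnot(is(session, "RawSession"))
  if (length > session@blockDuration)
    stop("epoch length exceeds the segment duration")
  scalp <- setdiff(session@montage, c("M1", "M2"))
  x <- session@eeg[scalp, , drop = FALSE]
  grid <- epochStarts(session@events, session@blockDuration, length, stride)
  epochSignal(x, session@eegRate, grid, length, session@subjectID, "eeg")
}

#' Run the full EEG preprocessing chain
#'
#' Fixed stage order: mastoid re-reference, 0.5-45 Hz Butterworth band-pass
#' plus 50 Hz notch, downsample to 200 Hz, ocular regression, 3-s epoching.
#'
#' @param session A raw [RawSession-class].
#' @param stride Epoch stride in seconds (default 3).
#' @param targetRate Downsampling target in Hz (default 200).
#' @param ... Passed to [filterEEG()].
#' @return An [EpochSet-class] of clean scalp epochs.
#' @export
preprocessEEG <- function(session, stride = 3, targetRate = 200, ...) {
  session <- rereferenceMastoids(session)
  session <- filterEEG(session, ...)
  session <- downsampleEEG(session, targetRate)
  session <- removeOcular(session)
  epochEEG(session, stride = stride)
}
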