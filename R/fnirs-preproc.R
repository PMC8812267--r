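## fNIRS preprocessing: motion correction -> 0.5 Hz low-pass -> 3-s epoching
## on the same wall-clock grid as the EEG epochs.

#' Correct motion artifacts in the chromophore traces
#'
#' Robust derivative correction: first differences whose magnitude exceeds
#' `thresh` robust standard deviations (1.4826 x MAD of the first
#' difference) are replaced by the median difference of the clean samples
#' and the trace is reintegrated. This corrects both transient spikes and
#' persistent baseline steps deterministically and leaves artifact-free
#' traces untouched (at the default threshold the false-flag probability of
#' Gaussian noise is negligible, so clean statistics are not biased).
#' A trace whose differences are all flagged is passed through with a
#' warning.
#'
#' @param session A [RawSession-class].
#' @param thresh Flagging threshold in robust SDs of the first difference
#'   (default 8).
#' @return The corrected [RawSession-class].
#' @export
motionCorrect <- function(session, thresh = 8) {
  stopifnot(is(session, "RawSession"))
  for (tr in rownames(session@fnirs)) {
    x <- session@fnirs[tr, ]
    d <- diff(x)
    s <- stats::mad(d)
    if (s == 0) next                      # constant or noiseless trace
    bad <- abs(d) > thresh * s
    if (all(bad)) {
      warning("all samples of trace ", tr, " flagged; passed through")
      next
    }
    if (any(bad)) {
      d[bad] <- stats::median(d[!bad])
      session@fnirs[tr, ] <- x[1] + c(0, cumsum(d))
    }
  }
  session
}

#' Low-pass filter the chromophore traces
#'
#' Zero-phase Butterworth low-pass (order 4) at `cutoff` Hz to suppress
#' instrumental noise, cardiac and respiratory oscillations.
#'
#' @param session A [RawSession-class].
#' @param cutoff Corner frequency in Hz (default 0.5); must be below the
#'   fNIRS Nyquist frequency.
#' @return The filtered [RawSession-class].
#' @export
lowpassFNIRS <- function(session, cutoff = 0.5) {
  stopifnot(is(session, "RawSession"))
  nyq <- session@fnirsRate / 2
  if (cutoff >= nyq) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(4, cutoff / nyq, type = "low")
  session@fnirs <- filtfiltRows(bf$b, bf$a, session@fnirs)
  session
}

#' Cut the fNIRS traces into labeled 3-s epochs
#'
#' Uses the same stimulus-anchored window grid as [epochEEG()], so epoch k
#' of both modalities covers the same wall-clock window (required by the
#' neurovascular-coupling feature).
#'
#' @param session A [RawSession-class].
#' @param length Window length in seconds (default 3).
#' @param stride Window stride in seconds (default 3).
#' @return An [EpochSet-class] with modality `"fnirs"` (4 traces per epoch).
#' @export
epochFNIRS <- function(session, length = 3, stride = 3) {
  stopifnot(is(session, "RawSession"))
  if (length > session@blockDuration)
    stop("epoch length exceeds the segment duration")
  grid <- epochStarts(session@events, session@blockDuration, length, stride)
  epochSignal(session@fnirs, session@fnirsRate, grid, length,
              session@subjectID, "fnirs")
}

#' Run the full fNIRS preprocessing chain
#'
#' Motion correction, 0.5 Hz low-pass, 3-s epoching.
#'
#' @param session A raw [RawSession-class].
#' @param stride Epoch stride in seconds (default 3).
#' @param cutoff Low-pass corner in Hz (default 0.5).
#' @param thresh Motion-correction threshold (default 8 robust SDs).
#' @return An [EpochSet-class] with modality `"fnirs"`.
#' @export
preprocessFNIRS <- function(session, stride = 3, cutoff = 0.5, thresh = 8) {
  session <- motionCorrect(session, thresh = thresh)
  session <- lowpassFNIRS(session, cutoff = cutoff)
  epochFNIRS(session, stride = stride)
}
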