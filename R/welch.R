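## Welch power spectral density, vectorized over (channel, epoch) pairs.
## Defaults: 1-s Hann segments with 50% overlap on the 3-s / 200 Hz epoch,
## giving 5 averaged periodograms and a 1 Hz bin width.

hannWindow <- function(L) 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))

# Welch PSD of every (channel, epoch) series in an EpochSet.
# Returns list(freq, psd) with psd of dim (channels*epochs) x nFreq.
welchPSDMatrix <- function(arr, fs, segSeconds = 1, overlap = 0.5) {
  d <- dim(arr)
  C <- d[1]; S <- d[2]; E <- d[3]
  L <- round(segSeconds * fs)
  if (S < L) stop("epoch shorter than the Welch segment length")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, S - L + 1L, by = step)
  w <- hannWindow(L)
  nf <- floor(L / 2) + 1L
  m <- matrix(aperm(arr, c(1, 3, 2)), nrow = C * E, ncol = S)
  wm <- matrix(w, nrow = nrow(m), ncol = L, byrow = TRUE)
  acc <- matrix(0, nrow = nrow(m), ncol = nf)
  for (s in starts) {
    seg <- m[, s + 0:(L - 1), drop = FALSE] * wm
    f <- stats::mvfft(t(seg))
    acc <- acc + t(Mod(f[seq_len(nf), , drop = FALSE])^2)
  }
  scale <- rep(2, nf)
  scale[1] <- 1
  if (L %% 2 == 0) scale[nf] <- 1
  psd <- acc * matrix(scale, nrow(acc), nf, byrow = TRUE) /
    (fs * sum(w^2) * length(starts))
  list(freq = (seq_len(nf) - 1) * fs / L, psd = psd)
}

#' Welch band power per channel and epoch
#'
#' Computes the Welch power spectral density of every channel in every epoch
#' (Hann segments of `segSeconds`, `overlap` fractional overlap) and
#' integrates it over each frequency band `[lo, hi)`.
#'
#' @param epochs An [EpochSet-class].
#' @param bands A band-definition data.frame as from [bandDefinitions()].
#' @param segSeconds Welch segment length in seconds (default 1).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A numeric array channels x bands x epochs of non-negative band
#'   powers (signal-units squared).
#' @examples
#' cfg <- sessionConfig(nBlocks = 1L, blockDuration = 12, eegRate = 200,
#'                      montage = c("Fz", "O1", "M1", "M2"), noiseSd = 0,
#'                      ocularRate = 0, seed = 1)
#' ep <- epochEEG(generateSession(cfg, "S01"))
#' dim(welchBandPower(ep))   # 2 channels x 4 bands x 4 epochs
#' @export
welchBandPower <- function(epochs, bands = bandDefinitions(),
                           segSeconds = 1, overlap = 0.5) {
  stopifnot(is(epochs, "EpochSet"))
  fs <- epochs@rate
  if (any(bands$lo < 0) || any(bands$hi > fs / 2))
    stop("bands must lie inside [0, Nyquist]")
  if (any(bands$lo >= bands$hi)) stop("band lo must be < hi")
  d <- dim(epochs@data)
  out <- array(0, dim = c(d[1], nrow(bands), d[3]),
               dimnames = list(dimnames(epochs@data)[[1]], bands$name, NULL))
  if (d[3] == 0L) return(out)
  # chunk over epochs to bound the FFT working set
  chunk <- max(1L, floor(250000 / (d[1] + 1)))
  for (s in seq(1L, d[3], by = chunk)) {
    j <- s:min(s + chunk - 1L, d[3])
    ps <- welchPSDMatrix(epochs@data[, , j, drop = FALSE], fs,
                         segSeconds, overlap)
    df <- ps$freq[2] - ps$freq[1]
    for (bi in seq_len(nrow(bands))) {
      sel <- ps$freq >= bands$lo[bi] & ps$freq < bands$hi[bi]
      bp <- rowSums(ps$psd[, sel, drop = FALSE]) * df
      out[, bi, j] <- matrix(bp, d[1], length(j))
    }
  }
  out
}
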