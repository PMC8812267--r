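## Zero-phase IIR filtering and uniform resampling primitives.
##
## applyFilter() evaluates the direct-form difference equation through
## stats::filter (convolution for the numerator, recursive for the
## denominator); zeroPhase() applies it forward and backward over
## odd-reflection padding, matching the usual filtfilt behavior. Filter
## design itself comes from signal::butter / the RBJ notch formulas.

# one forward pass of the b/a difference equation
applyFilter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)                  # prime the convolution
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb - 1 + seq_along(x)]
  if (length(a) > 1)
    v <- as.numeric(stats::filter(v, -a[-1] / a[1], method = "recursive")) / a[1]
  v
}

# forward-backward (zero-phase) filtering with odd-reflection padding
zeroPhase <- function(b, a, x) {
  n <- length(x)
  np <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 10L)
  xp <- c(2 * x[1] - x[np + 1L:np][np:1], x,
          2 * x[n] - x[n - 1L:np])
  y <- applyFilter(b, a, xp)
  y <- rev(applyFilter(b, a, rev(y)))
  y[np + seq_len(n)]
}

# zero-phase filtering of every row of a matrix
filtfiltRows <- function(b, a, x) {
  out <- x
  for (i in seq_len(nrow(x))) out[i, ] <- zeroPhase(b, a, x[i, ])
  out
}

# uniform Catmull-Rom cubic resampling of every row from rate fsIn to fsOut;
# output grid starts at t = 0, length round(n * fsOut / fsIn)
resampleRows <- function(x, fsIn, fsOut, chunk = 100000L) {
  n <- ncol(x)
  nOut <- round(n * fsOut / fsIn)
  pos <- (seq_len(nOut) - 1) * fsIn / fsOut   # 0-based fractional index
  i <- pmin(pmax(floor(pos), 0), n - 1)
  u <- pos - i
  idx0 <- pmax(i - 1, 0) + 1L
  idx1 <- i + 1L
  idx2 <- pmin(i + 1, n - 1) + 1L
  idx3 <- pmin(i + 2, n - 1) + 1L
  w0 <- (-u^3 + 2 * u^2 - u) / 2
  w1 <- (3 * u^3 - 5 * u^2 + 2) / 2
  w2 <- (-3 * u^3 + 4 * u^2 + u) / 2
  w3 <- (u^3 - u^2) / 2
  out <- matrix(0, nrow(x), nOut, dimnames = list(rownames(x), NULL))
  for (s in seq(1L, nOut, by = chunk)) {
    j <- s:min(s + chunk - 1L, nOut)
    out[, j] <-
      x[, idx0[j], drop = FALSE] * rep(w0[j], each = nrow(x)) +
      x[, idx1[j], drop = FALSE] * rep(w1[j], each = nrow(x)) +
      x[, idx2[j], drop = FALSE] * rep(w2[j], each = nrow(x)) +
      x[, idx3[j], drop = FALSE] * rep(w3[j], each = nrow(x))
  }
  out
}
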