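## Welch averaged-periodogram spectral estimation. Hann-windowed overlapping
## segments, one-sided density scaling, so that sum(power) * df equals the
## variance of a demeaned input (Parseval).

#' Welch power spectral density
#'
#' One-sided Welch estimate with a Hann window and 50% segment overlap.
#' Accepts a single trace or a matrix of traces (time in rows) and, for
#' matrices, computes all spectra in one pass via the multivariate FFT.
#'
#' @param x numeric vector, or matrix with time in rows and one trace per
#'   column.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples; defaults to `min(n, 256)`.
#'   Frequencies are `k * fs / nperseg`.
#' @param overlap fractional segment overlap in `[0, 1)` (default 0.5).
#' @param demean subtract each trace's mean before estimation (default TRUE,
#'   matching mean-detrended pixel analysis).
#' @return A list with `frequency` (Hz, from 0 to `fs/2`) and `power`
#'   (density units, `x^2/Hz`): a vector for vector input, a bins-by-traces
#'   matrix for matrix input.
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 4, by = 1 / 100))
#' w <- welchPsd(x, fs = 100, nperseg = 100)
#' w$frequency[which.max(w$power)]  # 5 Hz
#' @export
welchPsd <- function(x, fs, nperseg = NULL, overlap = 0.5, demean = TRUE) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples")
  if (fs <= 0) stop("'fs' must be positive")
  if (is.null(nperseg)) nperseg <- min(n, 256L)
  nperseg <- as.integer(min(nperseg, n))
  if (nperseg < 2) stop("'nperseg' must be at least 2")
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  if (demean) x <- sweep(x, 2L, colMeans(x))

  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nperseg - 1)) / nperseg))  # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nperseg %/% 2L + 1L

  acc <- matrix(0, nfreq, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L), , drop = FALSE] * w
    X <- stats::mvfft(seg)[seq_len(nfreq), , drop = FALSE]
    acc <- acc + (Mod(X)^2) * scale
  }
  p <- acc / length(starts)
  # one-sided: double interior bins (DC, and Nyquist when nperseg is even,
  # appear once in the full spectrum)
  dbl <- seq_len(nfreq)[-1L]
  if (nperseg %% 2L == 0L) dbl <- dbl[-length(dbl)]
  p[dbl, ] <- 2 * p[dbl, ]

  freq <- (seq_len(nfreq) - 1L) * fs / nperseg
  list(frequency = freq, power = if (vec) drop(p) else p)
}

## arc length of an ordered pixel path, in px
.arcLengthPx <- function(coords) {
  if (nrow(coords) < 2) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

## local-quadratic (Savitzky-Golay-style) path smoother with one-sided
## windows at the ends; unlike a moving average it does not bend the ends
## of curved paths inward, which would bias turning-angle sums
.smoothPath <- function(v, window) {
  n <- length(v)
  half <- window %/% 2
  if (half < 1 || n < 5) return(v)
  out <- numeric(n)
  proj <- vector("list", (half + 1)^2)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    keyi <- (i - lo) * (half + 1) + (hi - i) + 1L
    p <- proj[[keyi]]
    if (is.null(p)) {
      x <- (lo:hi) - i
      X <- cbind(1, x, x^2)
      p <- solve(crossprod(X), t(X))[1, ]
      proj[[keyi]] <- p
    }
    out[i] <- sum(p * v[lo:hi])
  }
  out
}

## deterministic per-call RNG scope: runs expr with the given seed without
## clobbering the caller's RNG stream
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
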