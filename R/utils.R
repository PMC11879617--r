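#' Decibel helpers
#'
#' Convert between linear power / amplitude quantities and decibels.
#' Sound pressure levels throughout the package are referenced to 1 uPa,
#' the standard underwater-acoustics reference pressure.
#'
#' @param p linear power (or power-like) quantity
#' @param a linear amplitude quantity
#' @param db value in decibels
#' @return numeric, converted value
#' @keywords internal
#' @name db-helpers
NULL

#' @rdname db-helpers
db_from_power <- function(p) 10 * log10(p)

#' @rdname db-helpers
db_from_amplitude <- function(a) 20 * log10(a)

#' @rdname db-helpers
power_from_db <- function(db) 10^(db / 10)

#' @rdname db-helpers
amplitude_from_db <- function(db) 10^(db / 20)

#' Root-mean-square of a vector
#' @param x numeric vector
#' @keywords internal
rms <- function(x) sqrt(mean(x^2))

# Sentinel used where a level is undefined (silence, empty groups).
SENTINEL_DB <- -999

#' Kurtosis (normalised fourth moment)
#'
#' Plain kurtosis m4/m2^2 about the mean, the convention under which a
#' Gaussian signal scores 3. Returns `NA` for (near-)constant input, where
#' the statistic is undefined.
#'
#' @param x numeric vector
#' @param center subtract the mean first? Waveforms are effectively zero-mean
#'   so this matters only for envelopes; the raw (uncentred) variant is used
#'   for envelope peakedness, where the positive mean is informative.
#' @return kurtosis value, or `NA_real_` when variance is ~0
#' @export
kurtosis <- function(x, center = TRUE) {
  if (center) x <- x - mean(x)
  m2 <- mean(x^2)
  if (!is.finite(m2) || m2 <= .Machine$double.eps * max(1, mean(abs(x)))^2) {
    return(NA_real_)
  }
  mean(x^4) / m2^2
}

#' Sliding-window mean via cumulative sums
#'
#' O(n) centred moving average; the first/last `width/2` samples use the
#' truncated window that fits inside the vector.
#'
#' @param x numeric vector
#' @param width window width in samples (coerced to odd)
#' @keywords internal
moving_mean <- function(x, width) {
  n <- length(x)
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  h <- (width - 1L) %/% 2L
  if (n <= 2L * h + 1L) {
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    return((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  }
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  core <- (h + 1L):(n - h)
  out[core] <- (cs[core + h + 1L] - cs[core - h]) / width
  head_i <- seq_len(h)
  out[head_i] <- (cs[head_i + h + 1L] - cs[1L]) / (head_i + h)
  tail_i <- (n - h + 1L):n
  out[tail_i] <- (cs[n + 1L] - cs[tail_i - h]) / (n - tail_i + 1L + h)
  out
}

#' Zero-phase IIR filtering for long records
#'
#' Applies a `signal` filter object forward and backward with
#' [stats::filter()] (compiled recursion), avoiding the per-call overhead of
#' `signal::filtfilt` on multi-million-sample files. Edges are handled by
#' reflecting a short pad of the record at both ends.
#'
#' @param filt a filter object with `$b` (numerator) and `$a` (denominator)
#' @param x numeric vector
#' @return filtered vector, same length as `x`
#' @keywords internal
filtfilt_fast <- function(filt, x) {
  b <- as.numeric(filt$b)
  a <- as.numeric(filt$a)
  one_pass <- function(v) {
    u <- stats::filter(v, b, method = "convolution", sides = 1L)
    u[is.na(u)] <- 0  # leading taps of the FIR stage
    if (length(a) > 1L) {
      u <- stats::filter(u, -a[-1L] / a[1L], method = "recursive") / a[1L]
    }
    as.numeric(u)
  }
  n <- length(x)
  pad <- min(n - 1L, 3L * (length(a) + length(b)) * 10L)
  xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - seq_len(pad)])
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[pad + seq_len(n)]
}
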