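#' Spectrogram parameterisation
#'
#' Two presets are used throughout: `"display_A"` (Hann window of 5000
#' samples, DFT 8192) — the parameterisation under which the choruses and
#' pulses are measured at the native 5333 Hz rate — and `"peakfreq_B"`
#' (Hann 256, DFT 256, 80% overlap), used for peak-frequency measurement on
#' audio decimated to 250 Hz.
#'
#' @param window_size window length, samples
#' @param dft_size DFT length, samples (`>= window_size`; zero-padded)
#' @param overlap_fraction fractional overlap between segments, in `[0, 1)`
#' @param window taper name; only `"hann"` is implemented
#' @return a `spectrogram_spec` list
#' @export
spectrogram_spec <- function(window_size, dft_size = window_size,
                             overlap_fraction = 0.5, window = "hann") {
  stopifnot(dft_size >= window_size, overlap_fraction >= 0,
            overlap_fraction < 1, identical(window, "hann"))
  structure(list(window = window, window_size = as.integer(window_size),
                 dft_size = as.integer(dft_size),
                 overlap_fraction = overlap_fraction),
            class = "spectrogram_spec")
}

#' @rdname spectrogram_spec
#' @param name `"display_A"` or `"peakfreq_B"`
#' @export
preset_spec <- function(name = c("display_A", "peakfreq_B")) {
  name <- match.arg(name)
  switch(name,
    display_A  = spectrogram_spec(5000L, 8192L, overlap_fraction = 0.5),
    peakfreq_B = spectrogram_spec(256L, 256L, overlap_fraction = 0.8))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# Short-time Fourier transform: returns one-sided power spectral density per
# segment (columns = segments), scaled so that sum(density) * df equals the
# segment variance (Parseval). Vectorised over segments via mvfft.
stft_psd <- function(x, sample_rate, spec) {
  n <- length(x)
  win <- spec$window_size
  hop <- max(1L, as.integer(round(win * (1 - spec$overlap_fraction))))
  if (n < win) {
    stop("audio too short for spectral estimation: need at least ",
         win, " samples (", sprintf("%.2f", win / sample_rate), " s)")
  }
  starts <- seq.int(1L, n - win + 1L, by = hop)
  w <- hann_window(win)
  segs <- matrix(x[outer(seq_len(win) - 1L, starts, `+`)], nrow = win) * w
  if (spec$dft_size > win) {
    segs <- rbind(segs, matrix(0, spec$dft_size - win, ncol(segs)))
  }
  X <- stats::mvfft(segs)
  nfft <- spec$dft_size
  nbin <- nfft %/% 2L + 1L
  P <- (Mod(X[seq_len(nbin), , drop = FALSE])^2) / (sample_rate * sum(w^2))
  if (nbin > 2L) P[2:(nbin - 1L), ] <- 2 * P[2:(nbin - 1L), ]
  freq <- (seq_len(nbin) - 1L) * sample_rate / nfft
  list(freq = freq, power = P, t = (starts - 1L + win / 2) / sample_rate,
       resolution_hz = sample_rate / nfft)
}

#' Welch power spectral density of an audio segment
#'
#' Averages Hann-tapered, overlapping segment periodograms over the whole
#' file. The per-segment spectra are retained (`segment_density`) because the
#' chorus detector's noise estimate is a *median across time segments* —
#' that robustness to high-energy transients is lost once segments are
#' averaged.
#'
#' @param audio an [audio_segment()] (or plain numeric vector)
#' @param spec a [spectrogram_spec()]; default the `display_A` preset with
#'   50% Welch overlap
#' @param sample_rate_hz required when `audio` is a bare vector
#' @return a `psd_estimate`: `frequency_bins` (Hz), `density` (linear power
#'   per Hz, averaged), `segment_density` (bins x segments matrix),
#'   `n_segments`, `resolution_hz`, `sample_rate_hz`
#' @export
compute_psd <- function(audio, spec = preset_spec("display_A"),
                        sample_rate_hz = NULL) {
  if (inherits(audio, "audio_segment")) {
    x <- audio$samples
    sample_rate_hz <- audio$sample_rate_hz
  } else {
    stopifnot(!is.null(sample_rate_hz))
    x <- as.numeric(audio)
  }
  s <- stft_psd(x, sample_rate_hz, spec)
  structure(list(frequency_bins = s$freq,
                 density = rowMeans(s$power),
                 segment_density = s$power,
                 n_segments = ncol(s$power),
                 resolution_hz = s$resolution_hz,
                 sample_rate_hz = sample_rate_hz),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins to %.1f Hz, %d segments, df = %.3f Hz\n",
              length(x$frequency_bins), max(x$frequency_bins), x$n_segments,
              x$resolution_hz))
  invisible(x)
}

# indices of PSD bins whose centres fall in [f_low, f_high)
band_bins <- function(psd, f_low, f_high) {
  which(psd$frequency_bins >= f_low & psd$frequency_bins < f_high)
}

#' Integrated power in a frequency band
#'
#' Integral of the PSD over `[f_low, f_high)`, half-open in bin space so that
#' adjoining bands never double count a bin. With the Welch scaling used
#' here, the full-band integral equals the signal variance (Parseval).
#'
#' @param psd a `psd_estimate`
#' @param f_low,f_high band edges in Hz, `0 <= f_low < f_high <=` Nyquist
#' @return band power (pressure-squared units, e.g. uPa^2)
#' @export
band_power <- function(psd, f_low, f_high) {
  nyq <- max(psd$frequency_bins)
  if (!(f_low >= 0 && f_low < f_high)) stop("invalid band: need 0 <= f_low < f_high")
  if (f_high > nyq + psd$resolution_hz) stop("band exceeds Nyquist (", nyq, " Hz)")
  idx <- band_bins(psd, f_low, f_high)
  sum(psd$density[idx]) * psd$resolution_hz
}

#' Decimate audio to a lower sampling rate
#'
#' Anti-alias lowpass (long linear-phase FIR with a Blackman taper, cutoff at
#' 0.84 of the new Nyquist, applied via overlap-add FFT convolution with the
#' group delay removed) followed by linear interpolation onto the new sample
#' grid. Content below the new Nyquist is preserved in frequency to within
#' one analysis bin; in steady state, energy above it is suppressed by well
#' over 60 dB. Within about one filter length (~0.4 s at the native 5333 Hz
#' rate) of the record ends the suppression is edge-limited, as for any
#' finite-record filter; selections should avoid the extreme edges.
#'
#' @param audio an [audio_segment()]
#' @param target_rate_hz new sampling rate, must be below the native rate
#' @return a decimated [audio_segment()]
#' @export
decimate_to <- function(audio, target_rate_hz) {
  stopifnot(inherits(audio, "audio_segment"))
  fs <- audio$sample_rate_hz
  if (target_rate_hz >= fs) {
    stop("target rate (", target_rate_hz, " Hz) must be below the native rate (",
         fs, " Hz)")
  }
  x <- audio$samples
  cutoff <- 0.84 * target_rate_hz / 2
  ntap <- 2000L
  if (length(x) <= 3L * ntap) ntap <- max(8L, 2L * (length(x) %/% 6L))
  h <- signal::fir1(ntap, cutoff / (fs / 2), type = "low",
                    window = signal::blackman(ntap + 1L))
  # mirror padding: the reflected signal continues the local waveform, so no
  # broadband edge transient is excited at the joins
  pad <- min(ntap, length(x))
  xp <- c(x[pad:1], x, x[length(x) - seq_len(pad) + 1L])
  y <- signal::fftfilt(h, c(xp, rep(0, ntap)))
  y <- y[pad + ntap / 2 + seq_along(x)]   # remove group delay ntap/2
  t_old <- (seq_along(x) - 1) / fs
  t_new <- seq(0, t_old[length(t_old)], by = 1 / target_rate_hz)
  xn <- stats::approx(t_old, y, xout = t_new)$y
  audio_segment(xn, target_rate_hz, calibrated = audio$calibrated,
                meta = audio$meta, file_id = audio$file_id)
}
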