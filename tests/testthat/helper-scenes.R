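# Shared synthetic fixtures, built once per test run. Short (2 min) files
# keep unit tests fast; the calibration suite builds its own full-length
# scenes.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

noise_scene_2min <- function() {
  fixture("noise_2min", function() {
    render_scene(scene_config(file_duration_s = 120, rng_seed = 101))
  })
}

chorus_scene_2min <- function() {
  fixture("chorus_2min", function() {
    render_scene(scene_config(file_duration_s = 120,
                              chorus_level_db = c(lfc = 10, hfc99 = 8),
                              rng_seed = 102))
  })
}

pulse_scene_10min <- function() {
  fixture("pulse_10min", function() {
    render_scene(scene_config(file_duration_s = 600, pulse_rate_per_file = 20,
                              pulse_rl_db = c(120, 135), rng_seed = 103))
  })
}

# brute-force single-shot periodogram band power (independent of the Welch
# path: one full-length DFT, naive bin loop). A Hann taper controls leakage
# from the strong low-frequency end of 1/f ambient spectra, which would
# otherwise swamp narrow bands under a rectangular window.
oracle_band_power <- function(x, fs, f_low, f_high) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  X <- stats::fft(x * w)
  freq <- (seq_len(n) - 1) * fs / n
  p <- 0
  for (i in seq_len(n %/% 2 + 1)) {
    if (freq[i] >= f_low && freq[i] < f_high) {
      scale <- if (i == 1 || (n %% 2 == 0 && i == n %/% 2 + 1)) 1 else 2
      p <- p + scale * Mod(X[i])^2 / (n^2 * mean(w^2))
    }
  }
  p
}

# brute-force band SNR recomputed from the retained per-segment spectra with
# naive loops (independent of compute_band_snr's vectorised path)
oracle_band_snr <- function(psd, signal_band, noise_bands) {
  f <- psd$frequency_bins
  sig_idx <- which(f >= signal_band[1] & f < signal_band[2])
  sig <- mean(psd$density[sig_idx])
  seg_noise <- numeric(psd$n_segments)
  for (s in seq_len(psd$n_segments)) {
    vals <- c()
    for (b in noise_bands) {
      idx <- which(f >= b[1] & f < b[2])
      vals <- c(vals, psd$segment_density[idx, s])
    }
    seg_noise[s] <- mean(vals)
  }
  10 * log10(sig / stats::median(seg_noise))
}

# brute-force PSD area: explicit trapezoid sums
oracle_psd_area <- function(psd, band, guard_hz = 2) {
  f <- psd$frequency_bins
  idx <- which(f >= band[1] & f < band[2])
  d <- psd$density[idx]; fb <- f[idx]
  lev_lo <- stats::median(psd$density[f >= band[1] - guard_hz & f < band[1]])
  lev_hi <- stats::median(psd$density[f >= band[2] & f < band[2] + guard_hz])
  base <- lev_lo + (lev_hi - lev_lo) * (fb - band[1]) / (band[2] - band[1])
  tz <- function(y) {
    s <- 0
    for (i in seq_len(length(y) - 1)) s <- s + (y[i] + y[i + 1]) / 2 * (fb[i + 1] - fb[i])
    s
  }
  tz(d - base) / tz(base)
}

# brute-force tie-corrected Kruskal-Wallis H via explicit rank arithmetic
oracle_kruskal_h <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  H <- 0
  for (g in levels(groups)) {
    idx <- groups == g
    H <- H + sum(r[idx])^2 / sum(idx)
  }
  H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}
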