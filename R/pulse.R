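#' Decision-tree thresholds for 20-Hz pulse detection
#'
#' The detector combines waveform kurtosis, a kurtosis product, spectral and
#' temporal SNR and a signal-bandwidth count in a multi-step decision. The
#' main branch requires signal kurtosis > 3.25, kurtosis product > 40,
#' spectral SNR > 9 dB and temporal SNR > -2 dB. Within a chorus a fainter
#' pulse (temporal SNR > -7 dB) is still accepted if it is broadband
#' (bandwidth count > 75) and clearly peaked (kurtosis > 4).
#'
#' @param signal_kurtosis main-branch kurtosis threshold
#' @param kurtosis_product waveform-kurtosis x envelope-kurtosis threshold
#' @param spectral_snr dB
#' @param temporal_snr main-branch temporal SNR threshold, dB (may be
#'   negative: a window's envelope peak is compared against the file-wide
#'   median envelope, which a chorus can raise above local peaks)
#' @param temporal_snr_2 faint-in-chorus temporal SNR threshold, dB
#' @param signal_bandwidth bandwidth count threshold (DFT bins above half
#'   the in-band peak; see [extract_pulse_features()])
#' @param signal_kurtosis_1_2 faint-branch kurtosis threshold
#' @return a `pulse_thresholds` list
#' @export
pulse_thresholds <- function(signal_kurtosis = 3.25, kurtosis_product = 40,
                             spectral_snr = 9, temporal_snr = -2,
                             temporal_snr_2 = -7, signal_bandwidth = 75,
                             signal_kurtosis_1_2 = 4) {
  stopifnot(temporal_snr_2 <= temporal_snr,
            signal_kurtosis_1_2 >= signal_kurtosis)
  structure(list(signal_kurtosis = signal_kurtosis,
                 kurtosis_product = kurtosis_product,
                 spectral_snr = spectral_snr, temporal_snr = temporal_snr,
                 temporal_snr_2 = temporal_snr_2,
                 signal_bandwidth = signal_bandwidth,
                 signal_kurtosis_1_2 = signal_kurtosis_1_2),
            class = "pulse_thresholds")
}

#' Detector geometry
#'
#' A ~1 s pulse must be a *transient* within its feature window for kurtosis
#' to separate it from noise: over a context window of `context_s` seconds a
#' clean pulse occupying fraction p has waveform kurtosis ~1.5/p and raw
#' envelope kurtosis ~1/p, so with the 8 s default a clean pulse scores
#' kurtosis ~= 9-12 and kurtosis product well above 40, while Gaussian noise
#' sits at 3 and ~3x1.1. Candidates are localised at band-limited envelope
#' peaks rather than on a fixed grid; `hop_s` defines the window grid used
#' for false-positive-rate bookkeeping. Analysis runs at a working rate of
#' ~500 Hz (all pulse content lies below 40 Hz), where the 15-26 Hz bandpass
#' is numerically comfortable; `corners_hz` are the filter's -3 dB corner
#' frequencies, placed just outside the band so 15-26 Hz is passed flat.
#'
#' @param band pulse analysis band, Hz (15-26)
#' @param corners_hz bandpass corner frequencies, Hz
#' @param context_s feature context window, s
#' @param hop_s nominal analysis hop, s (FPR bookkeeping unit)
#' @param min_separation_s minimum spacing between candidate peaks, s
#' @param envelope_s moving-RMS envelope window, s
#' @param peak_dominance_db a candidate's envelope peak must be within this
#'   many dB of the context window's envelope maximum — rejects the noise
#'   peaks flanking a loud pulse, whose context features are dominated by
#'   that pulse, while keeping similar-amplitude pulses a few seconds apart
#' @param work_rate_hz target working sample rate, Hz
#' @param edge_guard_s candidates this close to the record ends are ignored
#'   (bandpass settling transients make features unreliable there)
#' @export
pulse_detector_config <- function(band = c(15, 26), corners_hz = c(14, 27.5),
                                  context_s = 8, hop_s = 0.5,
                                  min_separation_s = 0.8, envelope_s = 0.1,
                                  peak_dominance_db = 6, work_rate_hz = 500,
                                  edge_guard_s = 1) {
  list(band = band, corners_hz = corners_hz, context_s = context_s,
       hop_s = hop_s, min_separation_s = min_separation_s,
       envelope_s = envelope_s, peak_dominance_db = peak_dominance_db,
       work_rate_hz = work_rate_hz, edge_guard_s = edge_guard_s)
}

# boxcar prefilter + pick-every-Rth decimation to the detector working rate;
# all pulse-band content sits far below the post-decimation Nyquist, and the
# boxcar suppresses the folding bands by > 20 dB (on 1/f ambient spectra the
# residual alias power in 15-26 Hz is negligible)
decimate_boxcar <- function(x, fs, work_rate) {
  r <- max(1L, floor(fs / work_rate))
  if (r == 1L) return(list(x = x, fs = fs, r = 1L))
  xm <- moving_mean(x, r)
  idx <- seq.int(1L, length(x), by = r)
  list(x = xm[idx], fs = fs / r, r = r)
}

# band-limited waveform and moving-RMS envelope at the working rate
pulse_band_envelope <- function(x, fs, config) {
  d <- decimate_boxcar(x, fs, config$work_rate_hz)
  bf <- signal::butter(4, config$corners_hz / (d$fs / 2), type = "pass")
  xb <- filtfilt_fast(bf, d$x)
  env <- sqrt(pmax(moving_mean(xb^2, round(config$envelope_s * d$fs)), 0))
  list(xb = xb, env = env, xd = d$x, fs = d$fs)
}

# indices of local maxima of env satisfying a logical gate
local_maxima <- function(env, gate) {
  n <- length(env)
  if (n < 3) return(integer(0))
  is_max <- c(FALSE, env[2:(n - 1)] > env[1:(n - 2)] &
                     env[2:(n - 1)] >= env[3:n], FALSE)
  which(is_max & gate)
}

# greedy minimum-separation thinning, strongest (highest env) first
greedy_separate <- function(cand, env, fs, min_sep_s) {
  if (length(cand) < 2) return(cand)
  cand <- cand[order(env[cand], decreasing = TRUE)]
  sep <- round(min_sep_s * fs)
  taken <- integer(0)
  for (c0 in cand) {
    if (!length(taken) || all(abs(taken - c0) >= sep)) taken <- c(taken, c0)
  }
  sort(taken)
}

# features for a candidate centred at working-rate sample ic
pulse_features_at <- function(be, ic, med_env, config,
                              window_override = NULL) {
  fs <- be$fs
  half <- round(config$context_s * fs / 2)
  if (is.null(window_override)) {
    i0 <- max(1L, ic - half); i1 <- min(length(be$xd), ic + half)
  } else {
    i0 <- window_override[1]; i1 <- window_override[2]
  }
  idx <- i0:i1
  xb <- be$xb[idx]
  env <- be$env[idx]
  k <- kurtosis(xb)
  env_k <- kurtosis(env, center = FALSE)
  kprod <- k * env_k
  tsnr <- db_from_amplitude(max(env) / med_env)
  # spectral features on the raw (decimated, unfiltered) context window
  w <- be$xd[idx] * hann_window(length(idx))
  nfft <- 2^ceiling(log2(max(length(w), 16)))
  P <- Mod(stats::fft(c(w, rep(0, nfft - length(w)))))^2
  nbin <- nfft %/% 2 + 1
  freq <- (seq_len(nbin) - 1) * fs / nfft
  P <- P[seq_len(nbin)]
  inb <- freq >= config$band[1] & freq < config$band[2]
  outb <- (freq >= config$band[1] - 7 & freq < config$band[1] - 1) |
          (freq >= config$band[2] + 1 & freq < config$band[2] + 7)
  peak <- max(P[inb])
  ssnr <- db_from_power(peak / stats::median(P[outb]))
  bw_region <- freq >= 10 & freq < 40
  bandwidth <- sum(P[bw_region] > peak / 2)
  data.frame(signal_kurtosis = k, kurtosis_product = kprod,
             spectral_snr_db = ssnr, temporal_snr_db = tsnr,
             signal_bandwidth = bandwidth,
             t_begin_s = (i0 - 1) / fs, t_end_s = i1 / fs)
}

#' Apply the multi-step pulse decision to a feature vector
#'
#' The main branch requires signal kurtosis, kurtosis product, spectral SNR
#' and temporal SNR above their thresholds. When a chorus is present, a
#' window failing only the temporal-SNR step is still accepted down to the
#' relaxed `temporal_snr_2` threshold, provided its bandwidth count exceeds
#' `signal_bandwidth` and its kurtosis exceeds the stricter
#' `signal_kurtosis_1_2` — a fainter but clearly pulse-like transient inside
#' the chorus.
#'
#' @param features one-row data.frame from [extract_pulse_features()]
#' @param thresholds a [pulse_thresholds()]
#' @param chorus_present enables the faint branch
#' @return `"main"`, `"faint-in-chorus"`, or `NA` (rejected)
#' @export
decide_pulse_branch <- function(features, thresholds = pulse_thresholds(),
                                chorus_present = FALSE) {
  ft <- features
  if (!all(is.finite(c(ft$signal_kurtosis, ft$kurtosis_product,
                       ft$spectral_snr_db, ft$temporal_snr_db)))) {
    return(NA_character_)  # degenerate window (e.g. zero variance)
  }
  main_ok <- ft$signal_kurtosis > thresholds$signal_kurtosis &&
    ft$kurtosis_product > thresholds$kurtosis_product &&
    ft$spectral_snr_db > thresholds$spectral_snr
  if (main_ok && ft$temporal_snr_db > thresholds$temporal_snr) {
    return("main")
  }
  if (chorus_present && main_ok &&
      ft$temporal_snr_db > thresholds$temporal_snr_2 &&
      ft$signal_bandwidth > thresholds$signal_bandwidth &&
      ft$signal_kurtosis > thresholds$signal_kurtosis_1_2) {
    return("faint-in-chorus")
  }
  NA_character_
}

#' Decision-tree features for one analysis window
#'
#' Computed on an analysis window of the 15-26 Hz band-limited signal:
#' `signal_kurtosis` is the kurtosis of the band-limited waveform;
#' `kurtosis_product` multiplies it by the raw (uncentred) kurtosis of the
#' moving-RMS envelope, which is ~1 for stationary noise and large for an
#' isolated transient; `temporal_snr_db` compares the window's envelope
#' peak to the file-wide median envelope; `spectral_snr_db` compares the
#' in-band spectral peak to the median density in the neighbouring
#' out-of-band region (8-14 and 27-33 Hz); `signal_bandwidth` counts DFT
#' bins in 10-40 Hz whose power exceeds half the in-band peak — large for a
#' downsweep that spreads energy across the band, small for tonal or
#' narrowband noise peaks (the count is taken at ~0.065 Hz/bin, the
#' detector's native resolution for an 8 s context).
#'
#' @param audio an [audio_segment()]
#' @param window `c(t_begin, t_end)` seconds within the file, >= 0.5 s long
#' @param config a [pulse_detector_config()]
#' @return a one-row data.frame of features
#' @export
extract_pulse_features <- function(audio, window,
                                   config = pulse_detector_config()) {
  stopifnot(inherits(audio, "audio_segment"))
  if (diff(window) < 0.5) stop("analysis window shorter than 0.5 s")
  be <- pulse_band_envelope(audio$samples, audio$sample_rate_hz, config)
  med_env <- stats::median(be$env)
  i0 <- max(1L, round(window[1] * be$fs) + 1L)
  i1 <- min(length(be$xd), round(window[2] * be$fs))
  pulse_features_at(be, (i0 + i1) %/% 2L, med_env, config,
                    window_override = c(i0, i1))
}

#' Detect 20-Hz pulses in a file
#'
#' Localises candidate pulses at peaks of the 15-26 Hz moving-RMS envelope,
#' computes the decision-tree features on a context window around each, and
#' accepts a candidate on the main branch (kurtosis, kurtosis product,
#' spectral SNR, temporal SNR > -2 dB) or — only when `chorus_present` — on
#' the faint-in-chorus branch (temporal SNR > -7 dB with bandwidth > 75 and
#' kurtosis > 4). Cheap moment features computed from cumulative sums gate
#' the candidates so the per-candidate FFT only runs where a pulse is
#' plausible. Overlapping accepted windows are merged; each detection's
#' time support is the envelope's quarter-peak extent (clamped to
#' 0.5-2.5 s) and its SPL_rms over 15-26 Hz is recorded.
#'
#' @param audio a calibrated [audio_segment()]
#' @param thresholds a [pulse_thresholds()]
#' @param chorus_present was the low-frequency chorus detected in this file?
#'   (enables the faint branch)
#' @param config a [pulse_detector_config()]
#' @return data.frame: file_id, t_begin_s, t_end_s, branch, features,
#'   spl_rms_db, calibrated
#' @export
detect_pulses <- function(audio, thresholds = pulse_thresholds(),
                          chorus_present = FALSE,
                          config = pulse_detector_config()) {
  stopifnot(inherits(audio, "audio_segment"))
  if (!audio$calibrated) {
    warning("audio is uncalibrated; SPL_rms values are relative, not dB re 1 uPa")
  }
  be <- pulse_band_envelope(audio$samples, audio$sample_rate_hz, config)
  fs <- be$fs
  n <- length(be$xd)
  med_env <- stats::median(be$env)
  empty <- data.frame(file_id = character(), t_begin_s = numeric(),
                      t_end_s = numeric(), branch = character(),
                      signal_kurtosis = numeric(), kurtosis_product = numeric(),
                      spectral_snr_db = numeric(), temporal_snr_db = numeric(),
                      signal_bandwidth = numeric(), spl_rms_db = numeric(),
                      calibrated = logical(), stringsAsFactors = FALSE)
  if (med_env <= 0) return(empty)
  floor_gate <- med_env * amplitude_from_db(min(thresholds$temporal_snr,
                                                thresholds$temporal_snr_2))
  guard <- round(config$edge_guard_s * fs)
  in_bounds <- seq_len(n) > guard & seq_len(n) <= n - guard
  cands <- local_maxima(be$env, be$env > floor_gate & in_bounds)
  if (length(cands)) {
    # cheap moment kurtoses at the candidate positions via cumulative sums
    half <- round(config$context_s * fs / 2)
    cs2 <- cumsum(c(0, be$xb^2)); cs4 <- cumsum(c(0, be$xb^4))
    ce2 <- cumsum(c(0, be$env^2)); ce4 <- cumsum(c(0, be$env^4))
    lo <- pmax(cands - half, 1L); hi <- pmin(cands + half, n)
    nw <- hi - lo + 1
    k_c <- ((cs4[hi + 1L] - cs4[lo]) / nw) /
           pmax((cs2[hi + 1L] - cs2[lo]) / nw, 1e-300)^2
    ek_c <- ((ce4[hi + 1L] - ce4[lo]) / nw) /
            pmax((ce2[hi + 1L] - ce2[lo]) / nw, 1e-300)^2
    cands <- cands[k_c > thresholds$signal_kurtosis &
                   k_c * ek_c > thresholds$kurtosis_product]
  }
  cands <- greedy_separate(cands, be$env, fs, config$min_separation_s)
  rows <- list()
  half <- round(config$context_s * fs / 2)
  dom <- amplitude_from_db(-config$peak_dominance_db)
  for (ic in cands) {
    ctx <- max(1L, ic - half):min(n, ic + half)
    if (be$env[ic] < dom * max(be$env[ctx])) next
    ft <- pulse_features_at(be, ic, med_env, config)
    branch <- decide_pulse_branch(ft, thresholds, chorus_present)
    if (is.na(branch)) next
    # time support: envelope quarter-peak extent around the candidate (the
    # lower fraction compensates the envelope rise time, keeping reported
    # onsets close to the true signal onset)
    q_peak <- be$env[ic] / 4
    lo <- ic; while (lo > 1 && be$env[lo - 1] > q_peak &&
                     (ic - lo) / fs < 1.25) lo <- lo - 1
    hi <- ic; while (hi < n && be$env[hi + 1] > q_peak &&
                     (hi - ic) / fs < 1.25) hi <- hi + 1
    if ((hi - lo) / fs < 0.5) {
      pad <- round(0.25 * fs)
      lo <- max(1L, ic - pad); hi <- min(n, ic + pad)
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(file_id = audio$file_id, t_begin_s = (lo - 1) / fs,
                 t_end_s = hi / fs, branch = branch,
                 stringsAsFactors = FALSE),
      ft[, c("signal_kurtosis", "kurtosis_product", "spectral_snr_db",
             "temporal_snr_db", "signal_bandwidth")],
      data.frame(spl_rms_db = db_from_amplitude(rms(be$xb[lo:hi])),
                 calibrated = audio$calibrated))
  }
  if (!length(rows)) return(empty)
  det <- do.call(rbind, rows)
  det <- det[order(det$t_begin_s), , drop = FALSE]
  # merge overlapping detections: union of time supports, features of the
  # stronger (higher temporal SNR) member
  merged <- det[1, , drop = FALSE]
  if (nrow(det) > 1) {
    for (j in 2:nrow(det)) {
      last <- nrow(merged)
      if (det$t_begin_s[j] < merged$t_end_s[last]) {
        t0 <- min(merged$t_begin_s[last], det$t_begin_s[j])
        t1 <- max(merged$t_end_s[last], det$t_end_s[j])
        if (det$temporal_snr_db[j] > merged$temporal_snr_db[last]) {
          merged[last, ] <- det[j, ]
        }
        merged$t_begin_s[last] <- t0
        merged$t_end_s[last] <- t1
      } else {
        merged <- rbind(merged, det[j, ])
      }
    }
  }
  det <- merged
  det$t_end_s <- pmin(det$t_end_s, det$t_begin_s + 2.5)
  rownames(det) <- NULL
  det
}

#' Band-limited SPL_rms of an audio snippet
#'
#' RMS sound pressure level (dB re 1 uPa) of the 15-26 Hz band-filtered
#' snippet, the quantity compared against modelled received levels for the
#' detection-range attribution. Filtering happens zero-phase at the
#' detector working rate with corners placed so the band is passed flat.
#'
#' @param audio a calibrated [audio_segment()]
#' @param window `c(t_begin, t_end)` in seconds; default the whole segment
#' @param config a [pulse_detector_config()] (defines band and corners)
#' @return SPL in dB re 1 uPa (the silence sentinel `-999` for zero signal)
#' @export
spl_rms <- function(audio, window = NULL, config = pulse_detector_config()) {
  stopifnot(inherits(audio, "audio_segment"))
  d <- decimate_boxcar(audio$samples, audio$sample_rate_hz,
                       config$work_rate_hz)
  bf <- signal::butter(4, config$corners_hz / (d$fs / 2), type = "pass")
  xb <- filtfilt_fast(bf, d$x)
  if (!is.null(window)) {
    if (diff(window) <= 0) stop("zero-length window")
    i0 <- max(1L, round(window[1] * d$fs) + 1L)
    i1 <- min(length(xb), round(window[2] * d$fs))
    if (i1 < i0) stop("window outside audio")
    xb <- xb[i0:i1]
  }
  r <- rms(xb)
  if (r <= 0) return(SENTINEL_DB)
  db_from_amplitude(r)
}
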