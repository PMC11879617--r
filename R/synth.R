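#' Template for a fin whale 20-Hz pulse
#'
#' The 20-Hz pulse is a short (~1 s), loud downsweep from about 28 Hz to
#' about 15 Hz, with reported source levels of 160-186 dB re 1 uPa at 1 m.
#' Some populations produce a simultaneous faint narrowband high-frequency
#' (HF) component whose peak frequency (near 86 or 99 Hz) distinguishes
#' acoustic populations; its amplitude is below that of the 20-Hz pulse.
#'
#' @param duration_s pulse duration, seconds
#' @param f_start_hz,f_end_hz sweep start/end frequency, Hz (`f_start > f_end`)
#' @param source_level_db source level, dB re 1 uPa at 1 m
#' @param hf_peak_hz peak frequency of the HF component, Hz, or `NULL` for a
#'   pulse without HF component; must fall inside exactly one of the HF
#'   detection bands (84-87 or 96-100 Hz)
#' @param hf_bandwidth_hz nominal HF component width, Hz (used by the scene
#'   generator to jitter per-pulse peaks)
#' @param hf_level_offset_db HF level relative to the pulse, dB (negative)
#' @return a `pulse_template` list
#' @export
pulse_template <- function(duration_s = 1.0, f_start_hz = 28, f_end_hz = 15,
                           source_level_db = 180, hf_peak_hz = NULL,
                           hf_bandwidth_hz = 3, hf_level_offset_db = -10) {
  stopifnot(duration_s > 0, f_start_hz > f_end_hz, f_end_hz > 0)
  if (source_level_db < 160 || source_level_db > 186) {
    warning("source level ", source_level_db,
            " dB is outside the reported 160-186 dB range")
  }
  if (!is.null(hf_peak_hz)) {
    in86 <- hf_peak_hz >= 84 && hf_peak_hz < 87
    in99 <- hf_peak_hz >= 96 && hf_peak_hz < 100
    if (!xor(in86, in99)) {
      stop("hf_peak_hz must lie inside exactly one HF detection band ",
           "(84-87 or 96-100 Hz); got ", hf_peak_hz)
    }
    stopifnot(hf_level_offset_db < 0)
  }
  structure(list(duration_s = duration_s, f_start_hz = f_start_hz,
                 f_end_hz = f_end_hz, source_level_db = source_level_db,
                 hf_peak_hz = hf_peak_hz, hf_bandwidth_hz = hf_bandwidth_hz,
                 hf_level_offset_db = hf_level_offset_db),
            class = "pulse_template")
}

# raised-cosine (Tukey) taper; frac = fraction of the length tapered at EACH end
tukey_taper <- function(n, frac = 0.1) {
  m <- max(1L, round(n * frac))
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(m) / m)
  c(ramp, rep(1, n - 2L * m), rev(ramp))
}

#' Render one 20-Hz pulse at a given received level
#'
#' Produces a linear downsweep with a 10% raised-cosine onset/offset taper,
#' scaled so the RMS pressure of the sweep equals the requested received
#' level (dB re 1 uPa). When the template carries an HF component, a tapered
#' narrowband tone at `hf_peak_hz` with RMS `rl_db + hf_level_offset_db` is
#' added over the same time support.
#'
#' @param template a [pulse_template()]
#' @param rl_db received level of the 20-Hz sweep, dB re 1 uPa (RMS)
#' @param sample_rate_hz sampling rate, Hz
#' @param hf_peak_hz optional override of the template's HF peak (used by the
#'   scene generator to jitter per-pulse peaks)
#' @return numeric pressure waveform, uPa
#' @export
render_pulse <- function(template, rl_db, sample_rate_hz, hf_peak_hz = NULL) {
  stopifnot(inherits(template, "pulse_template"))
  if (rl_db > template$source_level_db) {
    stop("received level (", rl_db, " dB) cannot exceed the source level (",
         template$source_level_db, " dB)")
  }
  if (is.null(hf_peak_hz)) hf_peak_hz <- template$hf_peak_hz
  fmax <- max(template$f_start_hz, if (is.null(hf_peak_hz)) 0 else hf_peak_hz)
  if (sample_rate_hz < 2.2 * fmax) {
    stop("sample rate ", sample_rate_hz, " Hz is below the Nyquist margin for ",
         fmax, " Hz content (need >= ", 2.2 * fmax, " Hz)")
  }
  n <- max(4L, round(template$duration_s * sample_rate_hz))
  t <- (seq_len(n) - 1) / sample_rate_hz
  # linear sweep: instantaneous frequency f_start -> f_end
  k <- (template$f_end_hz - template$f_start_hz) / template$duration_s
  phase <- 2 * pi * (template$f_start_hz * t + 0.5 * k * t^2)
  taper <- tukey_taper(n, 0.1)
  sweep <- sin(phase) * taper
  sweep <- sweep / rms(sweep) * amplitude_from_db(rl_db)
  if (!is.null(hf_peak_hz)) {
    hf <- sin(2 * pi * hf_peak_hz * t) * taper
    hf <- hf / rms(hf) * amplitude_from_db(rl_db + template$hf_level_offset_db)
    sweep <- sweep + hf
  }
  sweep
}

#' Configuration of a synthetic acoustic scene
#'
#' Defines the study conditions for the generator: 10-minute files at
#' 5333 Hz (144 consecutive files tile one nominal day), a configurable mean
#' number of foreground pulses per file, per-band diffuse chorus elevations,
#' 1/f-shaped ambient noise, and broadband high-energy transients.
#'
#' @param file_duration_s file duration, seconds
#' @param sample_rate_hz sampling rate, Hz
#' @param n_files number of files to generate
#' @param pulse_rate_per_file mean count of foreground pulses per file
#'   (Poisson), or the exact count when `song_ini_s` is set
#' @param song_ini_s optional regular inter-note interval, seconds; when set,
#'   pulses are laid out as a regular song with this spacing
#' @param chorus_level_db named vector `c(lfc=, hfc86=, hfc99=)`: in-band
#'   energy elevation of the diffuse chorus above ambient, dB (0 = absent)
#' @param noise list: `rms_db` broadband ambient RMS (dB re 1 uPa), `kind`
#'   `"pink"` (1/f-shaped) or `"white"`
#' @param transient_rate mean count of broadband transients per file
#' @param pulse_rl_db range (min, max) of foreground pulse received levels,
#'   dB re 1 uPa, drawn uniformly
#' @param rng_seed integer seed; identical configs give bit-identical scenes
#' @return a `scene_config` list
#' @export
scene_config <- function(file_duration_s = 600, sample_rate_hz = 5333,
                         n_files = 1L, pulse_rate_per_file = 0,
                         song_ini_s = NULL,
                         chorus_level_db = c(lfc = 0, hfc86 = 0, hfc99 = 0),
                         noise = list(rms_db = 110, kind = "pink"),
                         transient_rate = 0,
                         pulse_rl_db = c(115, 135),
                         rng_seed = 1L) {
  lv <- c(lfc = 0, hfc86 = 0, hfc99 = 0)
  lv[names(chorus_level_db)] <- chorus_level_db
  stopifnot(file_duration_s > 0, sample_rate_hz > 2 * 100,
            n_files >= 1, pulse_rate_per_file >= 0, all(lv >= 0),
            transient_rate >= 0, length(pulse_rl_db) == 2)
  structure(list(file_duration_s = file_duration_s,
                 sample_rate_hz = sample_rate_hz, n_files = as.integer(n_files),
                 pulse_rate_per_file = pulse_rate_per_file,
                 song_ini_s = song_ini_s, chorus_level_db = lv,
                 noise = noise, transient_rate = transient_rate,
                 pulse_rl_db = pulse_rl_db, rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

# 1/f-shaped ambient noise: parallel one-pole bank (Kellet coefficients)
# collapsed to a single ARMA(3,3) pass, scaled to the requested broadband
# RMS in uPa.
pink_arma <- local({
  poles <- c(0.99765, 0.96300, 0.57000)
  gains <- c(0.0990460, 0.2965164, 1.0526913)
  direct <- 0.1848
  conv <- function(p, q) {
    r <- numeric(length(p) + length(q) - 1L)
    for (i in seq_along(p)) r[i + seq_along(q) - 1L] <- r[i + seq_along(q) - 1L] + p[i] * q
    r
  }
  a <- Reduce(conv, lapply(poles, function(p) c(1, -p)))   # denominator
  b <- direct * a
  for (i in seq_along(poles)) {
    num <- Reduce(conv, lapply(poles[-i], function(p) c(1, -p)))
    b[seq_along(num)] <- b[seq_along(num)] + gains[i] * num
  }
  list(b = b, a = a)
})

render_ambient <- function(n, rms_db, kind = "pink") {
  w <- stats::rnorm(n)
  if (identical(kind, "white")) {
    x <- w
  } else {
    u <- stats::filter(w, pink_arma$b, method = "convolution", sides = 1L)
    u[seq_len(length(pink_arma$b) - 1L)] <- w[seq_len(length(pink_arma$b) - 1L)]
    x <- as.numeric(stats::filter(u, -pink_arma$a[-1L], method = "recursive"))
  }
  x / rms(x) * amplitude_from_db(rms_db)
}

# band power (uPa^2) of a long record from a coarse non-overlapping Welch
# estimate; used by the generator to calibrate chorus elevations (narrow
# HF bands make time-domain bandpass filters numerically fragile here)
welch_band_power <- function(x, f_low, f_high, fs, max_segments = 120L) {
  win <- min(8192L, 2^floor(log2(length(x))))
  if (length(x) > max_segments * win) x <- x[seq_len(max_segments * win)]
  psd <- compute_psd(x, spectrogram_spec(win, win, overlap_fraction = 0),
                     sample_rate_hz = fs)
  band_power(psd, f_low, f_high)
}

CHORUS_BAND_EDGES <- list(lfc = c(17, 25), hfc86 = c(84, 87), hfc99 = c(96, 100))

# Diffuse chorus track for one band: superposition of many faint copies
# (>= 50 per minute) at uniformly random offsets, scaled afterwards so that
# adding the track raises the band energy by exactly level_db over ambient.
render_chorus_track <- function(band, level_db, ambient, template, config) {
  n <- length(ambient)
  fs <- config$sample_rate_hz
  dur <- config$file_duration_s
  k <- max(10L, ceiling(50 * dur / 60))
  track <- numeric(n)
  if (band == "lfc") {
    unit <- render_pulse(
      pulse_template(template$duration_s, template$f_start_hz,
                     template$f_end_hz, template$source_level_db),
      rl_db = 0, sample_rate_hz = fs)
  } else {
    centre <- if (band == "hfc86") 85.5 else 98
  }
  m <- if (band == "lfc") length(unit) else round(template$duration_s * fs)
  starts <- sample.int(max(1L, n - m), k, replace = TRUE)
  amps <- amplitude_from_db(stats::runif(k, -6, 0))
  for (i in seq_len(k)) {
    idx <- starts[i] + seq_len(m) - 1L
    if (band == "lfc") {
      track[idx] <- track[idx] + unit * amps[i]
    } else {
      f <- stats::rnorm(1, centre, template$hf_bandwidth_hz / 3)
      edges <- CHORUS_BAND_EDGES[[band]]
      f <- min(max(f, edges[1] + 0.3), edges[2] - 0.3)
      t <- (seq_len(m) - 1) / fs
      track[idx] <- track[idx] +
        sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi)) * tukey_taper(m, 0.1) * amps[i]
    }
  }
  edges <- CHORUS_BAND_EDGES[[band]]
  p_noise <- welch_band_power(ambient, edges[1], edges[2], fs)
  p_track <- welch_band_power(track, edges[1], edges[2], fs)
  target <- p_noise * (power_from_db(level_db) - 1)
  track * sqrt(target / p_track)
}

#' Render a synthetic scene with ground truth
#'
#' Generates `n_files` single-channel pressure time series containing
#' 1/f-shaped ambient noise and, as configured, foreground 20-Hz pulses
#' (with optional HF components), diffuse choruses built from many
#' overlapping faint calls, and broadband transients. Every synthesised
#' signal gets exactly one ground-truth record. With all signal rates at
#' zero the output is pure coloured noise and the truth table is empty.
#'
#' @param config a [scene_config()]
#' @param template a [pulse_template()] used for foreground pulses and for
#'   the chorus call copies
#' @param out_dir optional directory; when given, WAV files (float32), a
#'   deployment sidecar and a selection-table truth file are written there
#' @param site_id site label recorded in metadata and truth
#' @param full_scale_db digital full scale in dB re 1 uPa for the WAV
#'   mapping (stored in the sidecar)
#' @return list with `files` (list of [audio_segment()]), `truth`
#'   (data.frame: file_id, signal_type, t_begin_s, t_end_s, f_low_hz,
#'   f_high_hz, true_peak_hz, true_rl_db), `meta`
#' @export
render_scene <- function(config, template = pulse_template(), out_dir = NULL,
                         site_id = "SYN", full_scale_db = 160) {
  stopifnot(inherits(config, "scene_config"), inherits(template, "pulse_template"))
  set.seed(config$rng_seed)
  fs <- config$sample_rate_hz
  n <- round(config$file_duration_s * fs)
  if (n < 4) stop("file duration too short")
  files <- vector("list", config$n_files)
  truth <- list()
  for (fi in seq_len(config$n_files)) {
    fid <- sprintf("%s_%04d", site_id, fi)
    x <- render_ambient(n, config$noise$rms_db, config$noise$kind)
    # diffuse choruses
    for (band in names(config$chorus_level_db)) {
      lv <- config$chorus_level_db[[band]]
      if (lv > 0) {
        x <- x + render_chorus_track(band, lv, x, template, config)
        edges <- CHORUS_BAND_EDGES[[band]]
        truth[[length(truth) + 1L]] <- data.frame(
          file_id = fid,
          signal_type = paste0(sub("hfc", "hfc", band), "_chorus"),
          t_begin_s = 0, t_end_s = config$file_duration_s,
          f_low_hz = edges[1], f_high_hz = edges[2],
          true_peak_hz = NA_real_, true_rl_db = NA_real_)
      }
    }
    # foreground pulses
    if (!is.null(config$song_ini_s) && config$pulse_rate_per_file > 0) {
      n_p <- round(config$pulse_rate_per_file)
      t0 <- stats::runif(1, 0, config$song_ini_s)
      onsets <- t0 + (seq_len(n_p) - 1) * config$song_ini_s
      onsets <- onsets[onsets + template$duration_s < config$file_duration_s]
    } else {
      n_p <- stats::rpois(1, config$pulse_rate_per_file)
      onsets <- sort(stats::runif(n_p, 0,
                                  config$file_duration_s - template$duration_s))
    }
    for (on in onsets) {
      rl <- stats::runif(1, config$pulse_rl_db[1], config$pulse_rl_db[2])
      hfp <- template$hf_peak_hz
      if (!is.null(hfp)) {
        hfp <- hfp + stats::rnorm(1, 0, template$hf_bandwidth_hz / 3)
        edges <- if (template$hf_peak_hz < 90) c(84, 87) else c(96, 100)
        hfp <- min(max(hfp, edges[1] + 0.2), edges[2] - 0.2)
      }
      w <- render_pulse(template, rl, fs, hf_peak_hz = hfp)
      i0 <- round(on * fs) + 1L
      idx <- i0 + seq_along(w) - 1L
      x[idx] <- x[idx] + w
      truth[[length(truth) + 1L]] <- data.frame(
        file_id = fid, signal_type = "pulse",
        t_begin_s = on, t_end_s = on + template$duration_s,
        f_low_hz = template$f_end_hz, f_high_hz = template$f_start_hz,
        true_peak_hz = NA_real_, true_rl_db = rl)
      if (!is.null(hfp)) {
        truth[[length(truth) + 1L]] <- data.frame(
          file_id = fid, signal_type = "hf_component",
          t_begin_s = on, t_end_s = on + template$duration_s,
          f_low_hz = hfp - 1, f_high_hz = hfp + 1,
          true_peak_hz = hfp, true_rl_db = rl + template$hf_level_offset_db)
      }
    }
    # broadband high-energy transients
    n_t <- stats::rpois(1, config$transient_rate)
    for (ti in seq_len(n_t)) {
      dur <- stats::runif(1, 0.1, 0.5)
      m <- round(dur * fs)
      on <- stats::runif(1, 0, config$file_duration_s - dur)
      burst <- stats::rnorm(m) * tukey_taper(m, 0.2)
      burst <- burst / rms(burst) *
        amplitude_from_db(config$noise$rms_db + stats::runif(1, 20, 25))
      i0 <- round(on * fs) + 1L
      x[i0 + seq_len(m) - 1L] <- x[i0 + seq_len(m) - 1L] + burst
      truth[[length(truth) + 1L]] <- data.frame(
        file_id = fid, signal_type = "transient",
        t_begin_s = on, t_end_s = on + dur,
        f_low_hz = 0, f_high_hz = fs / 2,
        true_peak_hz = NA_real_, true_rl_db = NA_real_)
    }
    files[[fi]] <- audio_segment(x, fs, calibrated = TRUE, file_id = fid)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    file_id = character(), signal_type = character(), t_begin_s = numeric(),
    t_end_s = numeric(), f_low_hz = numeric(), f_high_hz = numeric(),
    true_peak_hz = numeric(), true_rl_db = numeric())
  meta <- deployment_metadata(site_id, sample_rate_hz = fs,
                              full_scale_upa = amplitude_from_db(full_scale_db))
  for (fi in seq_along(files)) files[[fi]]$meta <- meta
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
      stop("cannot create output directory: ", out_dir)
    }
    fs_upa <- meta$full_scale_upa
    clipped <- FALSE
    for (f in files) {
      dig <- f$samples / fs_upa
      if (any(abs(dig) > 1)) clipped <- TRUE
      write_wav(dig, file.path(out_dir, paste0(f$file_id, ".wav")), fs)
    }
    meta$clipped <- clipped
    write_deployment_metadata(meta, file.path(out_dir, "deployment.json"))
    write_selection_table(truth_to_selections(truth),
                          file.path(out_dir, "truth_selections.txt"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  list(files = files, truth = truth, meta = meta)
}

#' Recorder gain/sensitivity chain
#'
#' Applies the hydrophone sensitivity (dB re 1 V/uPa, given as a positive
#' magnitude, e.g. 192.6) and the recorder set gain to a pressure waveform,
#' yielding digital samples relative to an ADC full scale of 1 V. The inverse
#' recovers pressure to within quantisation error. Samples beyond full scale
#' are flagged (`clipped`), never silently truncated.
#'
#' @param waveform pressure waveform, uPa
#' @param gain_db recorder set gain, dB
#' @param sensitivity_db hydrophone sensitivity magnitude, dB re 1 V/uPa
#' @return list: `samples` (digital), `gain_db`, `sensitivity_db`, `clipped`
#' @export
apply_recorder_chain <- function(waveform, gain_db, sensitivity_db) {
  stopifnot(is.finite(gain_db), is.finite(sensitivity_db))
  scale <- amplitude_from_db(gain_db - sensitivity_db)  # uPa -> digital
  samples <- waveform * scale
  list(samples = samples, gain_db = gain_db, sensitivity_db = sensitivity_db,
       clipped = any(abs(samples) > 1))
}

#' @rdname apply_recorder_chain
#' @param chain the list returned by `apply_recorder_chain`
#' @export
invert_recorder_chain <- function(chain) {
  chain$samples / amplitude_from_db(chain$gain_db - chain$sensitivity_db)
}
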