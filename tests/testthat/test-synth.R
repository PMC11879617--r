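test_that("rendered pulse RMS matches the requested received level", {
  tpl <- pulse_template()
  for (rl in c(100, 120, 160)) {
    w <- render_pulse(tpl, rl, 5333)
    expect_equal(20 * log10(sqrt(mean(w^2))), rl, tolerance = 0.1 / rl)
  }
})

test_that("HF component peaks at its configured frequency", {
  fs <- 5333
  w <- render_pulse(pulse_template(hf_peak_hz = 99), 120, fs)
  # brute-force periodogram of the HF band content
  n <- length(w)
  P <- Mod(stats::fft(w * finchorus:::hann_window(n)))^2
  freq <- (seq_len(n) - 1) * fs / n
  hf_region <- freq >= 80 & freq <= 110
  peak_hz <- freq[hf_region][which.max(P[hf_region])]
  expect_lt(abs(peak_hz - 99), fs / n + 0.5)
})

test_that("86 vs 99 Hz templates swap HF band dominance at equal level", {
  fs <- 5333
  w86 <- render_pulse(pulse_template(hf_peak_hz = 86), 120, fs)
  w99 <- render_pulse(pulse_template(hf_peak_hz = 99), 120, fs)
  p86_in86 <- oracle_band_power(w86, fs, 84, 87)
  p86_in99 <- oracle_band_power(w86, fs, 96, 100)
  p99_in86 <- oracle_band_power(w99, fs, 84, 87)
  p99_in99 <- oracle_band_power(w99, fs, 96, 100)
  expect_gt(p86_in86, 10 * p86_in99)
  expect_gt(p99_in99, 10 * p99_in86)
})

test_that("HF peak must fall inside exactly one detection band", {
  expect_error(pulse_template(hf_peak_hz = 90), "exactly one")
  expect_error(pulse_template(hf_peak_hz = 120), "exactly one")
  expect_s3_class(pulse_template(hf_peak_hz = 86), "pulse_template")
  expect_s3_class(pulse_template(hf_peak_hz = 99.5), "pulse_template")
})

test_that("render_pulse rejects sub-Nyquist sample rates and RL above SL", {
  expect_error(render_pulse(pulse_template(hf_peak_hz = 99), 120, 150),
               "Nyquist")
  expect_error(render_pulse(pulse_template(), 185, 5333), "source level")
})

test_that("scenes are deterministic given a seed, down to WAV bytes", {
  cfg <- scene_config(file_duration_s = 30, pulse_rate_per_file = 3,
                      rng_seed = 42)
  s1 <- render_scene(cfg)
  s2 <- render_scene(cfg)
  expect_identical(s1$files[[1]]$samples, s2$files[[1]]$samples)
  expect_identical(s1$truth, s2$truth)
  d1 <- file.path(tempdir(), "scene_a"); d2 <- file.path(tempdir(), "scene_b")
  render_scene(cfg, out_dir = d1)
  render_scene(cfg, out_dir = d2)
  w1 <- list.files(d1, pattern = "wav$", full.names = TRUE)
  w2 <- list.files(d2, pattern = "wav$", full.names = TRUE)
  expect_identical(readBin(w1, "raw", file.size(w1)),
                   readBin(w2, "raw", file.size(w2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("all-zero signal rates give pure noise and an empty truth table", {
  sc <- noise_scene_2min()
  expect_identical(nrow(sc$truth), 0L)
  expect_true(all(is.finite(sc$files[[1]]$samples)))
})

test_that("every generated signal has exactly one truth record", {
  cfg <- scene_config(file_duration_s = 60, pulse_rate_per_file = 5,
                      transient_rate = 2, n_files = 3, rng_seed = 7)
  sc <- render_scene(cfg, template = pulse_template(hf_peak_hz = 86))
  pulses <- sc$truth[sc$truth$signal_type == "pulse", ]
  hf <- sc$truth[sc$truth$signal_type == "hf_component", ]
  expect_identical(nrow(hf), nrow(pulses))   # one HF record per pulse
  expect_true(all(sc$truth$t_begin_s >= 0))
  expect_true(all(sc$truth$t_end_s <= 60))
  expect_true(all(sc$truth$t_begin_s < sc$truth$t_end_s))
})

test_that("configured chorus elevation is realised in the band", {
  cfg0 <- scene_config(file_duration_s = 120, rng_seed = 55)
  cfg10 <- scene_config(file_duration_s = 120,
                        chorus_level_db = c(lfc = 10), rng_seed = 55)
  x0 <- render_scene(cfg0)$files[[1]]$samples
  x10 <- render_scene(cfg10)$files[[1]]$samples
  # same seed => identical ambient; the ratio isolates the chorus track
  p0 <- oracle_band_power(x0, 5333, 17, 25)
  p10 <- oracle_band_power(x10, 5333, 17, 25)
  expect_equal(10 * log10(p10 / p0), 10, tolerance = 0.1)
})

test_that("HF chorus components stay inside their detection band", {
  sc <- chorus_scene_2min()
  x <- sc$files[[1]]$samples
  in_band <- oracle_band_power(x, 5333, 96, 100)
  out_band <- oracle_band_power(x, 5333, 101, 105)
  expect_gt(10 * log10(in_band / out_band), 5)
})

test_that("recorder chain round-trips pressure within 0.1 dB", {
  fs <- 5333
  t <- (0:(fs - 1)) / fs
  tone <- sin(2 * pi * 100 * t) * 10^(120 / 20) * sqrt(2)
  # gain 0, unity sensitivity (0 dB): identity
  ch0 <- apply_recorder_chain(tone, 0, 0)
  expect_equal(ch0$samples, tone)
  # the deployed setting: set gain 48 dB
  ch <- apply_recorder_chain(tone, 48, 192.6)
  back <- invert_recorder_chain(ch)
  expect_equal(20 * log10(sqrt(mean(back^2))), 120, tolerance = 0.1 / 120)
  expect_false(ch$clipped)
  # clipping flagged, not truncated
  loud <- apply_recorder_chain(tone * 1e10, 48, 0)
  expect_true(loud$clipped)
  expect_gt(max(abs(loud$samples)), 1)
})
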