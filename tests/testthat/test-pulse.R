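test_that("kurtosis of Gaussian noise is ~3; degenerate input gives NA", {
  set.seed(401)
  ks <- replicate(50, kurtosis(rnorm(5000)))
  expect_lt(abs(mean(ks) - 3), 0.1)
  expect_true(is.na(kurtosis(rep(1, 100))))
  expect_true(is.na(kurtosis(numeric(0))))
})

test_that("features on noise sit below the decision thresholds", {
  sc <- noise_scene_2min()
  ft <- extract_pulse_features(sc$files[[1]], c(30, 38))
  thr <- pulse_thresholds()
  # a noise window must fail at least one main-branch gate
  expect_true(ft$signal_kurtosis < thr$signal_kurtosis + 1 ||
              ft$kurtosis_product < thr$kurtosis_product)
  expect_true(is.na(decide_pulse_branch(ft, thr)))
})

test_that("a clean high-RL pulse passes every main-branch threshold", {
  fs <- 5333
  set.seed(402)
  w <- render_pulse(pulse_template(), 130, fs)
  amb <- render_scene(scene_config(file_duration_s = 30, rng_seed = 403,
                                   noise = list(rms_db = 100, kind = "pink")))
  x <- amb$files[[1]]$samples
  x[15 * fs + seq_along(w)] <- x[15 * fs + seq_along(w)] + w
  ft <- extract_pulse_features(audio_segment(x, fs), c(11.5, 19.5))
  thr <- pulse_thresholds()
  expect_gt(ft$signal_kurtosis, thr$signal_kurtosis)
  expect_gt(ft$kurtosis_product, thr$kurtosis_product)
  expect_gt(ft$spectral_snr_db, thr$spectral_snr)
  expect_gt(ft$temporal_snr_db, thr$temporal_snr)
  expect_identical(decide_pulse_branch(ft, thr), "main")
})

test_that("a constant window yields no detection", {
  ft <- data.frame(signal_kurtosis = NA_real_, kurtosis_product = NA_real_,
                   spectral_snr_db = NA_real_, temporal_snr_db = NA_real_,
                   signal_bandwidth = 0)
  expect_true(is.na(decide_pulse_branch(ft)))
})

test_that("windows shorter than 0.5 s are rejected", {
  sc <- noise_scene_2min()
  expect_error(extract_pulse_features(sc$files[[1]], c(10, 10.3)), "0.5 s")
})

test_that("two pulses 10 s apart give exactly two detections within 0.5 s", {
  fs <- 5333
  cfg <- scene_config(file_duration_s = 60, rng_seed = 404)
  x <- render_scene(cfg)$files[[1]]$samples
  w <- render_pulse(pulse_template(), 128, fs)
  onsets <- c(20, 30)
  for (on in onsets) {
    x[on * fs + seq_along(w)] <- x[on * fs + seq_along(w)] + w
  }
  det <- detect_pulses(audio_segment(x, fs))
  expect_identical(nrow(det), 2L)
  expect_true(all(abs(sort(det$t_begin_s) - onsets) <= 0.5))
})

test_that("detection counts fall monotonically as thresholds rise", {
  sc <- pulse_scene_10min()
  audio <- sc$files[[1]]
  counts <- sapply(c(3.25, 5, 8, 12, 20), function(k) {
    nrow(detect_pulses(audio, pulse_thresholds(
      signal_kurtosis = k, signal_kurtosis_1_2 = max(k, 4))))
  })
  expect_true(all(diff(counts) <= 0))
  counts2 <- sapply(c(40, 80, 200, 500), function(kp) {
    nrow(detect_pulses(audio, pulse_thresholds(kurtosis_product = kp)))
  })
  expect_true(all(diff(counts2) <= 0))
})

test_that("faint branch fires only when a chorus is present", {
  ft <- data.frame(signal_kurtosis = 6, kurtosis_product = 80,
                   spectral_snr_db = 12, temporal_snr_db = -4,
                   signal_bandwidth = 120)
  expect_true(is.na(decide_pulse_branch(ft, chorus_present = FALSE)))
  expect_identical(decide_pulse_branch(ft, chorus_present = TRUE),
                   "faint-in-chorus")
  # relaxed temporal SNR alone is not enough: bandwidth and kurtosis gates
  ft$signal_bandwidth <- 40
  expect_true(is.na(decide_pulse_branch(ft, chorus_present = TRUE)))
  ft$signal_bandwidth <- 120; ft$signal_kurtosis <- 3.5
  expect_true(is.na(decide_pulse_branch(ft, chorus_present = TRUE)))
  # below the relaxed floor nothing is accepted
  ft$signal_kurtosis <- 6; ft$temporal_snr_db <- -8
  expect_true(is.na(decide_pulse_branch(ft, chorus_present = TRUE)))
  # integration: detections on a pulse scene never carry the faint branch
  # when the flag is off
  det <- detect_pulses(pulse_scene_10min()$files[[1]], chorus_present = FALSE)
  expect_true(all(det$branch == "main"))
})

test_that("merged detections never overlap and keep legal durations", {
  det <- detect_pulses(pulse_scene_10min()$files[[1]])
  expect_gt(nrow(det), 10)
  d <- det[order(det$t_begin_s), ]
  expect_true(all(d$t_begin_s[-1] >= d$t_end_s[-nrow(d)]))
  durs <- d$t_end_s - d$t_begin_s
  expect_true(all(durs >= 0.5 - 1e-9 & durs <= 2.5 + 1e-9))
})

test_that("SPL_rms recovers the construction level and rejects out-of-band tones", {
  fs <- 5333
  set.seed(405)
  w <- render_pulse(pulse_template(), 120, fs)
  x <- c(rnorm(fs * 5) * 1e-3, w, rnorm(fs * 5) * 1e-3)
  expect_equal(spl_rms(audio_segment(x, fs), c(5, 6)), 120, tolerance = 0.5 / 120)
  # 50 Hz tone at a broadband level of 120 dB: band-filtered SPL >= 40 dB down
  t <- (0:(fs * 20 - 1)) / fs
  tone <- sin(2 * pi * 50 * t) * 10^(120 / 20) * sqrt(2)
  expect_lt(spl_rms(audio_segment(tone, fs), c(5, 15)), 80)
  # silence: sentinel
  expect_equal(spl_rms(audio_segment(rep(0, fs * 10), fs)), -999)
  expect_error(spl_rms(audio_segment(rnorm(fs), fs), c(2, 2)), "zero-length")
})
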