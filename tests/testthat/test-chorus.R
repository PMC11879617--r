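# synthetic psd_estimate with prescribed density shapes, for exact checks
make_psd <- function(density, df = 0.5, n_segments = 8,
                     segment_density = NULL) {
  nb <- length(density)
  if (is.null(segment_density)) {
    segment_density <- matrix(density, nb, n_segments)
  }
  structure(list(frequency_bins = (seq_len(nb) - 1) * df, density = density,
                 segment_density = segment_density,
                 n_segments = ncol(segment_density), resolution_hz = df,
                 sample_rate_hz = 2 * df * (nb - 1)),
            class = "psd_estimate")
}

test_that("band SNR is ~0 dB on white noise and exact on a forced ratio", {
  set.seed(301)
  psd <- compute_psd(rnorm(5333 * 60), sample_rate_hz = 5333)
  snr <- compute_band_snr(psd)
  expect_lt(abs(snr), 0.75)
  # forced 10x ratio
  d <- rep(1, 200)
  d[35:50] <- 10  # bins with centres in [17, 25) Hz at df = 0.5
  psd10 <- make_psd(d)
  expect_equal(compute_band_snr(psd10, c(17, 25),
                                list(c(10, 15), c(27, 32))), 10,
               tolerance = 1e-9)
})

test_that("median noise estimate is robust to injected transients", {
  cfg_clean <- scene_config(file_duration_s = 120,
                            chorus_level_db = c(lfc = 8), rng_seed = 303)
  cfg_trans <- scene_config(file_duration_s = 120,
                            chorus_level_db = c(lfc = 8), transient_rate = 3,
                            rng_seed = 303)
  # same seed: identical ambient + chorus, transients added on top
  m_clean <- chorus_metrics(render_scene(cfg_clean)$files[[1]])
  m_trans <- chorus_metrics(render_scene(cfg_trans)$files[[1]])
  expect_lt(abs(m_clean$snr_db[m_clean$band == "lfc"] -
                m_trans$snr_db[m_trans$band == "lfc"]), 1)
})

test_that("band SNR matches the brute-force oracle", {
  sc <- chorus_scene_2min()
  psd <- compute_psd(sc$files[[1]])
  snr <- compute_band_snr(psd)
  expect_equal(snr, oracle_band_snr(psd, c(17, 25), default_noise_bands()),
               tolerance = 1e-6)
})

test_that("PSD area is 0 for flat spectra and ~1 for a 2x rectangular bump", {
  flat <- make_psd(rep(3, 300))
  expect_equal(compute_psd_area(flat, c(96, 100)), 0, tolerance = 1e-12)
  d <- rep(1, 300)
  d[193:200] <- 2   # bins at 96-99.5 Hz for df = 0.5
  bump <- make_psd(d)
  expect_equal(compute_psd_area(bump, c(96, 100)), 1.0, tolerance = 0.01)
  # bump at 90 Hz affects neither HF band
  d2 <- rep(1, 300)
  d2[180:182] <- 5  # 89.5-90.5 Hz
  off <- make_psd(d2)
  expect_lt(abs(compute_psd_area(off, c(84, 87))), 0.05)
  expect_lt(abs(compute_psd_area(off, c(96, 100))), 0.05)
})

test_that("PSD area matches the brute-force trapezoid oracle", {
  sc <- chorus_scene_2min()
  psd <- compute_psd(sc$files[[1]])
  for (band in list(c(84, 87), c(96, 100))) {
    expect_equal(compute_psd_area(psd, band),
                 oracle_psd_area(psd, band), tolerance = 1e-6)
  }
})

test_that("threshold comparison is strict and uses the fixed defaults", {
  mk <- function(lfc_snr, a86 = 0, a99 = 0) {
    data.frame(file_id = "f", band = c("lfc", "hfc86", "hfc99"),
               snr_db = c(lfc_snr, 0, 0), psd_slope = 0,
               psd_area = c(0, a86, a99))
  }
  dec_hi <- decide_chorus(mk(4.01))
  dec_lo <- decide_chorus(mk(3.99))
  expect_true(dec_hi$counted[dec_hi$band == "lfc"])
  expect_false(dec_lo$counted[dec_lo$band == "lfc"])
  # all metrics zero: nothing detected
  expect_false(any(decide_chorus(mk(0))$raw_detected))
  # thresholds as configured
  expect_equal(dec_hi$threshold, c(4, 0.3, 0.35))
})

test_that("HF choruses only count with a concurrent low-frequency chorus", {
  m <- data.frame(file_id = "f", band = c("lfc", "hfc86", "hfc99"),
                  snr_db = c(2, 0, 0), psd_slope = 0,
                  psd_area = c(0, 0.5, 0.6))
  dec <- decide_chorus(m)
  expect_true(dec$raw_detected[dec$band == "hfc86"])
  expect_false(dec$counted[dec$band == "hfc86"])
  expect_false(dec$counted[dec$band == "hfc99"])
  # with LFC present the same HF metrics count
  m$snr_db[m$band == "lfc"] <- 5
  dec2 <- decide_chorus(m)
  expect_true(all(dec2$counted))
})

test_that("counted implies raw and concurrent LFC across random batches", {
  set.seed(305)
  for (rep in 1:30) {
    m <- data.frame(file_id = rep(sprintf("f%02d", 1:4), each = 3),
                    band = rep(c("lfc", "hfc86", "hfc99"), 4),
                    snr_db = runif(12, -2, 8), psd_slope = 0,
                    psd_area = runif(12, 0, 0.7))
    dec <- decide_chorus(m)
    expect_true(all(!dec$counted | dec$raw_detected))
    lfc_raw <- tapply(dec$raw_detected & dec$band == "lfc", dec$file_id, any)
    hf <- dec[dec$band != "lfc", ]
    expect_true(all(!hf$counted | lfc_raw[hf$file_id]))
  }
})

test_that("raising the simulated chorus level never lowers its metric", {
  levels_db <- c(3, 6, 9, 12)
  snrs <- numeric(length(levels_db))
  areas <- numeric(length(levels_db))
  for (i in seq_along(levels_db)) {
    cfg <- scene_config(file_duration_s = 120,
                        chorus_level_db = c(lfc = levels_db[i],
                                            hfc86 = levels_db[i]),
                        rng_seed = 77)  # same noise realisation throughout
    m <- chorus_metrics(render_scene(cfg)$files[[1]])
    snrs[i] <- m$snr_db[m$band == "lfc"]
    areas[i] <- m$psd_area[m$band == "hfc86"]
  }
  expect_true(all(diff(snrs) > 0))
  expect_true(all(diff(areas) > 0))
})
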