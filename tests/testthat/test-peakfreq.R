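tone_audio <- function(freqs, amps = rep(1, length(freqs)), dur = 10,
                       fs = 5333, noise = 0.01, seed = 601) {
  set.seed(seed)
  t <- (0:(round(fs * dur) - 1)) / fs
  x <- rnorm(length(t)) * noise
  for (i in seq_along(freqs)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t)
  audio_segment(x, fs)
}

test_that("a synthetic HF component is measured within one bin", {
  a <- tone_audio(99)
  pf <- measure_peak_frequency(a, list(begin_s = 1, end_s = 9,
                                       low_hz = 90, high_hz = 110))
  expect_lt(abs(pf$peak_freq_hz - 99), 250 / 256 + 1e-9)
})

test_that("the selection box restricts the measurement", {
  a <- tone_audio(c(86, 99))
  pf <- measure_peak_frequency(a, list(begin_s = 1, end_s = 9,
                                       low_hz = 84, high_hz = 92))
  expect_lt(abs(pf$peak_freq_hz - 86), 250 / 256 + 1e-9)
  expect_error(measure_peak_frequency(
    a, list(begin_s = 1, end_s = 9, low_hz = 140, high_hz = 150)), "Nyquist")
  expect_error(measure_peak_frequency(
    a, list(begin_s = 1, end_s = 0.5, low_hz = 84, high_hz = 92)),
    "positive area")
})

test_that("peak frequency is amplitude-invariant and stays inside the box", {
  set.seed(602)
  for (rep in 1:10) {
    f <- runif(1, 85, 99)
    a <- tone_audio(f, seed = 602 + rep)
    box <- list(begin_s = 1, end_s = 9, low_hz = 80, high_hz = 105)
    pf1 <- measure_peak_frequency(a, box)
    a2 <- audio_segment(a$samples * 250, a$sample_rate_hz)
    pf2 <- measure_peak_frequency(a2, box)
    expect_identical(pf1$peak_freq_hz, pf2$peak_freq_hz)
    expect_gte(pf1$peak_freq_hz, box$low_hz)
    expect_lte(pf1$peak_freq_hz, box$high_hz)
  }
})

test_that("generator peak frequencies are recovered from a measurement batch", {
  set.seed(603)
  peaks <- rnorm(50, 86.5, 1.25)
  peaks <- pmin(pmax(peaks, 84.2), 86.9)
  measured <- sapply(peaks, function(f) {
    a <- tone_audio(f, dur = 4, seed = round(f * 1000))
    measure_peak_frequency(a, list(begin_s = 0.5, end_s = 3.5,
                                   low_hz = 80, high_hz = 92))$peak_freq_hz
  })
  se <- sd(peaks) / sqrt(length(peaks))
  expect_lt(abs(mean(measured) - mean(peaks)), 2 * se + 250 / 256 / 2)
})

test_that("Kruskal-Wallis omnibus matches the brute-force rank oracle", {
  set.seed(604)
  for (rep in 1:10) {
    v <- c(rnorm(8, 86, 1), rnorm(7, 87, 1), rnorm(9, 99, 1))
    v <- round(v, 1)  # induce ties
    g <- rep(c("a", "b", "c"), c(8, 7, 9))
    cg <- compare_groups(data.frame(group = g, peak_freq_hz = v))
    expect_equal(cg$omnibus$statistic, oracle_kruskal_h(v, g),
                 tolerance = 1e-9)
  }
})

test_that("large separations are detected; constants give a null result", {
  set.seed(605)
  m <- data.frame(group = rep(c("w", "e"), each = 100),
                  peak_freq_hz = c(rnorm(100, 86.5, 1.25),
                                   rnorm(100, 96.8, 0.86)))
  cg <- compare_groups(m)
  expect_lt(cg$omnibus$p_value, 1e-3)
  expect_true(all(cg$pairwise$p_adjusted < 1e-3))
  # three identical constant groups
  m0 <- data.frame(group = rep(c("a", "b", "c"), each = 5), peak_freq_hz = 5)
  cg0 <- compare_groups(m0)
  expect_equal(cg0$omnibus$statistic, 0)
  expect_equal(cg0$omnibus$p_value, 1)
})

test_that("Dunn pairwise table covers all pairs and matches a manual case", {
  v <- c(1, 3, 5, 7, 9, 11, 2, 4, 6, 8, 10, 12)
  g <- rep(c("a", "b", "c"), each = 4)
  d <- dunn_test(v, g, p_adjust_method = "none")
  expect_identical(nrow(d), 3L)
  expect_setequal(paste(d$group1, d$group2),
                  c("a b", "a c", "b c"))
  # manual z for the a-c pair: no ties, so T = 0
  r <- rank(v); N <- 12
  z_ac <- (mean(r[g == "a"]) - mean(r[g == "c"])) /
    sqrt(N * (N + 1) / 12 * (1 / 4 + 1 / 4))
  expect_equal(d$z[d$group1 == "a" & d$group2 == "c"], z_ac, tolerance = 1e-12)
  # Holm adjustment never lowers a p-value
  dh <- dunn_test(v, g, p_adjust_method = "holm")
  expect_true(all(dh$p_adjusted >= dh$p_unadjusted - 1e-15))
})

test_that("undersized groups are excluded with a warning", {
  m <- data.frame(group = c(rep("a", 5), rep("b", 5), "tiny"),
                  peak_freq_hz = c(rnorm(5, 86), rnorm(5, 99), 90))
  expect_warning(cg <- compare_groups(m), "n < 2")
  expect_identical(sort(cg$groups$group), c("a", "b"))
})

test_that("top-SNR file selection ranks chorus-positive files", {
  dec <- data.frame(
    file_id = rep(sprintf("f%d", 1:5), each = 3),
    band = rep(c("lfc", "hfc86", "hfc99"), 5),
    snr_db = rep(c(5, 9, 7, 2, 8), each = 3),
    counted = rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), each = 3))
  top <- select_top_snr_files(dec, "hfc86", n_files = 2)
  expect_identical(top, c("f2", "f3"))
})
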