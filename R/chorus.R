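#' Chorus detection bands and thresholds
#'
#' The three fixed detection bands: low-frequency chorus (LFC) 17-25 Hz and
#' the two high-frequency choruses at 84-87 Hz (86-Hz chorus, HFC86) and
#' 96-100 Hz (99-Hz chorus, HFC99). Detection uses band SNR for the LFC and
#' the baseline-corrected PSD Area for the HF choruses, each compared
#' against a fixed threshold applied uniformly across sites: SNR > 4 dB,
#' PSD Area > 0.3 (HFC86) and > 0.35 (HFC99).
#'
#' @return named list of `c(f_low, f_high)` band edges (Hz)
#' @export
chorus_bands <- function() CHORUS_BAND_EDGES

#' @rdname chorus_bands
#' @export
default_chorus_thresholds <- function() {
  list(lfc = list(metric = "snr", threshold = 4),
       hfc86 = list(metric = "psd_area", threshold = 0.3),
       hfc99 = list(metric = "psd_area", threshold = 0.35))
}

#' Default adjacent noise bands for the LFC band SNR
#'
#' 10-15 Hz and 27-32 Hz: same total width as the signal band, separated
#' from 17-25 Hz by 2 Hz guard gaps so pulse/chorus energy does not leak
#' into the noise estimate. Configurable.
#' @export
default_noise_bands <- function() list(c(10, 15), c(27, 32))

#' Band signal-to-noise ratio with a median noise estimate
#'
#' `10*log10` of the mean in-band density over a robust noise estimate: the
#' mean density across the adjacent noise bands is computed per time
#' segment, and the *median over segments* is taken, so that a minority of
#' segments contaminated by high-energy transients does not inflate the
#' noise floor.
#'
#' @param psd a `psd_estimate` from [compute_psd()]
#' @param signal_band `c(f_low, f_high)` Hz
#' @param noise_bands list of `c(f_low, f_high)` bands, disjoint from the
#'   signal band
#' @return SNR in dB
#' @export
compute_band_snr <- function(psd, signal_band = chorus_bands()$lfc,
                             noise_bands = default_noise_bands()) {
  sig_idx <- band_bins(psd, signal_band[1], signal_band[2])
  if (!length(sig_idx)) stop("empty signal band")
  noise_idx <- unlist(lapply(noise_bands, function(b) {
    if (b[2] > signal_band[1] && b[1] < signal_band[2]) {
      stop("noise band [", b[1], ", ", b[2], ") overlaps the signal band")
    }
    band_bins(psd, b[1], b[2])
  }))
  if (!length(noise_idx)) stop("empty noise bands")
  sig <- mean(psd$density[sig_idx])
  noise_per_seg <- colMeans(psd$segment_density[noise_idx, , drop = FALSE])
  db_from_power(sig / stats::median(noise_per_seg))
}

#' Baseline-corrected normalised PSD Area of a band
#'
#' Area between the in-band density and a linear baseline interpolated
#' between the noise levels just outside the band edges (median density over
#' `guard_hz`-wide strips beyond each edge), normalised by the baseline
#' area. Dimensionless and scale-free: ~0 for a featureless spectrum, ~1.0
#' when the in-band density sits at twice the baseline.
#'
#' @param psd a `psd_estimate`
#' @param band `c(f_low, f_high)` Hz
#' @param guard_hz width of the strips outside the edges from which the
#'   baseline levels are taken
#' @return PSD Area (dimensionless)
#' @export
compute_psd_area <- function(psd, band, guard_hz = 2) {
  idx <- band_bins(psd, band[1], band[2])
  if (!length(idx)) stop("band contains no PSD bins")
  d <- psd$density[idx]
  if (any(!is.finite(d))) stop("non-finite density in band")
  f <- psd$frequency_bins[idx]
  lo_idx <- band_bins(psd, band[1] - guard_hz, band[1])
  hi_idx <- band_bins(psd, band[2], band[2] + guard_hz)
  lev_lo <- stats::median(psd$density[lo_idx])
  lev_hi <- stats::median(psd$density[hi_idx])
  baseline <- lev_lo + (lev_hi - lev_lo) * (f - band[1]) / (band[2] - band[1])
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(f))
  if (length(f) < 2) return((d - baseline) / baseline)
  base_area <- trapz(baseline)
  if (base_area <= 0) stop("non-positive baseline area")
  trapz(d - baseline) / base_area
}

#' PSD slope across a band
#'
#' Least-squares slope of the density (dB) against frequency (Hz) across
#' the band. Reported alongside SNR and PSD Area for completeness; it is
#' not used in the detection decision.
#'
#' @inheritParams compute_psd_area
#' @return slope in dB/Hz
#' @export
compute_psd_slope <- function(psd, band) {
  idx <- band_bins(psd, band[1], band[2])
  if (length(idx) < 2) stop("band too narrow for a slope")
  f <- psd$frequency_bins[idx]
  d <- db_from_power(pmax(psd$density[idx], .Machine$double.xmin))
  unname(stats::coef(stats::lm(d ~ f))[2])
}

#' Per-file chorus band metrics
#'
#' Computes SNR, PSD Slope and PSD Area for the three chorus bands from a
#' Welch PSD of the whole file.
#'
#' @param audio an [audio_segment()], or a precomputed `psd_estimate`
#' @param spec spectrogram parameterisation for the PSD
#' @param noise_bands adjacent noise bands for the LFC SNR
#' @param file_id identifier (defaults to the audio's)
#' @return data.frame: file_id, band, snr_db, psd_slope, psd_area
#' @export
chorus_metrics <- function(audio, spec = preset_spec("display_A"),
                           noise_bands = default_noise_bands(),
                           file_id = NULL) {
  psd <- if (inherits(audio, "psd_estimate")) audio else compute_psd(audio, spec)
  if (is.null(file_id)) {
    file_id <- if (inherits(audio, "audio_segment")) audio$file_id else "audio"
  }
  bands <- chorus_bands()
  rows <- lapply(names(bands), function(bn) {
    b <- bands[[bn]]
    nb <- if (bn == "lfc") noise_bands else {
      list(c(b[1] - 5, b[1] - 1), c(b[2] + 1, b[2] + 5))
    }
    data.frame(file_id = file_id, band = bn,
               snr_db = compute_band_snr(psd, b, nb),
               psd_slope = compute_psd_slope(psd, b),
               psd_area = compute_psd_area(psd, b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Chorus detection decisions with the conditional counting rule
#'
#' Compares each band's chosen metric against its threshold (strict
#' inequality). A raw HF-chorus detection is only *counted* when the
#' low-frequency chorus is detected concurrently in the same file — the HF
#' component co-occurs with 20-Hz pulse activity, and the rule suppresses
#' environmental-noise false positives in the HF bands. LFC counted equals
#' LFC raw.
#'
#' @param metrics data.frame from [chorus_metrics()] (may span many files)
#' @param thresholds list as [default_chorus_thresholds()]
#' @return data.frame: file_id, band, metric_used, metric_value, threshold,
#'   raw_detected, counted
#' @export
decide_chorus <- function(metrics, thresholds = default_chorus_thresholds()) {
  need <- c("file_id", "band", "snr_db", "psd_area")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("metrics missing columns: ", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(metrics)), function(i) {
    band <- metrics$band[i]
    th <- thresholds[[band]]
    if (is.null(th)) stop("no threshold configured for band ", band)
    value <- switch(th$metric, snr = metrics$snr_db[i],
                    psd_area = metrics$psd_area[i],
                    stop("unknown metric ", th$metric))
    if (!is.finite(value)) stop("missing/non-finite metric for ", band,
                                " in file ", metrics$file_id[i])
    data.frame(file_id = metrics$file_id[i], band = band,
               metric_used = th$metric, metric_value = value,
               threshold = th$threshold,
               raw_detected = value > th$threshold,
               stringsAsFactors = FALSE)
  })
  dec <- do.call(rbind, rows)
  lfc_by_file <- tapply(dec$raw_detected & dec$band == "lfc", dec$file_id, any)
  dec$counted <- dec$raw_detected &
    (dec$band == "lfc" | unname(lfc_by_file[dec$file_id]))
  dec
}
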