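#' Robust peak-frequency measurement inside a selection box
#'
#' Measures the HF component's peak frequency the way an analyst's "robust"
#' spectrogram measurement does: audio is decimated to 250 Hz, a
#' spectrogram is computed with the peak-frequency preset (Hann 256,
#' DFT 256, 80% overlap), and the frequency of the maximum-magnitude
#' time-frequency cell inside the selection box is returned. The
#' measurement is invariant to overall amplitude scaling and always lies
#' inside the box's frequency bounds.
#'
#' @param audio an [audio_segment()]; decimated internally when its rate is
#'   above `rate_hz`
#' @param box list/row with `begin_s`, `end_s`, `low_hz`, `high_hz`
#' @param rate_hz analysis rate (250 Hz)
#' @param spec spectrogram preset
#' @return one-row data.frame: file_id, begin_s, end_s, low_hz, high_hz,
#'   peak_freq_hz
#' @export
measure_peak_frequency <- function(audio, box, rate_hz = 250,
                                   spec = preset_spec("peakfreq_B")) {
  stopifnot(inherits(audio, "audio_segment"))
  if (box$end_s <= box$begin_s || box$high_hz <= box$low_hz) {
    stop("selection box must have positive area")
  }
  if (box$high_hz > rate_hz / 2) {
    stop("box upper frequency ", box$high_hz,
         " Hz exceeds the Nyquist after decimation (", rate_hz / 2, " Hz)")
  }
  if (audio$sample_rate_hz > rate_hz) audio <- decimate_to(audio, rate_hz)
  s <- stft_psd(audio$samples, audio$sample_rate_hz, spec)
  tin <- s$t >= box$begin_s & s$t <= box$end_s
  fin <- s$freq >= box$low_hz & s$freq <= box$high_hz
  if (!any(tin) || !any(fin)) {
    stop("selection box lies outside the spectrogram")
  }
  sub <- s$power[fin, tin, drop = FALSE]
  peak <- arrayInd(which.max(sub), dim(sub))
  data.frame(file_id = audio$file_id, begin_s = box$begin_s,
             end_s = box$end_s, low_hz = box$low_hz, high_hz = box$high_hz,
             peak_freq_hz = s$freq[fin][peak[1]], stringsAsFactors = FALSE)
}

#' Dunn's post-hoc test for pairwise rank comparisons
#'
#' Pairwise z statistics following a Kruskal-Wallis omnibus test, with the
#' usual tie correction, and p-values adjusted for multiplicity (Holm by
#' default). Implemented from the standard formula:
#' z_ij = (Rbar_i - Rbar_j) / sqrt( (N(N+1)/12 - T) (1/n_i + 1/n_j) ),
#' T = sum(t^3 - t) / (12 (N - 1)) over tie groups.
#'
#' @param values numeric vector of measurements
#' @param groups factor/character of group labels
#' @param p_adjust_method method passed to [stats::p.adjust()]
#' @return data.frame: group1, group2, z, p_unadjusted, p_adjusted
#' @export
dunn_test <- function(values, groups, p_adjust_method = "holm") {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  mean_r <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (mean_r[[i]] - mean_r[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_unadjusted = p,
             p_adjusted = stats::p.adjust(p, method = p_adjust_method),
             stringsAsFactors = FALSE)
}

#' Cross-site comparison of peak-frequency distributions
#'
#' Descriptive statistics per site/year group, a tie-corrected
#' Kruskal-Wallis omnibus test across groups, and Dunn's pairwise post-hoc
#' z tests with multiplicity adjustment. Groups with fewer than 2
#' measurements are excluded with a warning.
#'
#' @param measurements data.frame with `group` and `peak_freq_hz` columns
#'   (or supply `values`/`groups` directly)
#' @param p_adjust_method adjustment for the pairwise table (default Holm)
#' @return list: `groups` (per-group n/mean/sd/median/quartiles),
#'   `omnibus` (chi-squared statistic, df, p), `pairwise` (Dunn table)
#' @export
compare_groups <- function(measurements, p_adjust_method = "holm") {
  stopifnot(all(c("group", "peak_freq_hz") %in% names(measurements)))
  values <- measurements$peak_freq_hz
  groups <- factor(measurements$group)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding groups with n < 2: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups with n >= 2")
  desc <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), mean = mean(v), sd = stats::sd(v),
               q25 = q[1], median = q[2], q75 = q[3],
               stringsAsFactors = FALSE)
  }))
  if (length(unique(values)) == 1L) {
    # fully tied data: the tie-corrected statistic degenerates to 0/0;
    # by convention there is no evidence against the null
    omnibus <- list(statistic = 0, df = nlevels(groups) - 1L, p_value = 1)
  } else {
    kw <- stats::kruskal.test(values, groups)
    omnibus <- list(statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p_value = kw$p.value)
  }
  list(groups = desc,
       omnibus = omnibus,
       pairwise = dunn_test(values, groups, p_adjust_method))
}

#' Select the highest-SNR chorus-positive files for HF analysis
#'
#' Mirrors the sample-selection protocol for peak-frequency measurement:
#' among files where the given HF chorus was counted, rank by the file's
#' 20-Hz band SNR and keep the top `n_files`.
#'
#' @param decisions output of [decide_chorus()] joined with `snr_db`
#' @param hf_band `"hfc86"` or `"hfc99"`
#' @param n_files how many files to keep (10 in the original protocol)
#' @return character vector of file ids, highest SNR first
#' @export
select_top_snr_files <- function(decisions, hf_band, n_files = 10) {
  lfc <- decisions[decisions$band == "lfc", c("file_id", "snr_db")]
  hf <- decisions[decisions$band == hf_band & decisions$counted, "file_id"]
  cand <- lfc[lfc$file_id %in% hf, , drop = FALSE]
  cand <- cand[order(cand$snr_db, decreasing = TRUE), , drop = FALSE]
  utils::head(cand$file_id, n_files)
}
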