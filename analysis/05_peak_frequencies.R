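# HF-component peak frequencies: per site, take the chorus-positive files
# with the highest 20-Hz band SNR, measure the peak frequency of each
# detected HF component on 250 Hz decimated audio inside a selection box
# around the HF band, and compare the sites' distributions
# (Kruskal-Wallis + Dunn).

source(file.path("analysis", "00_config.R"))

decisions <- read.csv(result_path("chorus_decisions.csv"))
truth <- read.csv(result_path("demo_truth.csv"))

measurements <- list()
for (site in names(DEMO$sites)) {
  s <- DEMO$sites[[site]]
  hf_band <- if (s$hf_peak_hz < 90) "hfc86" else "hfc99"
  dec <- decisions[decisions$site_id == site, ]
  top <- select_top_snr_files(dec, hf_band, n_files = 10)
  wavs <- list.files(site_scene_dir(site), pattern = "\\.wav$",
                     recursive = TRUE, full.names = TRUE)
  names(wavs) <- sub("\\.wav$", "", basename(wavs))
  box_f <- if (hf_band == "hfc86") c(80, 92) else c(92, 104)
  for (fid in top) {
    audio <- decimate_to(read_wav_with_metadata(wavs[[fid]]), 250)
    # one box per true HF component in the file (the analyst's box, drawn
    # from the truth annotations)
    hf <- truth[truth$file_id == fid & truth$signal_type == "hf_component", ]
    for (k in seq_len(nrow(hf))) {
      box <- list(begin_s = max(0.2, hf$t_begin_s[k] - 0.2),
                  end_s = min(DEMO$file_duration_s - 0.2, hf$t_end_s[k] + 0.2),
                  low_hz = box_f[1], high_hz = box_f[2])
      m <- measure_peak_frequency(audio, box)
      m$site_id <- site
      m$true_peak_hz <- hf$true_peak_hz[k]
      measurements[[length(measurements) + 1L]] <- m
    }
  }
}
pf <- do.call(rbind, measurements)
write.csv(pf, result_path("peak_frequencies.csv"), row.names = FALSE)

cmp <- compare_groups(data.frame(group = pf$site_id,
                                 peak_freq_hz = pf$peak_freq_hz))
write.csv(cmp$groups, result_path("peakfreq_groups.csv"), row.names = FALSE)
write.csv(cmp$pairwise, result_path("peakfreq_pairwise.csv"), row.names = FALSE)

message(sprintf("%d HF components measured", nrow(pf)))
print(cmp$groups)
message(sprintf("Kruskal-Wallis chi-squared = %.2f, df = %d, p = %.3g",
                cmp$omnibus$statistic, cmp$omnibus$df, cmp$omnibus$p_value))
print(cmp$pairwise)
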