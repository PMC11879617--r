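# Daily acoustic presence: per-day chorus percentages, 3-day running means,
# pulse counts, FPR reference lines, outlier-day review flags, and
# site-level mean chorus SNR.

source(file.path("analysis", "00_config.R"))

decisions <- read.csv(result_path("chorus_decisions.csv"))
pulses <- read.csv(result_path("pulse_detections.csv"))

refs <- fpr_reference(n_files_per_day = DEMO$files_per_day,
                      pulse_line_per_day = round(575 * DEMO$files_per_day / 144))
message(sprintf("chorus FPR line for the demo day: %.2f files/day",
                refs$chorus_line_files_per_day))

all_daily <- list()
for (site in names(DEMO$sites)) {
  dec <- decisions[decisions$site_id == site, ]
  pul <- pulses[pulses$site_id == site, ]
  ids <- unique(dec$file_id)
  calendar <- data.frame(
    file_id = ids,
    date = as.Date("2013-03-01") + (seq_along(ids) - 1) %/% DEMO$files_per_day)
  daily <- aggregate_daily(dec, pul, calendar, site_id = site)
  daily$smoothed_pct <- stats::ave(daily$pct, daily$band, FUN = running_mean3)
  all_daily[[site]] <- daily
  flags <- flag_outlier_days(daily[daily$band == "lfc", ], refs, "chorus")
  message(sprintf("%s: %d day-band rows, %d outlier-day flags", site,
                  nrow(daily), nrow(flags)))
}
daily <- do.call(rbind, all_daily)
rownames(daily) <- NULL
write.csv(daily, result_path("daily_presence.csv"), row.names = FALSE)

snr <- site_mean_snr(decisions)
write.csv(snr, result_path("site_mean_snr.csv"), row.names = FALSE)
message("site mean chorus SNR (counted files only):")
print(snr[!is.na(snr$mean_snr_db), ])
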