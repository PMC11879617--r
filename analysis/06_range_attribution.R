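# Detection-range attribution: compare each detected pulse's measured
# SPL_rms (15-26 Hz) with the received level a transmission-loss model
# predicts at a 3 km radius; pulses above that threshold are attributed to
# sources within the radius. Also demonstrates a tabulated TL curve
# (placeholder for an external propagation model's output).

source(file.path("analysis", "00_config.R"))

pulses <- read.csv(result_path("pulse_detections.csv"))

rows <- list()
for (site in names(DEMO$sites)) {
  det <- pulses[pulses$site_id == site, ]
  att <- attribute_within_radius(det, DEMO$tl, radius_m = 3000,
                                 site_id = site)
  rows[[site]] <- att
  message(sprintf(
    "%s: RL threshold at 3 km = %.2f dB; %d/%d detections above it (%.1f%%)",
    site, att$rl_threshold_db, att$n_within, att$n_total,
    100 * att$fraction_within))
}

# the same attribution through a tabulated curve import (synthetic example
# curve shipped with the package)
tab_path <- system.file("extdata", "example_tl_curve_synthetic.csv",
                        package = "finchorus")
tl_tab <- read_tl_table(tab_path)
att_tab <- attribute_within_radius(pulses, tl_tab, radius_m = 3000,
                                   site_id = "all_tabulated")
rows$tabulated <- att_tab
message(sprintf("tabulated curve: threshold %.2f dB, fraction within %.3f",
                att_tab$rl_threshold_db, att_tab$fraction_within))

att <- do.call(rbind, rows)
rownames(att) <- NULL
write.csv(att, result_path("range_attribution.csv"), row.names = FALSE)
message("wrote ", result_path("range_attribution.csv"))
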