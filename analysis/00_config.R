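# Shared configuration for the demo analysis: two synthetic deployments
# emulating the two acoustic populations — a western site whose fin whales
# carry the ~86 Hz HF component (EI, Elephant-Island-like) and an eastern
# site carrying the ~99 Hz component (GM, Greenwich-Meridian-like).
#
# The demo is scaled for a desk run: 60 s files, 24 files per nominal
# "day", 3 days per site. Day 1 is quiet; days 2-3 carry chorus and song.
# All downstream scripts read this file.

library(finchorus)

SCENE_DIR <- file.path("scratch", "scenes")
RESULTS_DIR <- "results"

DEMO <- list(
  file_duration_s = 60,
  files_per_day = 24,
  n_days = 3,
  sites = list(
    EI = list(hf_peak_hz = 86, seed0 = 9100,
              chorus = c(lfc = 8, hfc86 = 7, hfc99 = 0)),
    GM = list(hf_peak_hz = 99, seed0 = 9200,
              chorus = c(lfc = 7, hfc86 = 0, hfc99 = 7))
  ),
  pulse_rate_active = 6,        # pulses per active file
  pulse_rl_db = c(118, 134),
  tl = tl_model("hybrid", source_level_db = 180, transition_range_m = 500)
)

site_scene_dir <- function(site) file.path(SCENE_DIR, site)
result_path <- function(...) file.path(RESULTS_DIR, ...)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
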