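# finchorus

Passive acoustic monitoring infers where and when whales are present from
years of autonomous single-channel recordings. `finchorus` implements the
measurement chain for Southern Hemisphere fin whales (*Balaenoptera
physalus quoyi*), whose song is built from the stereotyped **20-Hz pulse**
— a ~1 s downsweep from ~28 Hz to ~15 Hz at source levels of 160–186 dB
re 1 µPa — and whose overlapping calls merge into a **low-frequency
chorus** in 17–25 Hz. A simultaneous faint narrowband **high-frequency
component** near 86 Hz or 99 Hz marks distinct acoustic populations and
produces choruses in the 84–87 Hz and 96–100 Hz bands. The package is
aimed at bioacousticians processing long-term deployments (10-minute WAV
files at 5333 Hz) who need reproducible detection, presence aggregation
and population discrimination without a GUI.

What it computes:

* **Chorus detection per file** — band SNR
  (`10·log10(S̄ / median_t(N̄_adj))`, with the median over time segments
  rejecting transients) for the low-frequency chorus, and a
  baseline-corrected, baseline-normalised **PSD Area** for the two HF
  choruses; fixed thresholds (SNR > 4 dB, Area > 0.3 / 0.35), and HF
  detections counted only when the low-frequency chorus is concurrent.
* **20-Hz pulse detection** — a decision tree over waveform kurtosis
  (> 3.25), kurtosis product (> 40), spectral SNR (> 9 dB), temporal SNR
  (> −2 dB), with a faint-in-chorus branch (> −7 dB, bandwidth > 75,
  kurtosis > 4); each detection carries its SPL_rms in 15–26 Hz.
* **Daily presence** — percentages of chorus-positive files and pulse
  counts per UTC day (144 ten-minute files/day), 3-day running means,
  false-positive reference lines (3% ≙ 4.32 files/day; 575 pulses/day),
  and isolated-exceedance review flags.
* **Peak frequency** — the robust spectrogram-peak measurement inside an
  analyst's selection box on 250 Hz decimated audio (Hann 256, 80%
  overlap), compared across sites with a tie-corrected Kruskal–Wallis test
  and Dunn's post-hoc z tests.
* **Range attribution** — detections with SPL_rms above the modelled
  received level `RL(r) = SL − TL(r)` at 3 km (SL = 180 dB re 1 µPa;
  spherical/cylindrical/hybrid or imported tabulated TL curves) are
  attributed to sources within that radius.
* **Synthetic scenes** — a ground-truthed generator (pulses, HF
  components, choruses as superposed faint calls, 1/f ambient noise,
  broadband transients, recorder gain/sensitivity chain) against which
  every stage is calibrated and tested.

## Worked example

Simulate a 5-minute file containing a low-frequency chorus at +8 dB, a
99-Hz chorus at +7 dB and five 20-Hz pulses, then run the detectors:

```r
library(finchorus)

cfg <- scene_config(file_duration_s = 300, pulse_rate_per_file = 5,
                    chorus_level_db = c(lfc = 8, hfc99 = 7),
                    pulse_rl_db = c(122, 132), rng_seed = 2013)
scene <- render_scene(cfg, template = pulse_template(hf_peak_hz = 99))
audio <- scene$files[[1]]

(metrics <- chorus_metrics(audio))
#>    file_id  band snr_db psd_slope psd_area
#> 1 SYN_0001   lfc  12.84    0.0624   0.8483
#> 2 SYN_0001 hfc86   0.12   -0.0370  -0.0289
#> 3 SYN_0001 hfc99  14.76    3.0697   6.9363

decide_chorus(metrics)[, c("band", "metric_used", "metric_value", "counted")]
#>    band metric_used metric_value counted
#> 1   lfc         snr      12.8413    TRUE
#> 2 hfc86    psd_area      -0.0289   FALSE
#> 3 hfc99    psd_area       6.9363    TRUE

pulses <- detect_pulses(audio, chorus_present = TRUE)
pulses[1:3, c("t_begin_s", "t_end_s", "branch", "signal_kurtosis", "spl_rms_db")]
#>   t_begin_s t_end_s branch signal_kurtosis spl_rms_db
#> 1     24.42   25.39   main          13.133      125.5
#> 2    149.14  150.13   main           7.829      128.7
#> 3    153.01  153.99   main           9.714      128.1

evaluate_detections(pulses, scene$truth, "pulse_timestamped",
                    n_files = 1, file_duration_s = 300)[c("tpr", "fpr")]
#> $tpr [1] 1        # all 4 rendered pulses recovered within ±0.5 s
#> $fpr [1] 0.00167  # one unmatched detection in 600 analysis windows

attribute_within_radius(pulses, tl_model("hybrid", source_level_db = 180),
                        radius_m = 3000)[c("rl_threshold_db", "fraction_within")]
#>   rl_threshold_db fraction_within
#> 1          118.24             0.8
```

Reading the numbers: the injected choruses clear their thresholds by wide
margins (SNR 12.8 dB vs 4; Area 6.94 vs 0.35) while the empty 86-Hz band
stays at zero; the pulse detector recovers every rendered pulse with
onsets within a quarter second and calibrated levels (125–129 dB re 1 µPa)
close to the rendered received levels; and four of the five detections
exceed the 3-km received-level threshold — the fifth is the one unmatched
(chorus-borne) detection, whose lower SPL places it beyond the radius.

## The demo analysis workflow

`analysis/` holds the numbered drivers of a complete scaled-down study —
two synthetic deployments emulating the 86-Hz (western) and 99-Hz
(Greenwich-Meridian) populations:

```sh
Rscript analysis/01_simulate.R          # scenes + ground truth (scratch/, results/)
Rscript analysis/02_detect_chorus.R     # band metrics + decisions per file
Rscript analysis/03_detect_pulses.R     # pulse detections + evaluation
Rscript analysis/04_aggregate_presence.R
Rscript analysis/05_peak_frequencies.R  # boxes, decimation, KW + Dunn
Rscript analysis/06_range_attribution.R
```

Each script states what it found (e.g. per-site peak-frequency means of
86.0 Hz vs 98.6 Hz separated at p ≈ 4·10⁻²⁶; 96–99% of detected pulses
attributed to within 3 km) and writes its tables under `results/`.

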