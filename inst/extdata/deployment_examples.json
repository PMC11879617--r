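{
  "_comment": "Example deployment/propagation configurations for the two sites where 20-Hz pulses were detected. The propagation block documents the settings a site-specific 3-D normal-mode model would use; this package consumes only the resulting RL-vs-range curve (see example_tl_curve_synthetic.csv for the import format).",
  "deployments": [
    {
      "site_id": "R1",
      "description": "Elephant Island",
      "latitude": -61.0147, "longitude": -55.9755,
      "water_depth_m": 320, "receiver_depth_m": 215,
      "gain_db": 48, "sensitivity_db": 192.6, "sensitivity_ref_hz": 251,
      "sample_rate_hz": 5333,
      "propagation": {
        "sender_depth_m": 15, "receiver_grid_depth_m": 10.7,
        "source_level_db": 180, "water_temperature_c": 0.8,
        "sediment_type": "sand",
        "grid_points_xyz": [2000, 2000, 500],
        "step_m_xyz": [354.4, 343.4, 10.7],
        "radial_slices": 100, "range_points": 500
      }
    },
    {
      "site_id": "R7",
      "description": "Greenwich Meridian",
      "latitude": -59.047, "longitude": 0.0963,
      "water_depth_m": 4600, "receiver_depth_m": 1020,
      "gain_db": 24, "sensitivity_db": 192.6, "sensitivity_ref_hz": 251,
      "sample_rate_hz": 5333,
      "propagation": {
        "sender_depth_m": 15, "receiver_grid_depth_m": 10.7,
        "source_level_db": 180, "water_temperature_c": -0.3,
        "sediment_type": "mud",
        "grid_points_xyz": [610, 635, 525],
        "step_m_xyz": [353.1, 346.8, 10.7],
        "radial_slices": 100, "range_points": 620
      }
    }
  ]
}
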