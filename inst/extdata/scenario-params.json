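{
  "comment": "Packaged film and scenario parameters for the four ODFs (C1, C2 = sodium CMC; P1, P2 = PVA) and three methods (petri, ocm, btm). Endpoint means/sds are the packaged study values; event schedules and friction signatures are scripted archetypes. Coefficient-of-friction levels are plausible stand-ins (no printed values exist); their ordering encodes the observed ranking P1 > P2 > C1 > C2.",
  "cap_s": 180.0,
  "films": {
    "C1": {"polymer": "CMC", "mw_kda": 395, "conc_pct_wv": 1, "width_mm": 30, "height_mm": 20, "thickness_um": 73.63},
    "C2": {"polymer": "CMC", "mw_kda": 725, "conc_pct_wv": 1, "width_mm": 30, "height_mm": 20, "thickness_um": 79.54},
    "P1": {"polymer": "PVA", "mw_kda": 39,  "conc_pct_wv": 5, "width_mm": 30, "height_mm": 20, "thickness_um": 35.25},
    "P2": {"polymer": "PVA", "mw_kda": 197, "conc_pct_wv": 5, "width_mm": 30, "height_mm": 20, "thickness_um": 38.78}
  },
  "endpoints": {
    "C1": {"petri": {"mean": 25.3, "sd": 0.7},  "ocm": {"censored": true}, "btm": {"mean": 11.0, "sd": 2.0}},
    "C2": {"petri": {"censored": true},         "ocm": {"censored": true}, "btm": {"mean": 8.0,  "sd": 2.0}},
    "P1": {"petri": {"mean": 7.4,  "sd": 0.6},  "ocm": {"mean": 24.0, "sd": 2.0}, "btm": {"mean": 31.0, "sd": 3.0}},
    "P2": {"petri": {"mean": 22.2, "sd": 0.9},  "ocm": {"censored": true}, "btm": {"mean": 21.0, "sd": 2.0}}
  },
  "ocm_archetypes": {
    "P1": {
      "kind": "detach_then_disintegrate",
      "detach_area_fraction": 0.2,
      "detach_speed_mm_s": 3.0,
      "shrink_onset_after_s": 2.0,
      "shrink_rate_per_s": 0.012
    },
    "P2": {
      "kind": "transient_tears",
      "corner_tear_onsets_s": [70, 80, 95],
      "corner_tear_coalesce_s": [78, 88, 103],
      "corner_cut_px": 20,
      "long_tear_onset_s": 105,
      "long_tear_coalesce_s": 160,
      "long_tear_at_frac": 0.3,
      "long_tear_span_frac": 0.85,
      "long_tear_width_px": 12
    },
    "C1": {"kind": "swell_only", "swell_onset_s": 5, "swell_factor": 1.12, "swell_ramp_s": 120},
    "C2": {"kind": "swell_only", "swell_onset_s": 5, "swell_factor": 1.18, "swell_ramp_s": 120}
  },
  "cof_signatures": {
    "C1": {"shape": "decline_plateau",   "mu_initial": 0.45, "mu_plateau": 0.30, "decline_s": 3, "fluctuation_amp": 0,    "noise_sd": 0.02},
    "C2": {"shape": "decline_plateau",   "mu_initial": 0.30, "mu_plateau": 0.18, "decline_s": 3, "fluctuation_amp": 0,    "noise_sd": 0.02},
    "P1": {"shape": "fluctuate_plateau", "mu_initial": 0.65, "mu_plateau": 0.48, "decline_s": 0, "fluctuation_amp": 0.06, "fluctuation_period_s": 5, "noise_sd": 0.02},
    "P2": {"shape": "fluctuate_plateau", "mu_initial": 0.66, "mu_plateau": 0.50, "decline_s": 0, "fluctuation_amp": 0.09, "fluctuation_period_s": 5, "noise_sd": 0.02}
  },
  "btm": {
    "frequency_hz": 1.0,
    "load_N": 1.0,
    "stroke_mm": 7.5,
    "sample_hz": 100,
    "fn_noise_sd_N": 0.01,
    "channel_angle_deg": 15,
    "ssf_ul_per_4_strokes": 100,
    "duration_margin_s": 15
  },
  "ocm": {
    "compression_period_s": 2.0,
    "compression_duration_s": 0.4,
    "compression_brightness": 0.85,
    "duration_margin_s": 12
  },
  "video": {
    "width_px": 640,
    "height_px": 480,
    "mm_per_px": 0.1,
    "fps": 30,
    "corner_radius_mm": 1.5,
    "noise_sd": 0.02,
    "film_rgb": [0.82, 0.10, 0.45],
    "background_rgb": [0.82, 0.74, 0.70],
    "btm_band_halfwidth_px": 25,
    "btm_band_amplitude": 0.15,
    "btm_band_sweep_px": 140
  },
  "petri": {"latency_truncation_sd": 3}
}
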