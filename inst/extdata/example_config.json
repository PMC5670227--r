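{
  "seed": 7,
  "options": {"rule": "all_positive", "window_days": 84, "n_perm": 999},
  "climatology": {"DemoSite": {"mmm": 29.5, "source": "example"}},
  "sites": [
    {
      "site_id": "DemoSite",
      "habitat": "subtidal",
      "start": "2016-01-01",
      "end": "2016-03-31",
      "scenario": {"mmm": 29.5, "mean_annual": 29.2,
                   "seasonal_amplitude": 0.4, "season_phase": 45,
                   "heatwave": {"start": "2016-01-15", "duration_days": 60,
                                "magnitude": 0.6, "ramp_days": 7},
                   "noise_sd": 0.15},
      "survey": {
        "times": {"t1": "2016-01-20", "t2": "2016-03-31"},
        "profile": {"genera": {"Acropora": 0.8, "Porites": 0.2},
                    "coral_fraction": 0.5},
        "n_transects": 4,
        "quadrats_per_transect": 4,
        "mode": "photoquadrat"
      }
    }
  ]
}
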