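{
  "_comment": "Editable tissue dielectric properties. sigma in S/m, fields in V/cm. Values are literature-derived nominal settings, not results of this package.",
  "tissues": {
    "background": {"sigma0": 0.2,  "sigma_max": 0.4,  "e_low": 500, "e_high": 800,
                   "thresholds": {"ECT": {"e_rev": 400, "e_irr": 800}, "IRE": {"e_rev": 400, "e_irr": 600}}},
    "liver":      {"sigma0": 0.11, "sigma_max": 0.45, "e_low": 460, "e_high": 700,
                   "thresholds": {"ECT": {"e_rev": 400, "e_irr": 800}, "IRE": {"e_rev": 400, "e_irr": 600}}},
    "vessel":     {"sigma0": 0.7,  "sigma_max": 0.7,  "e_low": 500, "e_high": 900,
                   "thresholds": {"ECT": {"e_rev": 400, "e_irr": 800}, "IRE": {"e_rev": 400, "e_irr": 600}}},
    "tumor":      {"sigma0": 0.3,  "sigma_max": 0.75, "e_low": 400, "e_high": 700,
                   "thresholds": {"ECT": {"e_rev": 400, "e_irr": 800}, "IRE": {"e_rev": 400, "e_irr": 600}}},
    "bone":       {"sigma0": 0.02, "sigma_max": 0.02, "e_low": 800, "e_high": 1200,
                   "thresholds": {"ECT": {"e_rev": 400, "e_irr": 800}, "IRE": {"e_rev": 400, "e_irr": 600}}},
    "brain":      {"sigma0": 0.26, "sigma_max": 0.5,  "e_low": 450, "e_high": 700,
                   "thresholds": {"ECT": {"e_rev": 400, "e_irr": 800}, "IRE": {"e_rev": 400, "e_irr": 600}}}
  }
}
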