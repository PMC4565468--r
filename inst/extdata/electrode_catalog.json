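{
  "_comment": "Nominal needle-electrode catalog. Dimensions are editable placeholders in mm / volts, not manufacturer-verified data.",
  "electrodes": [
    {
      "id": "hexagonal-7",
      "style": "hexagonal",
      "needle_diameter_mm": 1.2,
      "active_lengths_mm": [10, 20, 30],
      "default_active_length_mm": 20,
      "offsets_mm": [[0, 0], [8.7, 0], [4.35, 7.5344210129246152], [-4.35, 7.5344210129246152], [-8.7, 0], [-4.35, -7.5344210129246152], [4.35, -7.5344210129246152]],
      "max_voltage_V": 1000
    },
    {
      "id": "linear-pair",
      "style": "linear",
      "needle_diameter_mm": 1.2,
      "active_lengths_mm": [10, 20, 30],
      "default_active_length_mm": 20,
      "offsets_mm": [[-4, 0], [4, 0]],
      "max_voltage_V": 1000
    },
    {
      "id": "finger-axial",
      "style": "finger_axial",
      "needle_diameter_mm": 0.7,
      "active_lengths_mm": [5, 10],
      "default_active_length_mm": 10,
      "offsets_mm": [[-2.5, 0], [2.5, 0]],
      "max_voltage_V": 1000
    },
    {
      "id": "finger-perpendicular",
      "style": "finger_perpendicular",
      "needle_diameter_mm": 0.7,
      "active_lengths_mm": [5, 10],
      "default_active_length_mm": 5,
      "offsets_mm": [[-3, 0], [3, 0]],
      "max_voltage_V": 1000
    },
    {
      "id": "variable-single",
      "style": "variable",
      "needle_diameter_mm": 1.2,
      "active_lengths_mm": [20, 30, 40],
      "default_active_length_mm": 30,
      "offsets_mm": [],
      "max_voltage_V": 3000
    },
    {
      "id": "nanoknife-variable",
      "style": "variable",
      "needle_diameter_mm": 1.0,
      "active_lengths_mm": [10, 15, 20, 25, 30, 40],
      "default_active_length_mm": 20,
      "offsets_mm": [],
      "max_voltage_V": 3000
    }
  ]
}
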