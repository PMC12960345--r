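{
  "scale_1767_6pt": {
    "description": "Six-point visual wind-force scale used in the 1767-68 register; representative speeds in m/s at 10 m.",
    "codes": [1, 2, 3, 4, 5, 6],
    "speeds_ms_10m": [0.45, 3.4, 8.0, 13.9, 20.75, 30.5]
  },
  "scale_1789_5pt": {
    "description": "Five-point visual wind-force scale used in the 1789-92 register; representative speeds in m/s at 10 m.",
    "codes": [0, 1, 2, 3, 4],
    "speeds_ms_10m": [0.3, 2.4, 9.3, 18.9, 30.5]
  }
}
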