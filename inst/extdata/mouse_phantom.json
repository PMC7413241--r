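{
  "body_mass_g": 25,
  "organs": {
    "blood": 1.7,
    "heart": 0.15,
    "liver": 1.37,
    "lungs": 0.15,
    "spleen": 0.1,
    "kidneys": 0.34,
    "intestine": 2,
    "pancreas": 0.3,
    "stomach": 0.25,
    "bone": 2.5,
    "marrow": 0.25,
    "muscle": 9
  }
}
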