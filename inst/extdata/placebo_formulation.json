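{
  "description": "Placebo granule formulation: per-batch dry-basis masses and GAB sorption parameters of each material. The adsorbing subset defines m_adsorb, the denominator of the dry-basis moisture F_w.",
  "components": [
    {"name": "mannitol",       "mass_g": 213, "m_o": 0.00068, "C_GAB": 1.73, "k_w": 0.87},
    {"name": "avicel_ph101",   "mass_g": 96,  "m_o": 0.040,   "C_GAB": 17.4, "k_w": 0.80},
    {"name": "hypromellose",   "mass_g": 17,  "m_o": 0.018,   "C_GAB": 18.9, "k_w": 0.99},
    {"name": "croscarmellose", "mass_g": 5,   "m_o": 0.095,   "C_GAB": 13.4, "k_w": 0.92}
  ],
  "adsorbing": ["avicel_ph101", "hypromellose", "croscarmellose"]
}
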