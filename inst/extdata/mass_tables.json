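{
  "version": "1.0",
  "proton_da": 1.007276,
  "elements": {
    "monoisotopic": { "C": 12.0, "H": 1.007825, "N": 14.003074, "O": 15.994915, "S": 31.972071 },
    "average":      { "C": 12.011, "H": 1.008, "N": 14.007, "O": 15.999, "S": 32.06 }
  },
  "ptm_formulas": { "ac": "C2H2O", "me1": "CH2" }
}
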