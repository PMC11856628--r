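{
  "format": "arthroscore-spec",
  "version": 1,
  "class": "RgbBaselineSpec",
  "rMin": 102,
  "dMin": 74,
  "rMax": 1
}
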