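{
  "format": "arthroscore-spec",
  "version": 1,
  "class": "ThresholdSpec",
  "hueLo": 339.003403463668,
  "hueHi": 15.5172532790136,
  "sMin": 0.23451262168846,
  "vMin": 0.133331414447228,
  "aMin": 5.0032145693847,
  "lMax": 100,
  "gammaS": 0.592287915655714,
  "gammaA": 0.987729976354208,
  "sRef": 0.15,
  "aRef": 5,
  "rMax": 0.997389782694582
}
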