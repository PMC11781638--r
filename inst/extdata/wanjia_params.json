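{
  "n": 0.47,
  "Zr": 80,
  "beta": 13.8,
  "Sh": 0.21,
  "Sw": 0.29,
  "Sstar": 0.71,
  "Sfc": 0.76,
  "Ks": 80,
  "Delta": 0.15,
  "Emax": 0.372,
  "Ew": 0.186,
  "alpha": 0.371,
  "lambda": 0.485,
  "eta_convention": "standard"
}
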