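{
  "name": "wb97mv_semilocal",
  "version": "1.0",
  "note": "Power-series coefficients c_ij (terms w^i u^j) of the semilocal part of the omegaB97M-V enhancement factors, transcribed from the original publication (Mardirossian & Head-Gordon, J. Chem. Phys. 144, 214110, 2016). Term subsets per channel are fixed by that functional's best-subset selection.",
  "gamma": { "x": 0.004, "c_ss": 0.2, "c_os": 0.006 },
  "coefficients": {
    "x":    { "00": 0.85,  "10": 1.007,  "01": 0.259 },
    "c_ss": { "00": 0.443, "10": -1.437, "20": -4.535, "43": -0.640, "04": -3.390 },
    "c_os": { "00": 1.000, "10": 1.358,  "20": 2.924,  "60": -8.812, "21": -1.944, "61": 9.142 }
  }
}
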