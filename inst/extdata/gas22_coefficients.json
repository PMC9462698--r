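{
  "name": "gas22",
  "version": "1.0",
  "note": "Published closed-form GAS22 enhancement factors. F_x = 0.862 + 0.937 u + 0.318 w; F_c_ss = u - 4.108 w - 5.242 w^2 - 1.766 u^6 + 7.538 w^4 u^6; F_c_os = 0.805 + 7.989 w^2 - 7.548 w^6 + 2.001 w^6 x^(3/2) - 1.761 w^2 x^(3/2). The exponent of the novel x term is configurable via x_exponent; the default 3/2 follows the published description of the term as x^(3/2).",
  "gamma": { "x": 0.00384, "c_ss": 0.469 },
  "x_exponent": 1.5,
  "coefficients": {
    "x":    { "c0": 0.862, "c_u": 0.937, "c_w": 0.318 },
    "c_ss": { "c_u": 1.0, "c_w": -4.108, "c_w2": -5.242, "c_u6": -1.766, "c_w4u6": 7.538 },
    "c_os": { "c0": 0.805, "c_w2": 7.989, "c_w6": -7.548, "c_w6x": 2.001, "c_w2x": -1.761 }
  }
}
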