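{
  "lambda": 1.104,
  "L_cm": 0.19,
  "g_coef": [-0.01239342, -0.00102611],
  "F_a": {
    "r_cm": [1, 2, 3, 4, 5, 10],
    "a": [0.142, 0.151, 0.137, 0.096, 0.073, 0.087]
  },
  "F_b": 0
}
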