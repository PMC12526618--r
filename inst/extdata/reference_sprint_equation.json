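{
  "description": "Reference closed-form sprint-velocity model shipped as the package's worked example of a symbolically compressed network. Inputs: x1-x3 alpha/beta/gamma band coherence of the RA-BF muscle pair, x4-x6 alpha/beta/gamma band coherence of the TA-GL muscle pair, x7-x9 rectus femoris iEMG (mV s), RMS (mV), median frequency (Hz). Output: sprint phase velocity (m/s).",
  "intercept": 11.085,
  "equation": "y = 11.085 - 0.0017*x1 - 0.0002*x3 - 0.0016*x5 - 0.0036*x6 + 0.2996*x7 + 0.0005*x8 - 0.0006*x9 + 1.168e-05*exp(2.6409*x2) + 3.561e-06*exp(2.6896*x4)",
  "terms": [
    {"family": "x", "input": 1, "a": 1, "b": 0, "c": -0.0017, "d": 0},
    {"family": "x", "input": 3, "a": 1, "b": 0, "c": -0.0002, "d": 0},
    {"family": "x", "input": 5, "a": 1, "b": 0, "c": -0.0016, "d": 0},
    {"family": "x", "input": 6, "a": 1, "b": 0, "c": -0.0036, "d": 0},
    {"family": "x", "input": 7, "a": 1, "b": 0, "c": 0.2996, "d": 0},
    {"family": "x", "input": 8, "a": 1, "b": 0, "c": 0.0005, "d": 0},
    {"family": "x", "input": 9, "a": 1, "b": 0, "c": -0.0006, "d": 0},
    {"family": "exp", "input": 2, "a": 2.6409, "b": 0, "c": 1.168e-05, "d": 0},
    {"family": "exp", "input": 4, "a": 2.6896, "b": 0, "c": 3.561e-06, "d": 0}
  ]
}
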