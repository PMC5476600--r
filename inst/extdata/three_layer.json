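{
  "name": "three_layer_tissue",
  "layer": [
    {"mu_a": 0.02,  "musp": 2.0, "g": 0.8, "n": 1.4, "thickness": 1},
    {"mu_a": 0.003, "musp": 1.0, "g": 0.8, "n": 1.4, "thickness": 2},
    {"mu_a": 0.02,  "musp": 0.5, "g": 0.8, "n": 1.4, "thickness": "inf"}
  ],
  "n_external_top": 1.0,
  "beam": {"profile": "gaussian", "rho_w": 0.5},
  "solver": {"type": "pn", "N": 9, "domain": "spatial"}
}
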