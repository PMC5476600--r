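# Two-layer fluorescent tissue: emission-wavelength properties 20% below
# their excitation counterparts; only the upper layer fluoresces.
name: fluorescence_two_layer
layer:
  - mu_a: 0.02
    musp: 2.0
    g: 0.8
    n: 1.4
    thickness: 2
    fluorescence:
      mu_a: 0.016
      musp: 1.6
      g: 0.8
      quantum_yield: 1.0
  - mu_a: 0.03
    musp: 0.5
    g: 0.8
    n: 1.4
    thickness: inf
    fluorescence:
      mu_a: 0.024
      musp: 0.4
      g: 0.8
      quantum_yield: 0.0
n_external_top: 1.0
beam:
  profile: gaussian
  rho_w: 0.5
solver:
  type: pn
  N: 3
  domain: spatial
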