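# Reference radical pair: two peroxyl-like radicals, one spin-1/2 proton
# each with an isotropic hyperfine coupling (the dominant proton adjacent to
# the peroxide group; its motionally averaged tensor is close to isotropic).
# g is the isotropic average of the peroxyl-like eigenvalues
# (2.0023, 2.0072, 2.0329); hyperfine tensors in rad/ns, rates in 1/s.
radicals:
  - g: [2.0141333, 0, 0, 0, 2.0141333, 0, 0, 0, 2.0141333]
    nuclei:
      - label: H13X_1
        I: 0.5
        A: [0.3, 0, 0, 0, 0.3, 0, 0, 0, 0.3]
  - g: [2.0141333, 0, 0, 0, 2.0141333, 0, 0, 0, 2.0141333]
    nuclei:
      - label: H13X_2
        I: 0.5
        A: [0.3, 0, 0, 0, 0.3, 0, 0, 0, 0.3]
kinetics:
  kS_per_s: 2.0e8
  kST_per_s: 1.0e6
field:
  Bz_mT: 0.0
initial_state: triplet
free_electron_g: 2.0013
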