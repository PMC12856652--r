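# Relaxation inputs for the reference radical pair. Effective correlation
# times follow the membrane analysis (hyperfine 0.92 ns, g-tensor 1.21 ns,
# peroxide-group rotation 0.97 ns). Covariances are representative values
# for a peroxyl radical whose g-anisotropy (span ~0.03) is strongly
# modulated by the peroxide rotation while the hyperfine anisotropy is
# small: the regime where g-fluctuations dominate relaxation.
tau_omega_ns: 0.97
# g-matrix eigenvalue deviations from the free-electron g-factor 2.0013
delta_g: [0.0010, 0.0059, 0.0316]
hyperfine:
  tau_ns: 0.92
  # rad^2/ns^2; unlisted cross pairs are zero
  cov:
    xx: 1.0e-5
    yy: 1.0e-5
    zz: 1.0e-5
    xy: 1.0e-5
    xz: 1.0e-5
    yz: 1.0e-5
g_tensor:
  tau_ns: 1.21
  # dimensionless variances of the z-row g components; cross pairs zero
  cov:
    zx: 2.0e-4
    zy: 2.0e-4
    zz: 4.0e-4
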