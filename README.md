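# spinmfe

Spin-dynamics toolkit for **magnetic field effects (MFEs) on radical-pair
recombination**, built around the question of whether such effects survive
spin relaxation in fluid lipid membranes. The motivating system is a pair of
lipid peroxyl radicals whose recombination terminates lipid autoxidation:
singlet pairs recombine (rate constant $k_S$), singlet and triplet pairs
escape and propagate the chain (rate constant $k_{ST}$), and hyperfine and
Zeeman interactions interconvert singlet and triplet — so an applied field
changes the triplet yield

$$\Phi_T = k_{ST}\int_0^\infty \mathrm{Tr}\big(\hat P_T\,\rho(B,t)\big)\,dt ,$$

where $\rho$ obeys a stochastic Liouville equation with the spin Hamiltonian
$\hat H = \sum_i (\mu_B \mathbf B\cdot\mathbf g_i\cdot\hat{\mathbf S}_i/\hbar
+ \sum_n \hat{\mathbf I}_{i,n}\cdot\mathbf A_{i,n}\cdot\hat{\mathbf S}_i)$,
a Haberkorn reaction superoperator, and Bloch–Redfield–Wangsness (BRW)
relaxation built from the covariance functions of fluctuating hyperfine and
g-tensor components:

* covariance curves are estimated by FFT and fitted with 50 exponential
  decays on a fixed logarithmic lag grid (0.5 ps – 100 ns), giving effective
  correlation times $\tau_{\rm eff}=\sum_j c_j\tau_j$ and zero-frequency
  spectral densities $J(0)=\mathrm{cov}\sum_j c_j\tau_j$;
* three relaxation channels — hyperfine fluctuations, g-tensor fluctuations
  (scaling as $B_z^2$), and spin rotation with
  $k_{sr}=\Delta g^2/(9\tau^\Omega)$ — enter additively;
* yields are computed by an exact Liouville-space linear solve (time-domain
  propagation is kept only as a test oracle).

A synthetic-dynamics module generates surrogate dihedral/orientation
trajectories (Metropolis walk on a 1° grid with an excluded window and a
calibrated ~1 ns cos Ω correlation time; isotropic quaternion walk for slower
fragment tumbling) and dihedral→tensor mapping tables, so the complete
pipeline — trajectories → covariances → multiexponential fits → relaxation
superoperators → field scans — runs with no external data.

## Worked example

Triplet yield of the shipped reference pair (two peroxyl-like radicals, one
isotropic spin-1/2 proton each, 1 µs lifetime), static versus relaxing:

```r
library(spinmfe)
ref <- reference_system(kST_per_s = 1e6)     # 1 us lifetime
cfg <- scan_config(ref$system, ref$relax, kST_per_s = 1e6,
                   channel_sets = list(static = character(0), g = "g",
                                       all = c("hf", "g", "sr")))
res <- run_field_scan(cfg, quiet = TRUE)
print(res)
#> Field scan: 183 records (60 fields x 1 lifetimes x 3 channel sets)
#> yield ranges by channel set:
#>   static   phi_T in [0.5118, 0.8298]
#>   g        phi_T in [0.0448, 0.6695]
#>   all      phi_T in [0.0448, 0.6167]
```

Reading these numbers: without relaxation the zero-field yield is 0.6695,
dips to 0.5118 at 1.48 mT (the low-field effect: weak fields open extra
singlet–triplet mixing pathways, draining triplet pairs into recombination)
and rises to 0.8298 at high field where hyperfine mixing is suppressed. With
relaxation enabled the picture inverts at high field: g-tensor fluctuations
dephase the pair at a rate growing as $B_z^2$, so at 100 mT the triplet
yield collapses to 0.0448 — a field-induced change of −0.57, i.e. relaxation
*creates* a large MFE instead of erasing it, while the hyperfine and
spin-rotational channels barely move the curve. `mfe_metric(res)` tabulates
$\Delta\Phi_T(B)=\Phi_T(B)-\Phi_T(0)$ per series, and `plot(res)` draws the
field dependence.

The covariance side of the pipeline works the same way from code or files:

```r
p  <- synthetic_params(target_tau_ns = 1.0, seed = 42)
tr <- sample_dihedral_trajectory(p)          # calibrated Metropolis chain
s  <- scalar_series(cos(tr$values * pi/180), dt_ps = 1)
m  <- fit_cov_model(series_covariance(s, max_lag_ns = 50))
effective_correlation_time(m)                # ~1.0 ns
```

A thin command-line wrapper (`inst/cli/spinmfe.R`) exposes the same steps as
`synth`, `analyze`, `fit`, `scan` and `report` subcommands.

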