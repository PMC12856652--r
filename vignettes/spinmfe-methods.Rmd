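---
title: "Radical-pair spin dynamics with fluctuation-driven relaxation: models and methods"
author: "spinmfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radical-pair spin dynamics with fluctuation-driven relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinmfe)
```

# The problem

Termination of lipid autoxidation proceeds by pairwise recombination of
lipid peroxyl radicals. While the two radicals diffuse as a pair, their two
unpaired electron spins form a coupled quantum system whose singlet/triplet
character gates reactivity: only singlet pairs can recombine to closed-shell
products, while both singlet and triplet pairs can separate and propagate
the chain. Hyperfine and Zeeman interactions interconvert singlet and
triplet on the nanosecond scale, which makes the branching ratio — and hence
the steady-state radical population — sensitive to an applied magnetic
field (a magnetic field effect, MFE). Whether such effects survive in a
fluid membrane hinges on spin relaxation: thermal motion modulates the
hyperfine and g-tensors and can destroy the spin coherence the mechanism
needs.

`spinmfe` implements the full modelling chain for this question: a spin
Hamiltonian and reaction-kinetics model of the radical pair, estimation of
interaction-fluctuation statistics from trajectories, Bloch–Redfield–
Wangsness (BRW) relaxation superoperators built from those statistics, and
triplet-yield field scans with and without the individual relaxation
channels. A synthetic-dynamics module generates surrogate trajectories with
the statistical structure the analysis assumes, so the entire pipeline runs
and is testable without molecular-dynamics or quantum-chemistry inputs.

# Spin system and reaction kinetics

The Hilbert space is the tensor product of the two electron spin-1/2 spaces
with the spaces of all coupled nuclei, of dimension $4\prod_i\prod_{n}(2I_{i,n}+1)$.
The static Hamiltonian (angular-frequency units, rad/ns) is

$$\hat H = \sum_{i=1}^{2}\Big(\mu_B \mathbf{B}\cdot\mathbf{g}_i\cdot\hat{\mathbf S}_i/\hbar
+ \sum_{n}\hat{\mathbf I}_{i,n}\cdot\mathbf{A}_{i,n}\cdot\hat{\mathbf S}_i\Big),$$

with full $3\times3$ g-matrices and hyperfine tensors; for a field along
$z$ (perpendicular to the membrane) the Zeeman term reduces to
$\mu_B B_z(g_{zx}\hat S_x + g_{zy}\hat S_y + g_{zz}\hat S_z)_i/\hbar$.
Fields are supplied in mT and rates in 1/ns internally (1/s at file
boundaries); the conversion factor $\mu_B/\hbar = 0.08794$ rad/(ns·mT) is
carried by `phys_constants()`. The free-electron g-factor defaults to
2.0013 for consistency with the spin-rotational estimate used in this model
family; note this differs from the CODATA value (≈2.00232) and can be
overridden.

Reaction kinetics follow the conventional Haberkorn form: singlet-selective
recombination at rate $k_S$ (default $0.2\,\mathrm{ns}^{-1}$, i.e.
$2\times10^8\,\mathrm{s}^{-1}$) enters as
$\tfrac{k_S}{2}\{\hat P_S,\rho\}$, and spin-independent escape/propagation
at rate $k_{ST}$ as a scalar decay. The master equation in Liouville space
is $\dot\rho = -(i\hat H^\times + \hat{\hat K} + \hat{\hat R})\rho$, with
column-stacking vectorization. The triplet yield
$\Phi_T = k_{ST}\int_0^\infty \mathrm{Tr}(\hat P_T\rho(t))\,dt$ is computed
*algebraically*: the stationary integral $X=\int\rho\,dt$ solves the linear
system $LX=\rho_0$, so there is no quadrature truncation error, and the
three channel yields ($\Phi_T$, singlet propagation, singlet recombination)
sum to 1 identically. Time-domain propagation with an exact per-step
integral operator ($\int_0^h e^{-Ls}ds$, built by scaling-and-doubling) is
retained purely as a test oracle; the two routes agree to $10^{-6}$ on
random 16-dimensional pairs.

Initial states: `triplet` ($\hat P_T/3Z$), `singlet` ($\hat P_S/Z$), and
`f_pair` — the maximally mixed electronic state of radicals formed by
random encounters, carrying singlet/triplet probabilities 1/4 and 3/4.
The singlet projector is built from
$|S\rangle = (|\!\uparrow\downarrow\rangle-|\!\downarrow\uparrow\rangle)/\sqrt2$
in the Zeeman product basis, which pins all sign conventions; the
tensor-factor ordering (electron 1, electron 2, nuclei of radical 1, nuclei
of radical 2) is fixed so operator matrices are reproducible bit-for-bit.

# Fluctuation statistics

Relaxation is driven by the fluctuations $\Delta A_\alpha(t)$,
$\Delta g_\alpha(t)$ of tensor components along a trajectory
($\alpha \in \{xx, xy, \dots, zz\}$). `series_covariance()` estimates
auto-/cross-covariances with the biased $1/N$ estimator after mean removal,
via zero-padded FFTs (identical to the direct double sum to $10^{-10}$;
the biased estimator is the stable choice at long lags). Because the
tensors are symmetric and covariance is exchange-symmetric, only 21 of the
81 ordered component pairs are distinct (`distinct_component_pairs()`).

Each covariance curve is fitted as
$g_{\alpha\beta}(\tau) \approx \mathrm{cov}_{\alpha\beta}\sum_{j=1}^{50} c_j e^{-\tau/\tau_j}$
on a fixed logarithmic grid of 50 lag times from 0.5 ps to 100 ns, by
non-negative least squares with post-hoc renormalization to
$\sum_j c_j = 1$. Two numerical choices stabilize this severely
ill-conditioned basis against estimator noise:

* **Variance-stabilizing weights.** Residuals are weighted by
  $1/\sqrt{\tau + \Delta t}$, the inverse of the Bartlett-type growth of
  the covariance estimator's standard error with lag. Noiseless curves are
  fitted identically with or without weighting.
* **Identifiability cutoff.** Grid exponentials slower than half the fitted
  lag window (default window 50 ns) are excluded from the basis: over the
  window they are indistinguishable from a constant baseline, and under the
  non-negativity constraint they act as a one-sided trap for noise — a
  weight of only 0.005 on the 100 ns grid point shifts the effective
  correlation time by 0.5 ns.

The effective correlation time is $\tau_{\mathrm{eff}} = \sum_j c_j\tau_j$
(equal to the integral of the normalized fitted curve), and the
zero-frequency spectral density is
$J_{\alpha\beta}(0) = \mathrm{cov}_{\alpha\beta}\sum_j c_j\tau_j$, the
one-sided integral with no factor of two; imaginary parts (dynamic
frequency shifts) are discarded. For g-tensor components the field factor
$(\mu_B B_z/\hbar)^2$ is deliberately *not* part of the stored model — it
is applied when the relaxation superoperator is built, so one fitted model
serves every field point.

# Relaxation channels

All channels enter $\dot\rho = -R\rho$ with $R$ damping: a mandatory test
pins the sign by behavior (identity stationary, coherences decay) rather
than bookkeeping. The three channels add.

**Hyperfine fluctuations** (`hyperfine_redfield()`). Fluctuation operators
$\hat A_{ab} = \hat I_a\hat S_b$ for the significant nucleus of each
radical (one proton dominates the coupling in the motivating system;
others enter the static Hamiltonian only). In the default zero-frequency
(extreme-narrowing) evaluation,
$R\rho = \sum_{\alpha\beta} J_{\alpha\beta}(0)\,[\hat A_\alpha,[\hat A_\beta,\rho]]$.
The underlying theory is formulated in the interaction picture with
time-dependent operators; evaluating the spectral densities at
$\omega = 0$ makes the Schrödinger-picture implementation with stationary
operators exact, which is the regime the working formulas assume. An
optional `eigenbasis` mode instead evaluates Lorentzian spectral densities
$J(\omega) = \mathrm{cov}\sum_j c_j\tau_j/(1+(\omega\tau_j)^2)$ at the
transition frequencies of the static Hamiltonian; it reduces to the
zero-frequency form in the fast-fluctuation limit (tested) and exists for
validity checks. Cross-radical fluctuation correlations are taken as zero.

**g-tensor fluctuations** (`g_redfield()`). With the field along $z$, only
the $z$-row components $\Delta g_{zx}, \Delta g_{zy}, \Delta g_{zz}$ couple,
with operators $\hat S_x, \hat S_y, \hat S_z$ per radical and 6 distinct
covariance pairs. The superoperator carries the $(\mu_B B_z/\hbar)^2$
factor and therefore scales exactly as $B_z^2$; the scan pipeline exploits
this by building it once at 1 mT and rescaling per field point. Transverse
fields are rejected by this builder (out of scope).

**Spin rotation** (`spin_rotational_superoperator()`). Isotropic
depolarization at rate $k_{sr} = \Delta g^2/(9\tau^\Omega)$ with
$\Delta g^2 = \sum_n (g_{nn}-g_e)^2$ over the g-matrix eigenvalues and
$\tau^\Omega$ the rotational correlation time of the peroxide group — an
upper bound, since that is the fastest rotation in the system. The
superoperator is
$k_{sr}\big(\tfrac32\rho - \sum_i\sum_k \hat S_{ik}\rho\hat S_{ik}\big)$,
which annihilates the identity because $\sum_k \hat S_k\hat S_k = \tfrac34$
per electron.

# Tensor mapping

`map_trajectory()` converts a dihedral-angle trajectory plus a
fragment-orientation trajectory into lab-frame tensor trajectories using a
lookup table on a 1° dihedral grid (nearest neighbor, ties toward the
lower angle, periodic wrapping; linear interpolation was considered and
rejected because the reference protocol matches scanned structures
directly). Rotations are active, $T_{\mathrm{lab}} = R\,T_{\mathrm{frag}}\,R^\top$
with $R$ from unit quaternions stored (w, x, y, z); eigenvalues and traces
are preserved along the trajectory to machine precision, so the mapping
adds no spurious fluctuation. Angles falling in a window not covered by the
table raise an error naming the window.

# Synthetic dynamics

The generator emulates the statistical features the analysis consumes, not
the molecular detail:

* **Dihedral angle.** A Metropolis random walk on the periodic 1° grid
  with nearest-neighbor proposals. The stationary density is an explicit
  von Mises mixture (default: two equal lobes at ±100°, concentration 2)
  with a hard zero inside an excluded window (default 60° around 0°,
  emulating the sterically forbidden range of the peroxide rotation; the
  width is a free parameter, not a measured value). A discrete chain was
  chosen over continuous Langevin dynamics because it gives exact control
  of the stationary density including the hard window, and its diffusive
  character makes the correlation time calibrable: $\tau \times$ (attempts
  per frame) is nearly constant.
* **Calibration.** Two coarse iterations using a self-consistent windowed
  integrated-autocorrelation estimator on ~0.4M-frame pre-runs bracket the
  hop rate; three refinement iterations at full length then use the *same*
  covariance→fit→$\sum c_j\tau_j$ estimator that consumers of the
  trajectory use (so estimator bias cancels), with updates through the
  log-mean of the measured $\tau \times$ attempts product.
* **Orientation.** An isotropic rotational random walk: per frame a
  Gaussian rotation angle (default scale 0.015 rad) about a uniform random
  axis, giving rank-2 reorientation times of a few ns — slower than the
  dihedral rotation, as in the membrane.
* **Tensors.** The hyperfine tensor is $a_{\mathrm{iso}}\mathbb 1$ plus a
  small axial part whose principal frame rotates with the dihedral about
  the bond axis; the g-tensor is the fixed-eigenvalue peroxyl-like tensor
  (2.0023, 2.0072, 2.0329) rotated the same way. Eigenvalues are
  Ω-independent by construction, so all lab-frame fluctuation comes from
  the two motions. Defaults ($a_{\mathrm{iso}} = 0.3$ rad/ns ≈ 48 MHz,
  anisotropy 0.03 rad/ns) are EPR-plausible configuration values, chosen
  once; $a_{\mathrm{iso}}$ places the low-field structure near 1 mT.

What the generator does *not* emulate: multi-lipid structural observables,
anisotropic rotational diffusion, coupling between dihedral state and
reorientation, or any chemistry. Tests passing on synthetic data therefore
validate the statistical pipeline (estimators, fits, superoperator
construction, yield computation), not force-field realism.

## Ensemble correlation-time measurement

`measure_dihedral_tau()` mirrors the ensemble design of the motivating
analysis (12 radicals): 12 independent trajectories at the calibrated hop
rate, one fit each, and the per-trajectory effective times combined. The
*median* is reported as the location estimate (the mean alongside): under
the non-negativity constraint, single multiexponential fits have one-sided
heavy-tailed errors — occasional spurious weight on slow grid exponentials
— and the median of 12 suppresses these outliers; the plain mean is biased
upward by them. Recovery of targets {0.3, 1, 3} ns at 1.36M frames is
within ±9% across seeds, against an acceptance band of 15%.

# Reference system and field scans

The shipped reference configuration (`reference_system()`) is the minimal
pair carrying the phenomenology: two peroxyl-like radicals with isotropic
g = 2.01413 (the eigenvalue average) and one spin-1/2 proton each with
isotropic hyperfine coupling 0.3 rad/ns. Relaxation inputs use the
effective correlation times of the membrane analysis (hyperfine 0.92 ns,
g-tensor 1.21 ns, peroxide rotation 0.97 ns) with covariances chosen once
as representative of a peroxyl radical whose g-anisotropy (span ≈ 0.03) is
strongly modulated by the peroxide rotation while the hyperfine anisotropy
is small: var(Δg_zz) = 4×10⁻⁴, var(Δg_zx) = var(Δg_zy) = 2×10⁻⁴, hyperfine
component covariance 10⁻⁵ rad²/ns². The exact tensor statistics of the
membrane system are not published as numbers; these values reproduce its
qualitative regime — g-fluctuations dominate relaxation, hyperfine and
spin-rotational channels are nearly negligible.

`run_field_scan()` sweeps a logarithmic field grid (default 60 points,
0.01–100 mT, resolving both the ~1 mT low-field region and the high-field
decade) for each escape rate (defaults spanning lifetimes 1 ns–10 μs) and
channel set, always including a zero-field reference;
`mfe_metric()` reports $\Delta\Phi_T(B) = \Phi_T(B)-\Phi_T(0)$.

```{r scan, eval = FALSE}
ref <- reference_system(kST_per_s = 1e6)          # 1 us lifetime
cfg <- scan_config(ref$system, ref$relax, kST_per_s = 1e6)
res <- run_field_scan(cfg)
summary(res)
plot(res, kST_per_s = 1e6)
```

On this system the static (relaxation-free) curve shows the classic
low-field minimum near 1 mT and levels off at high field; switching on the
g-channel suppresses the triplet yield increasingly with $B_z^2$ (complete
suppression at 100 mT for microsecond lifetimes, as relaxed pairs drain
through the singlet channel), while hyperfine-only and spin-rotational-only
ablations stay close to the static curve. These orderings are asserted by
the test suite rather than quoted here.

# Numerical choices and degenerate inputs

* Liouville dimension for the reference pair is $16^2 = 256$; scans solve
  one complex 256×256 linear system per point (~ms), so a full
  60×6×5 scan takes well under a minute.
* The time-domain oracle integrates over 20 lifetimes with 400 exact
  integral steps; the neglected tail is $e^{-20}\approx 2\times10^{-9}$
  relative.
* `channel_yields()` requires $k_{ST}>0$ (the Liouvillian is then strictly
  dissipative and invertible); $k_{ST}=0$ raises an error advising
  time-domain integration.
* All-zero covariance curves yield a flagged degenerate model with zero
  prefactor; zero rates and zero fields yield exactly zero superoperators.
* Hyperfine tensors are symmetrized $(A+A^\top)/2$ on input; the
  21-distinct-pair bookkeeping presumes this symmetry.
* Test and acceptance problem sizes: property tests use 8-dimensional
  pairs and trajectories of 0.2–1M frames; the recovery measurement uses
  the full 1.36M-frame, 12-replicate design.

# Known limitations

* No nuclear Zeeman terms, no interradical exchange/dipolar coupling, no
  three-radical effects, and at most two radicals — deliberate scope
  bounds; interradical couplings would attenuate low-field effects.
* The g-relaxation builder is specific to z-aligned fields.
* The zero-frequency BRW evaluation is a second-order, extreme-narrowing
  theory; it is inaccurate when interaction fluctuations are slow or
  strong compared with the spin dynamics. The eigenbasis mode relaxes the
  frequency assumption but not the perturbative one.
* The spin-rotational rate is an upper-bound estimate assuming isotropic
  rotational diffusion.
* Effective correlation times of strongly multi-modal covariances are
  window-limited: components slower than half the fitted window are
  excluded by design.
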