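# Shared builders and independent oracles for the test suite.

# Random two-radical spec with one spin-1/2 nucleus per radical (Hilbert
# dimension 16), anisotropic tensors, field in [0, 100] mT and kST spanning
# lifetimes 1 ns .. 10 us.
random_spec16 <- function(seed) {
  set.seed(seed)
  rand_sym <- function(scale) {
    M <- matrix(rnorm(9, sd = scale), 3, 3)
    (M + t(M)) / 2
  }
  rad <- function() {
    g <- diag(3) * runif(1, 1.9, 2.1) + rand_sym(0.01)
    A <- diag(3) * rnorm(1, 0, 0.3) + rand_sym(0.1)
    radical_spec(g, list(nucleus_spec("H", 0.5, A)))
  }
  spin_system(rad(), rad(),
              kS = 0.2,
              kST = 10^runif(1, -4, 0),
              B = c(0, 0, runif(1, 0, 100)),
              initial = sample(c("triplet", "singlet", "f_pair"), 1))
}

# Random relaxation inputs compatible with random_spec16. Covariance
# matrices over the component alphabet are drawn positive semidefinite
# (X^T X), as physical fluctuation statistics are.
random_relax <- function(seed, cov_scale = 1e-4) {
  set.seed(seed)
  mk_models <- function(comps, scale) {
    n <- length(comps)
    X <- matrix(rnorm(n * n), n)
    S <- crossprod(X) / n * scale
    ms <- list()
    for (i in seq_len(n)) for (j in i:n) {
      a <- comps[i]; b <- comps[j]
      key <- spinmfe:::pair_key(a, b)
      ms[[key]] <- cov_model_simple(S[i, j], runif(1, 0.3, 3), c(a, b))
    }
    ms
  }
  hfm <- mk_models(c("xx", "xy", "xz", "yy", "yz", "zz"), cov_scale)
  gm <- mk_models(c("zx", "zy", "zz"), cov_scale)
  relaxation_inputs(hf = list(hfm, hfm), g = list(gm, gm),
                    tau_omega_ns = runif(1, 0.5, 2),
                    delta_g = abs(rnorm(3, 0, 0.01)))
}

rand_hermitian <- function(d) {
  M <- matrix(rnorm(d * d) + 1i * rnorm(d * d), d)
  (M + Conj(t(M))) / 2
}

# O(N^2) double-loop biased covariance estimator (oracle for the FFT path).
cov_direct <- function(x, y, nlag) {
  N <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  vapply(0:nlag, function(k)
    sum(xc[(k + 1):N] * yc[1:(N - k)]) / N, 0)
}

# Numeric one-sided integral of the normalized model curve (quadrature
# oracle for effective_correlation_time / spectral_density_zero).
model_integral_numeric <- function(model, t_max = 2000, n = 400000) {
  tt <- seq(0, t_max, length.out = n)
  v <- predict(model, tt, normalized = TRUE)
  sum((v[-1] + v[-n]) / 2) * (tt[2] - tt[1])
}

# Decay rate of a density-matrix element under propagation with a single
# relaxation superoperator (no Hamiltonian): fits log|rho_ij(t)|.
element_decay_rate <- function(R, rho0, i, j, t_end, steps = 60) {
  L <- R
  times <- seq(0, t_end, length.out = steps + 1)
  tr <- propagate_density(L, rho0, times)
  amp <- vapply(tr$rhos, function(r) Mod(r[i, j]), 0)
  keep <- amp > amp[1] * 1e-6
  fit <- stats::lm(log(amp[keep]) ~ times[keep])
  -unname(coef(fit)[2])
}

ref_paths <- function() {
  list(system = system.file("extdata", "reference_system.yaml",
                            package = "spinmfe", mustWork = TRUE),
       relax = system.file("extdata", "reference_relaxation.yaml",
                           package = "spinmfe", mustWork = TRUE))
}
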