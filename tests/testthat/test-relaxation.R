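# Two-radical system with one spin-1/2 nucleus on radical 1 only (dim 8),
# used by the closed-form oracles.
relax_test_system <- function() {
  sys <- spin_system(radical_spec(diag(3) * 2.002,
                                  list(nucleus_spec("H", 0.5, diag(3) * 0.3))),
                     radical_spec(diag(3) * 2.002),
                     kST = 1e-3, B = 0)
  list(sys = sys, ops = build_spin_operators(sys))
}

# Models with a single non-zero component pair; stored under the canonical
# pair keys the relaxation builders look up.
single_pair_models <- function(pair, cov, tau, all_keys) {
  ms <- list()
  for (k in all_keys) {
    p <- strsplit(k, ":")[[1]]
    key <- spinmfe:::pair_key(p[1], p[length(p)])
    ms[[key]] <- cov_model_simple(if (k == pair) cov else 0, tau,
                                  c(p[1], p[length(p)]))
  }
  ms
}

hf_keys <- apply(distinct_component_pairs(TRUE)[, 1:2], 1, paste, collapse = ":")
g_keys <- c("zx:zx", "zy:zy", "zz:zz", "zx:zy", "zx:zz", "zy:zz")

test_that("relaxation superoperators are trace-preserving and unital", {
  st <- relax_test_system()
  rx <- random_relax(13)
  rx$hf[2] <- list(NULL)  # radical 2 has no nucleus here
  Rs <- list(hf = hyperfine_redfield(rx, st$ops),
             g = g_redfield(rx, 50, st$ops),
             sr = spin_rotational_superoperator(0.02, st$ops))
  d <- st$ops$dim
  set.seed(1)
  for (R in Rs) {
    for (k in 1:50) {
      rho <- rand_hermitian(d)
      out <- matrix(R %*% as.vector(rho), d)
      expect_lt(abs(sum(diag(out))), 1e-12)
    }
    expect_lt(max(Mod(R %*% as.vector(diag(d) + 0i))), 1e-12)
  }
})

test_that("hyperfine channel reproduces the two-spin dephasing closed form", {
  st <- relax_test_system()
  cov <- 0.04; tau <- 1
  rx <- relaxation_inputs(
    hf = list(single_pair_models("zz:zz", cov, tau, hf_keys), NULL),
    tau_omega_ns = 1)
  R <- hyperfine_redfield(rx, st$ops)
  # zero models -> zero superoperator
  rx0 <- relaxation_inputs(
    hf = list(single_pair_models("zz:zz", 0, tau, hf_keys), NULL),
    tau_omega_ns = 1)
  expect_lt(max(Mod(hyperfine_redfield(rx0, st$ops))), 1e-15)
  # pure zz fluctuation: A = Iz Sz has eigenvalues +-1/4; a coherence
  # between eigenstates with d_a - d_b = 1/2 decays at J0 (d_a - d_b)^2
  J0 <- cov * tau
  d <- st$ops$dim
  rho0 <- matrix(0i, d, d)
  # basis ordering (e1, e2, n1): |up,up,up> = 1, |up,up,dn> = 2;
  # element (1,2): m_S1 m_I = +1/4 vs -1/4
  rho0[1, 2] <- 1; rho0[2, 1] <- 1
  rate <- element_decay_rate(R, rho0, 1, 2, t_end = 2 / (J0 * 0.25))
  expect_equal(rate, J0 * 0.25, tolerance = 0.05)
  # missing pair -> informative error
  ms <- single_pair_models("zz:zz", cov, tau, hf_keys)
  ms[["xx:xy"]] <- NULL
  rxm <- relaxation_inputs(hf = list(ms, NULL), tau_omega_ns = 1)
  expect_error(hyperfine_redfield(rxm, st$ops), "xx:xy")
})

test_that("g channel scales as Bz^2 and reproduces pure dephasing", {
  st <- relax_test_system()
  cov <- 2e-4; tau <- 1.21
  rx <- relaxation_inputs(
    g = list(single_pair_models("zz:zz", cov, tau, g_keys), NULL),
    tau_omega_ns = 1)
  expect_lt(max(Mod(g_redfield(rx, 0, st$ops))), 1e-15)
  R1 <- g_redfield(rx, 25, st$ops)
  R2 <- g_redfield(rx, 50, st$ops)
  expect_lt(max(Mod(R2 - 4 * R1)), 1e-12 * max(Mod(R2)))
  # transverse electron coherence decays at (muB Bz / hbar)^2 J0 for pure
  # Sz dephasing
  pc <- phys_constants()
  Bz <- 25
  rate_pred <- (pc$gamma_mT_ns * Bz)^2 * cov * tau
  d <- st$ops$dim
  # element between electron-1 up and down with all else fixed:
  # (e1,e2,n1) kron ordering, stride of e1 flip is 4
  rho0 <- matrix(0i, d, d)
  rho0[1, 5] <- 1; rho0[5, 1] <- 1
  rate <- element_decay_rate(R1, rho0, 1, 5, t_end = 2 / rate_pred)
  expect_equal(rate, rate_pred, tolerance = 0.05)
  expect_error(g_redfield(rx, c(1, 0, 10), st$ops), "z-aligned")
})

test_that("spin-rotational rate follows the eigenvalue-deviation formula", {
  expect_equal(spin_rotational_rate(c(0, 0, 0), 1), 0)
  expect_equal(spin_rotational_rate(c(1e-3, 1e-3, 1e-3), 1),
               3e-6 / 9, tolerance = 1e-12)
  k1 <- spin_rotational_rate(c(0.002, 0.005, 0.03), 0.97)
  k2 <- spin_rotational_rate(c(0.002, 0.005, 0.03), 2 * 0.97)
  expect_equal(k1, 2 * k2, tolerance = 1e-12)
  expect_error(spin_rotational_rate(c(0, 0, 0), -1), "positive")
})

test_that("spin-rotational superoperator depolarizes without touching identity", {
  st <- relax_test_system()
  expect_lt(max(Mod(spin_rotational_superoperator(0, st$ops))), 1e-15)
  R <- spin_rotational_superoperator(0.05, st$ops)
  d <- st$ops$dim
  expect_lt(max(Mod(R %*% as.vector(diag(d) + 0i))), 1e-13)
  # Sx-type electron coherence decays monotonically under this channel alone
  Sx <- st$ops$electrons[[1]]$x
  rho0 <- diag(d) / d + 0.3 * Sx / d
  tr <- propagate_density(R, rho0, seq(0, 80, length.out = 21))
  cohere <- vapply(tr$rhos, function(r) Re(sum(r * t(Sx))), 0)
  expect_true(all(diff(cohere) < 0))
  expect_error(spin_rotational_superoperator(-0.1, st$ops), "non-negative")
})

test_that("channels add per the decomposition and scale with covariance", {
  st <- relax_test_system()
  rx <- random_relax(23)
  rx$hf[2] <- list(NULL)
  sys <- st$sys; sys$B <- c(0, 0, 30)
  Rall <- build_relaxation(sys, st$ops, rx)
  Rsum <- hyperfine_redfield(rx, st$ops) +
    g_redfield(rx, 30, st$ops, sys$constants) +
    spin_rotational_superoperator(
      spin_rotational_rate(rx$delta_g, rx$tau_omega_ns), st$ops)
  expect_lt(max(Mod(Reduce(`+`, Rall) - Rsum)), 1e-12)
  # linearity: scaling every covariance by s scales the channel by s
  s <- 3.7
  rx_s <- rx
  rx_s$hf[[1]] <- lapply(rx$hf[[1]], function(m) {
    m$prefactor <- s * m$prefactor; m
  })
  expect_lt(max(Mod(hyperfine_redfield(rx_s, st$ops) -
                      s * hyperfine_redfield(rx, st$ops))), 1e-12)
})

test_that("propagation with a single channel preserves Hermiticity", {
  st <- relax_test_system()
  rx <- random_relax(31)
  rx$hf[2] <- list(NULL)
  d <- st$ops$dim
  set.seed(4)
  rho0 <- rand_hermitian(d); rho0 <- rho0 / Re(sum(diag(rho0)))
  for (R in list(hyperfine_redfield(rx, st$ops),
                 g_redfield(rx, 40, st$ops),
                 spin_rotational_superoperator(0.01, st$ops))) {
    tr <- propagate_density(R, rho0, seq(0, 50, length.out = 11))
    herm <- vapply(tr$rhos, function(r) max(Mod(r - Conj(t(r)))), 0)
    expect_lt(max(herm), 1e-9)
  }
})

test_that("eigenbasis mode reduces to zero-frequency for fast fluctuations", {
  st <- relax_test_system()
  # all weight on the shortest grid time: omega * tau << 1 for every
  # transition, so the Lorentzian J(omega) ~ J(0)
  rx <- relaxation_inputs(
    hf = list(single_pair_models("zz:zz", 0.04, 5e-4, hf_keys), NULL),
    tau_omega_ns = 1)
  H <- build_hamiltonian(st$sys, st$ops, B = 1)
  R0 <- hyperfine_redfield(rx, st$ops)
  Re1 <- hyperfine_redfield(rx, st$ops, H, mode = "eigenbasis")
  expect_lt(max(Mod(Re1 - R0)), 1e-3 * max(Mod(R0)))
  # identity still stationary in eigenbasis mode
  d <- st$ops$dim
  expect_lt(max(Mod(Re1 %*% as.vector(diag(d) + 0i))), 1e-12)
})
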