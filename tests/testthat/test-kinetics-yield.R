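test_that("reaction superoperator has the Haberkorn structure", {
  sys <- spin_system(radical_iso(2.0, 0.3), radical_iso(2.0, 0.3),
                     kS = 0, kST = 0.05, B = 0)
  pr <- singlet_triplet_projectors(sys)
  K <- reaction_superoperator(sys, pr)
  expect_lt(max(Mod(K - 0.05 * diag(sys$dim^2))), 1e-14)

  sys2 <- spin_system(radical_iso(2.0, 0.3), radical_iso(2.0, 0.3),
                      kS = 0.2, kST = 0.05, B = 0)
  K2 <- reaction_superoperator(sys2, pr)
  rhoT <- pr$PT / Re(sum(diag(pr$PT)))
  rhoS <- pr$PS / Re(sum(diag(pr$PS)))
  tr_of <- function(K, rho) {
    d <- nrow(rho)
    Re(sum(diag(matrix(K %*% as.vector(rho), d))))
  }
  expect_equal(tr_of(K2, rhoT), 0.05, tolerance = 1e-12)
  expect_equal(tr_of(K2, rhoS), 0.25, tolerance = 1e-12)
  expect_error(spin_system(radical_iso(2), radical_iso(2), kS = -1, kST = 0.1),
               "kS")
})

test_that("Liouvillian assembly gives exponential decay and trace behavior", {
  sys <- spin_system(radical_iso(2.0), radical_iso(2.0), kS = 0, kST = 0.1,
                     B = 0)
  pr <- singlet_triplet_projectors(sys)
  K <- reaction_superoperator(sys, pr)
  L <- assemble_liouvillian(matrix(0i, 4, 4), K, list())
  rho0 <- initial_density(sys, pr, "f_pair")
  tr <- propagate_density(L, rho0, seq(0, 30, length.out = 16))
  traces <- vapply(tr$rhos, function(r) Re(sum(diag(r))), 0)
  expect_equal(traces, exp(-0.1 * tr$times), tolerance = 1e-9)

  # Hamiltonian-only propagation conserves trace over 100 ns
  sysh <- random_spec16(21)
  H <- build_hamiltonian(sysh)
  Lh <- 1i * spinmfe:::sop_commutator(H)
  prh <- singlet_triplet_projectors(sysh)
  rh <- propagate_density(Lh, initial_density(sysh, prh, "f_pair"),
                          seq(0, 100, length.out = 11))
  traces <- vapply(rh$rhos, function(r) Re(sum(diag(r))), 0)
  expect_lt(max(abs(traces - 1)), 1e-10)
  # eigenvalues of rho constant under unitary evolution
  ev0 <- sort(Re(eigen(rh$rhos[[1]])$values))
  evN <- sort(Re(eigen(rh$rhos[[11]])$values))
  expect_equal(evN, ev0, tolerance = 1e-9)

  expect_error(assemble_liouvillian(H, diag(10) + 0i, list()), "dimension")
})

test_that("relaxation channels leave the trace decay to the reaction part", {
  sys <- random_spec16(5)
  ops <- build_spin_operators(sys)
  pr <- singlet_triplet_projectors(sys)
  H <- build_hamiltonian(sys, ops)
  R <- hyperfine_redfield(random_relax(5), ops)
  rho0 <- initial_density(sys, pr)
  times <- seq(0, 10 / sys$kST, length.out = 9)
  # relaxation adds no trace drain: with kS = 0 the trace histories with and
  # without the channel must match exactly
  sys0 <- sys; sys0$kS <- 0
  K0 <- reaction_superoperator(sys0, pr)
  tr0_no <- propagate_density(assemble_liouvillian(H, K0, list()), rho0, times)
  tr0_R <- propagate_density(assemble_liouvillian(H, K0, list(R)), rho0, times)
  t0_no <- vapply(tr0_no$rhos, function(r) Re(sum(diag(r))), 0)
  t0_R <- vapply(tr0_R$rhos, function(r) Re(sum(diag(r))), 0)
  expect_equal(t0_R, t0_no, tolerance = 1e-9)
})

test_that("no-mixing closed-form yields are exact", {
  mk <- function(initial) {
    spin_system(radical_iso(2.0023), radical_iso(2.0023),
                kS = 0.2, kST = 0.01, B = 1, initial = initial)
  }
  for (init in c("triplet", "singlet", "f_pair")) {
    sys <- mk(init)
    pr <- singlet_triplet_projectors(sys)
    L <- assemble_liouvillian(build_hamiltonian(sys),
                              reaction_superoperator(sys, pr), list())
    y <- channel_yields(L, initial_density(sys, pr), sys, pr)
    if (init == "triplet") {
      expect_equal(y$phi_T, 1, tolerance = 1e-8)
    } else if (init == "singlet") {
      expect_equal(y$phi_recomb, 0.2 / 0.21, tolerance = 1e-8)
      expect_lt(abs(y$phi_T), 1e-8)
    } else {
      expect_equal(y$phi_T, 0.75, tolerance = 1e-8)
    }
    expect_equal(y$total, 1, tolerance = 1e-10)
  }
})

test_that("algebraic yields match time-domain propagation on random specs", {
  for (seed in 1:8) {
    sys <- random_spec16(seed)
    ops <- build_spin_operators(sys)
    pr <- singlet_triplet_projectors(sys)
    H <- build_hamiltonian(sys, ops)
    K <- reaction_superoperator(sys, pr)
    Rl <- if (seed %% 2 == 0)
      list(hyperfine_redfield(random_relax(seed), ops)) else list()
    L <- assemble_liouvillian(H, K, Rl)
    rho0 <- initial_density(sys, pr)
    ya <- channel_yields(L, rho0, sys, pr)
    yt <- yields_time_domain(L, rho0, sys, pr)
    expect_lt(abs(ya$phi_T - yt$phi_T), 1e-6)
    expect_lt(abs(ya$phi_recomb - yt$phi_recomb), 1e-6)
  }
})

test_that("yields conserve probability and stay in [0,1] across random specs", {
  for (seed in 31:38) {
    sys <- random_spec16(seed)
    ops <- build_spin_operators(sys)
    pr <- singlet_triplet_projectors(sys)
    Rl <- if (seed %% 2 == 0) {
      rx <- random_relax(seed)
      list(hyperfine_redfield(rx, ops),
           g_redfield(rx, sys$B, ops, sys$constants),
           spin_rotational_superoperator(
             spin_rotational_rate(rx$delta_g, rx$tau_omega_ns), ops))
    } else list()
    L <- assemble_liouvillian(build_hamiltonian(sys, ops),
                              reaction_superoperator(sys, pr), Rl)
    y <- channel_yields(L, initial_density(sys, pr), sys, pr)
    expect_equal(y$total, 1, tolerance = 1e-8)
    for (v in c(y$phi_T, y$phi_S_prop, y$phi_recomb)) {
      expect_gte(v, -1e-10); expect_lte(v, 1 + 1e-10)
    }
  }
})

test_that("zero-field yields are invariant under joint tensor rotation", {
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  rot_rad <- function(r) {
    nuc <- lapply(r$nuclei, function(n)
      nucleus_spec(n$label, n$I, Rz %*% n$A %*% t(Rz)))
    radical_spec(Rz %*% r$g %*% t(Rz), nuc)
  }
  sys <- random_spec16(77)
  sys$B <- c(0, 0, 0)
  sys_rot <- spin_system(rot_rad(sys$radicals[[1]]), rot_rad(sys$radicals[[2]]),
                         kS = sys$kS, kST = sys$kST, B = c(0, 0, 0),
                         initial = sys$initial)
  yield_of <- function(s) {
    pr <- singlet_triplet_projectors(s)
    L <- assemble_liouvillian(build_hamiltonian(s),
                              reaction_superoperator(s, pr), list())
    channel_yields(L, initial_density(s, pr), s, pr)$phi_T
  }
  expect_equal(yield_of(sys_rot), yield_of(sys), tolerance = 1e-9)
})

test_that("propagation preserves Hermiticity and flags bad grids", {
  sys <- random_spec16(9)
  pr <- singlet_triplet_projectors(sys)
  L <- assemble_liouvillian(build_hamiltonian(sys),
                            reaction_superoperator(sys, pr), list())
  tr <- propagate_density(L, initial_density(sys, pr),
                          seq(0, 5 / sys$kST, length.out = 21))
  herm <- vapply(tr$rhos, function(r) max(Mod(r - Conj(t(r)))), 0)
  expect_lt(max(herm), 1e-9)
  expect_error(propagate_density(L, initial_density(sys, pr), c(0, 1, 3)),
               "uniform")
})
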