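# Canonical key for a tensor-component correlation pair: tensor symmetry
# (xy == yx) plus exchange symmetry g(a,b) == g(b,a).
pair_key <- function(a, b, symmetric = TRUE) {
  canon <- function(s) {
    u <- substr(s, 1, 1); v <- substr(s, 2, 2)
    if (symmetric && u > v) paste0(v, u) else s
  }
  paste(sort(c(canon(a), canon(b))), collapse = ":")
}

model_lookup <- function(models, a, b, symmetric = TRUE, what = "covariance") {
  key <- pair_key(a, b, symmetric)
  m <- models[[key]]
  if (is.null(m))
    stop(sprintf("missing %s model for component pair (%s, %s) [key %s]",
                 what, a, b, key))
  m
}

#' Relaxation inputs
#'
#' Bundles everything the three relaxation channels need: per-radical
#' covariance models for the significant nucleus' hyperfine tensor components
#' and for the g-matrix components, the rotational correlation time of the
#' spin-bearing fragment, and the deviations of the g-matrix eigenvalues
#' from the free-electron value.
#'
#' Model lists are keyed by canonical pair keys such as `"xx:xy"`
#' (tensor-symmetric and exchange-symmetric, 21 distinct keys for a full
#' symmetric tensor; the g channel at a z-aligned field only needs the 6 keys
#' over \{zx, zy, zz\}).
#'
#' @param hf List of two model lists (one per radical) for hyperfine tensor
#'   components, prefactors in rad^2/ns^2. NULL entries allowed.
#' @param g List of two model lists for g-matrix components (dimensionless
#'   prefactors).
#' @param tau_omega_ns Rotational correlation time of the spin-bearing group
#'   (ns), > 0.
#' @param delta_g Length-3 numeric: deviations of the g-matrix eigenvalues
#'   from the free-electron g-factor.
#' @return Object of class `relaxation_inputs`.
#' @export
relaxation_inputs <- function(hf = list(NULL, NULL), g = list(NULL, NULL),
                              tau_omega_ns, delta_g = c(0, 0, 0)) {
  stopifnot(tau_omega_ns > 0, length(delta_g) == 3)
  for (side in list(hf, g)) for (ml in side) if (!is.null(ml))
    for (m in ml) {
      stopifnot(inherits(m, "cov_model"))
      p <- m$pair
      if (length(p) == 2 && p[1] == p[2] && m$prefactor < 0)
        stop("autocovariance prefactor must be non-negative")
    }
  structure(list(hf = hf, g = g, tau_omega_ns = tau_omega_ns,
                 delta_g = as.numeric(delta_g)),
            class = "relaxation_inputs")
}

component_labels <- function() {
  ax <- c("x", "y", "z")
  as.vector(t(outer(ax, ax, paste0)))  # xx xy xz yx ... zz
}

# Generic BRW superoperator over a set of fluctuation operators `Aops`
# (named list) with a J-lookup function jfun(a, b) -> scalar J(0), or in
# eigenbasis mode jfun(a, b, omega) evaluated at transition frequencies.
brw_superoperator <- function(Aops, jfun, H = NULL,
                              mode = c("zero_frequency", "eigenbasis")) {
  mode <- match.arg(mode)
  labs <- names(Aops)
  d <- nrow(Aops[[1]])
  R <- matrix(0i, d * d, d * d)
  if (mode == "zero_frequency") {
    Cs <- lapply(Aops, sop_commutator)
    for (a in labs) for (b in labs) {
      J <- jfun(a, b)
      if (J != 0) R <- R + J * (Cs[[a]] %*% Cs[[b]])
    }
  } else {
    if (is.null(H)) stop("eigenbasis mode requires the Hamiltonian")
    eg <- eigen(H, symmetric = TRUE)
    V <- eg$vectors
    Vh <- Conj(t(V))
    wmat <- outer(eg$values, eg$values, "-")   # omega_ab = E_a - E_b
    for (a in labs) {
      Ca <- sop_commutator(Aops[[a]])
      for (b in labs) {
        Ab <- Vh %*% Aops[[b]] %*% V
        Jm <- matrix(jfun(a, b, as.vector(wmat)), d, d)
        Lam <- V %*% (Jm * Ab) %*% Vh
        R <- R + Ca %*% (sop_left(Lam) - sop_right(Conj(t(Lam))))
      }
    }
  }
  R
}

#' Hyperfine-fluctuation relaxation superoperator
#'
#' BRW relaxation from fluctuations of the hyperfine tensor of the
#' significant nucleus on each radical. The fluctuation operator for tensor
#' component ab is A_ab = I_a S_b (from the I . A . S coupling); the channel
#' sums over all 81 ordered component pairs with spectral densities taken
#' from the covariance models (21 distinct by symmetry). In the default
#' zero-frequency (extreme-narrowing) mode,
#' R rho = sum_ab J_ab(0) [A_a, [A_b, rho]], entering the master equation as
#' d rho/dt = -R rho so that coherences decay and the identity is
#' stationary; the optional eigenbasis mode evaluates Lorentzian spectral
#' densities at the transition frequencies of the static Hamiltonian.
#'
#' Cross-radical fluctuation correlations are taken as zero, and only the
#' flagged significant nucleus of each radical relaxes (others contribute to
#' the static Hamiltonian only).
#'
#' @param inputs A [relaxation_inputs()].
#' @param ops Operators from [build_spin_operators()].
#' @param H Static Hamiltonian (needed for eigenbasis mode only).
#' @param mode "zero_frequency" (default) or "eigenbasis".
#' @param nucleus Index of the significant nucleus within each radical
#'   (default 1).
#' @return Complex superoperator matrix, attribute `channel = "relax_hf"`.
#' @export
hyperfine_redfield <- function(inputs, ops, H = NULL,
                               mode = c("zero_frequency", "eigenbasis"),
                               nucleus = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(inputs, "relaxation_inputs"))
  d <- ops$dim
  R <- matrix(0i, d * d, d * d)
  labs <- component_labels()
  for (i in 1:2) {
    models <- inputs$hf[[i]]
    if (is.null(models)) next
    if (length(ops$nuclei[[i]]) < nucleus)
      stop(sprintf("radical %d has no nucleus %d to relax", i, nucleus))
    In <- ops$nuclei[[i]][[nucleus]]
    S <- ops$electrons[[i]]
    Aops <- stats::setNames(lapply(labs, function(ab) {
      a <- substr(ab, 1, 1); b <- substr(ab, 2, 2)
      In[[a]] %*% S[[b]]
    }), labs)
    jfun <- function(a, b, omega = NULL) {
      m <- model_lookup(models, a, b, what = "hyperfine covariance")
      if (is.null(omega)) spectral_density_zero(m) else spectral_density(m, omega)
    }
    R <- R + brw_superoperator(Aops, jfun, H, mode)
  }
  attr(R, "channel") <- "relax_hf"
  R
}

#' g-tensor-fluctuation relaxation superoperator
#'
#' BRW relaxation from fluctuations of the g-matrix components coupling to a
#' field along z. The fluctuating part of the Zeeman interaction is
#' mu_B Bz/hbar sum_k Delta g_zk S_k per radical, so the fluctuation
#' operators are the electron spin components S_x, S_y, S_z weighted by the
#' statistics of Delta g_zx, Delta g_zy, Delta g_zz (6 distinct covariance
#' pairs per radical). The field factor (mu_B Bz / hbar)^2 is applied here,
#' so at fixed models the superoperator scales exactly as Bz^2.
#'
#' @param inputs A [relaxation_inputs()].
#' @param Bz Field z-component in mT. A nonzero Bx/By is not supported by
#'   this builder (the covariance bookkeeping is specific to z-aligned
#'   fields).
#' @param ops Operators from [build_spin_operators()].
#' @param constants [phys_constants()] supplying mu_B/hbar.
#' @param H,mode As in [hyperfine_redfield()].
#' @return Complex superoperator matrix, attribute `channel = "relax_g"`.
#' @export
g_redfield <- function(inputs, Bz, ops, constants = phys_constants(),
                       H = NULL, mode = c("zero_frequency", "eigenbasis")) {
  mode <- match.arg(mode)
  stopifnot(inherits(inputs, "relaxation_inputs"))
  if (length(Bz) == 3L) {
    if (any(Bz[1:2] != 0))
      stop("g_redfield handles z-aligned fields only; nonzero Bx/By needs a general builder (not provided)")
    Bz <- Bz[3]
  }
  d <- ops$dim
  R <- matrix(0i, d * d, d * d)
  fieldfac <- (constants$gamma_mT_ns * Bz)^2
  if (fieldfac == 0) {
    attr(R, "channel") <- "relax_g"
    return(R)
  }
  for (i in 1:2) {
    models <- inputs$g[[i]]
    if (is.null(models)) next
    S <- ops$electrons[[i]]
    Aops <- list(zx = S$x, zy = S$y, zz = S$z)
    jfun <- function(a, b, omega = NULL) {
      m <- model_lookup(models, paste0("z", substr(a, 2, 2)),
                        paste0("z", substr(b, 2, 2)),
                        what = "g covariance")
      if (is.null(omega)) fieldfac * spectral_density_zero(m)
      else fieldfac * spectral_density(m, omega)
    }
    R <- R + brw_superoperator(Aops, jfun, H, mode)
  }
  attr(R, "channel") <- "relax_g"
  R
}

#' Spin-rotational relaxation rate
#'
#' k_sr = (Delta g_xx^2 + Delta g_yy^2 + Delta g_zz^2) / (9 tau_Omega),
#' where the Delta g_nn are the deviations of the g-matrix eigenvalues from
#' the free-electron g-factor and tau_Omega is the rotational correlation
#' time of the spin-bearing group. Because that rotation is the fastest in
#' the system, this estimate is an upper bound on the spin-rotational rate.
#'
#' @param delta_g Length-3 numeric vector of eigenvalue deviations.
#' @param tau_omega_ns Rotational correlation time in ns, > 0.
#' @return Rate in 1/ns.
#' @export
spin_rotational_rate <- function(delta_g, tau_omega_ns) {
  stopifnot(length(delta_g) == 3)
  if (tau_omega_ns <= 0) stop("tau_omega must be positive")
  sum(delta_g^2) / (9 * tau_omega_ns)
}

#' Spin-rotational relaxation superoperator
#'
#' Isotropic electron-spin depolarization of both radicals:
#' R rho = k_sr (3/2 rho - sum_i sum_k S_ik rho S_ik), entering the master
#' equation as d rho/dt = -R rho. The identity is stationary (per electron
#' sum_k S_k S_k = 3/4) and the channel is trace-preserving.
#'
#' @param k_sr Rate in 1/ns, >= 0.
#' @param ops Operators from [build_spin_operators()].
#' @return Complex superoperator matrix, attribute `channel = "relax_sr"`.
#' @export
spin_rotational_superoperator <- function(k_sr, ops) {
  if (k_sr < 0) stop("spin-rotational rate must be non-negative")
  d <- ops$dim
  R <- matrix(0i, d * d, d * d)
  if (k_sr > 0) {
    R <- k_sr * 1.5 * diag(d * d)
    for (i in 1:2) for (k in c("x", "y", "z")) {
      S <- ops$electrons[[i]][[k]]
      R <- R - k_sr * sop_sandwich(S, S)
    }
  }
  attr(R, "channel") <- "relax_sr"
  R
}

#' Build the enabled relaxation channels
#'
#' @param sys A [spin_system()].
#' @param ops Operators from [build_spin_operators()].
#' @param inputs A [relaxation_inputs()].
#' @param channels Subset of c("hf", "g", "sr"); empty for the static case.
#' @param H Static Hamiltonian (eigenbasis mode only).
#' @param mode Spectral-density mode, see [hyperfine_redfield()].
#' @return Named list of superoperators (possibly empty).
#' @export
build_relaxation <- function(sys, ops, inputs, channels = c("hf", "g", "sr"),
                             H = NULL, mode = "zero_frequency") {
  if (length(channels) == 0) return(list())
  channels <- match.arg(channels, c("hf", "g", "sr"), several.ok = TRUE)
  out <- list()
  if ("hf" %in% channels)
    out$hf <- hyperfine_redfield(inputs, ops, H, mode)
  if ("g" %in% channels)
    out$g <- g_redfield(inputs, sys$B, ops, sys$constants, H, mode)
  if ("sr" %in% channels)
    out$sr <- spin_rotational_superoperator(
      spin_rotational_rate(inputs$delta_g, inputs$tau_omega_ns), ops)
  out
}
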