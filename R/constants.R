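#' Physical constants and internal unit system
#'
#' All spin Hamiltonian and relaxation quantities are handled internally as
#' angular frequencies in rad/ns; magnetic fields are given in mT and kinetic
#' rate constants in 1/ns. Conversions from SI happen only at I/O boundaries
#' (configuration files carry rates in 1/s).
#'
#' The default free-electron g-factor is 2.0013, the value used throughout
#' the spin-rotational estimate of this model family. Note that this differs
#' from the CODATA free-electron value (about 2.00232); the discrepancy is
#' deliberate and the constant can be overridden.
#'
#' @param bohr_magneton Bohr magneton in J/T.
#' @param hbar Reduced Planck constant in J s.
#' @param free_electron_g Dimensionless free-electron g-factor.
#' @return An object of class `phys_constants`: a list with the fields above
#'   plus `gamma_mT_ns`, the derived factor mu_B/hbar expressed in
#'   rad/(ns mT), i.e. the electron angular Larmor frequency per unit g and
#'   per mT of field.
#' @examples
#' pc <- phys_constants()
#' # Larmor angular frequency of a g = 2.0023 electron in 1 mT, rad/ns:
#' 2.0023 * pc$gamma_mT_ns
#' @export
phys_constants <- function(bohr_magneton = 9.2740100783e-24,
                           hbar = 1.054571817e-34,
                           free_electron_g = 2.0013) {
  stopifnot(is.numeric(bohr_magneton), bohr_magneton > 0,
            is.numeric(hbar), hbar > 0,
            is.numeric(free_electron_g), free_electron_g > 0)
  # rad/(s T) -> rad/(ns mT): 1e-9 (s->ns) * 1e-3 (T->mT)
  gamma <- bohr_magneton / hbar * 1e-12
  structure(
    list(bohr_magneton = bohr_magneton,
         hbar = hbar,
         free_electron_g = free_electron_g,
         gamma_mT_ns = gamma,
         units = c(energy = "rad/ns", field = "mT", rate = "1/ns")),
    class = "phys_constants")
}

#' @export
print.phys_constants <- function(x, ...) {
  cat("Physical constants (internal units: rad/ns, mT, 1/ns)\n")
  cat(sprintf("  mu_B            = %.10e J/T\n", x$bohr_magneton))
  cat(sprintf("  hbar            = %.9e J s\n", x$hbar))
  cat(sprintf("  g_e             = %.5f\n", x$free_electron_g))
  cat(sprintf("  mu_B/hbar       = %.8f rad/(ns mT)\n", x$gamma_mT_ns))
  invisible(x)
}

# Rate conversion helpers used at configuration I/O boundaries.
rate_per_s_to_per_ns <- function(k) k * 1e-9
rate_per_ns_to_per_s <- function(k) k * 1e9
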