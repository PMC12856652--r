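#' Nuclear spin specification
#'
#' @param label Character label for the nucleus (e.g. "H13X").
#' @param I Spin quantum number, a positive half-integer (1/2, 1, 3/2, ...).
#' @param A 3x3 hyperfine coupling tensor in rad/ns. Symmetrized on input as
#'   (A + t(A))/2, since the covariance bookkeeping downstream presumes
#'   permutation symmetry of tensor components.
#' @return Object of class `nucleus_spec`.
#' @export
nucleus_spec <- function(label, I, A) {
  stopifnot(is.character(label), length(label) == 1L)
  stopifnot(is.numeric(I), length(I) == 1L, I >= 0.5)
  if (abs(2 * I - round(2 * I)) > 1e-12)
    stop("spin quantum number I must be a half-integer")
  A <- as.matrix(A)
  if (!all(dim(A) == c(3L, 3L)) || !all(is.finite(A)))
    stop("hyperfine tensor A must be a finite 3x3 matrix (rad/ns)")
  A <- (A + t(A)) / 2
  structure(list(label = label, I = I, A = A), class = "nucleus_spec")
}

#' Radical specification
#'
#' @param g 3x3 dimensionless g-matrix.
#' @param nuclei List of [nucleus_spec()] objects (may be empty).
#' @param g_window Sanity window for g entries; entries outside it are
#'   rejected. Default c(1.5, 2.5) brackets organic radical g-values.
#' @return Object of class `radical_spec`.
#' @export
radical_spec <- function(g, nuclei = list(), g_window = c(1.5, 2.5)) {
  g <- as.matrix(g)
  if (!all(dim(g) == c(3L, 3L)) || !all(is.finite(g)))
    stop("g must be a finite 3x3 matrix")
  diag_ok <- all(diag(g) >= g_window[1] & diag(g) <= g_window[2])
  if (!diag_ok)
    stop(sprintf("diagonal g entries outside sanity window [%g, %g]",
                 g_window[1], g_window[2]))
  if (!is.list(nuclei) || !all(vapply(nuclei, inherits, TRUE, "nucleus_spec")))
    stop("nuclei must be a list of nucleus_spec objects")
  structure(list(g = g, nuclei = nuclei), class = "radical_spec")
}

#' Convenience: isotropic radical
#'
#' @param g_iso Isotropic g value.
#' @param a_iso Isotropic hyperfine constants (rad/ns), one per nucleus;
#'   each contributes a spin-1/2 nucleus with A = a_iso * I3.
#' @param labels Optional nucleus labels.
#' @return A `radical_spec`.
#' @export
radical_iso <- function(g_iso = 2.0023, a_iso = numeric(0), labels = NULL) {
  if (is.null(labels)) labels <- paste0("H", seq_along(a_iso))
  nuc <- Map(function(a, lb) nucleus_spec(lb, 0.5, diag(3) * a),
             a_iso, labels)
  radical_spec(diag(3) * g_iso, unname(nuc))
}

#' Two-radical spin system specification
#'
#' Describes the static radical pair: the two radicals (g-matrices and coupled
#' nuclei), the singlet-selective recombination rate `kS`, the spin-independent
#' escape/propagation rate `kST`, the applied magnetic field and the initial
#' electronic spin state.
#'
#' The Hilbert-space dimension is 4 x prod(2 I + 1) over all nuclei.
#'
#' @param radical1,radical2 [radical_spec()] objects.
#' @param kS Singlet recombination rate constant in 1/ns (default 0.2,
#'   i.e. 2e8 1/s).
#' @param kST Spin-independent propagation rate constant in 1/ns.
#' @param B Magnetic field vector in mT (length 3), or a single number taken
#'   as the z-component (field perpendicular to the membrane plane).
#' @param initial One of "triplet", "singlet", "f_pair". F-pairs are radical
#'   pairs formed by random encounters: 1/4 singlet, 3/4 triplet.
#' @param constants A [phys_constants()] object.
#' @return Object of class `spin_system`.
#' @examples
#' sys <- spin_system(radical_iso(a_iso = 0.3), radical_iso(a_iso = 0.3),
#'                    kST = 0.001, B = 1)
#' sys$dim  # 16 = 4 x 2 x 2
#' @export
spin_system <- function(radical1, radical2, kS = 0.2, kST,
                        B = c(0, 0, 0), initial = "triplet",
                        constants = phys_constants()) {
  stopifnot(inherits(radical1, "radical_spec"),
            inherits(radical2, "radical_spec"))
  if (!is.numeric(kS) || kS < 0) stop("kS must be >= 0 (1/ns)")
  if (!is.numeric(kST) || kST <= 0) stop("kST must be > 0 (1/ns)")
  if (length(B) == 1L) B <- c(0, 0, B)
  stopifnot(length(B) == 3L, all(is.finite(B)))
  initial <- match.arg(initial, c("triplet", "singlet", "f_pair"))
  spins <- c(vapply(radical1$nuclei, `[[`, 0, "I"),
             vapply(radical2$nuclei, `[[`, 0, "I"))
  dim <- as.integer(4 * prod(2 * spins + 1))
  if (dim < 4L) stop("invalid Hilbert dimension")
  structure(
    list(radicals = list(radical1, radical2),
         kS = kS, kST = kST, B = B, initial = initial,
         constants = constants, dim = dim),
    class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  n1 <- length(x$radicals[[1]]$nuclei); n2 <- length(x$radicals[[2]]$nuclei)
  cat(sprintf("Radical pair spin system, Hilbert dimension %d\n", x$dim))
  cat(sprintf("  nuclei: %d + %d | kS = %g /ns, kST = %g /ns\n",
              n1, n2, x$kS, x$kST))
  cat(sprintf("  B = (%g, %g, %g) mT | initial state: %s\n",
              x$B[1], x$B[2], x$B[3], x$initial))
  invisible(x)
}

#' Read / write a spin-system configuration file
#'
#' YAML layout: `radicals` is a list of two blocks, each with `g` (9 numbers,
#' row-major) and `nuclei` (list of `label`, `I`, `A` as 9 numbers row-major,
#' rad/ns); `kinetics` holds `kS_per_s` and `kST_per_s` (converted to 1/ns
#' internally); `field` holds `Bz_mT` (a number or list); `initial_state`.
#'
#' @param path File path.
#' @param kST_per_s Optional override of the propagation rate (1/s) when the
#'   file lists several or the scan supplies its own.
#' @return `read_spin_system()`: a `spin_system` (using the first Bz if the
#'   file lists several) plus attribute `Bz_list_mT`.
#' @export
read_spin_system <- function(path, kST_per_s = NULL) {
  cfg <- yaml::read_yaml(path)
  rad <- lapply(cfg$radicals, function(r) {
    nuc <- lapply(r$nuclei, function(n)
      nucleus_spec(n$label, n$I, matrix(as.numeric(n$A), 3, 3, byrow = TRUE)))
    radical_spec(matrix(as.numeric(r$g), 3, 3, byrow = TRUE), nuc)
  })
  if (length(rad) != 2L) stop("configuration must define exactly two radicals")
  kS <- rate_per_s_to_per_ns(as.numeric(cfg$kinetics$kS_per_s))
  if (is.null(kST_per_s)) kST_per_s <- as.numeric(cfg$kinetics$kST_per_s)[1]
  kST <- rate_per_s_to_per_ns(kST_per_s)
  Bz <- as.numeric(unlist(cfg$field$Bz_mT))
  ge <- if (!is.null(cfg$free_electron_g)) as.numeric(cfg$free_electron_g) else 2.0013
  sys <- spin_system(rad[[1]], rad[[2]], kS = kS, kST = kST,
                     B = c(0, 0, Bz[1]),
                     initial = if (is.null(cfg$initial_state)) "triplet"
                               else cfg$initial_state,
                     constants = phys_constants(free_electron_g = ge))
  attr(sys, "Bz_list_mT") <- Bz
  sys
}

#' @rdname read_spin_system
#' @param sys A `spin_system`.
#' @export
write_spin_system <- function(sys, path) {
  stopifnot(inherits(sys, "spin_system"))
  cfg <- list(
    radicals = lapply(sys$radicals, function(r) list(
      g = as.numeric(t(r$g)),
      nuclei = lapply(r$nuclei, function(n)
        list(label = n$label, I = n$I, A = as.numeric(t(n$A)))))),
    kinetics = list(kS_per_s = rate_per_ns_to_per_s(sys$kS),
                    kST_per_s = rate_per_ns_to_per_s(sys$kST)),
    field = list(Bz_mT = sys$B[3]),
    initial_state = sys$initial,
    free_electron_g = sys$constants$free_electron_g)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
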