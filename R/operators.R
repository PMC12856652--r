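#' @useDynLib spinmfe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd coef predict residuals approx optimize quantile
#' @importFrom utils read.table write.table head tail
NULL

# Angular-momentum matrices for spin quantum number I on (2I+1) dims.
# Standard |I, m> basis ordered m = I, I-1, ..., -I.
spin_matrices <- function(I) {
  n <- as.integer(round(2 * I + 1))
  m <- seq(I, -I, by = -1)
  jz <- diag(m, n, n)
  # <I, m+1 | J+ | I, m> = sqrt(I(I+1) - m(m+1))
  jp <- matrix(0, n, n)
  if (n > 1) {
    off <- sqrt(I * (I + 1) - m[-1] * (m[-1] + 1))
    jp[cbind(seq_len(n - 1), 2:n)] <- off
  }
  jm <- t(jp)
  list(x = (jp + jm) / 2 + 0i,
       y = (jp - jm) / (2i),
       z = jz + 0i)
}

# Embed operator `op` at position `pos` in a tensor product with the given
# factor dimensions. Factor ordering is fixed globally as
# (electron 1, electron 2, nuclei of radical 1, nuclei of radical 2);
# kron() associates left-to-right, so matrices are bit-reproducible.
embed_operator <- function(op, pos, dims) {
  out <- matrix(1 + 0i, 1, 1)
  for (k in seq_along(dims)) {
    f <- if (k == pos) op else diag(dims[k]) + 0i
    out <- kronecker(out, f)
  }
  out
}

factor_dims <- function(sys) {
  spins <- c(vapply(sys$radicals[[1]]$nuclei, `[[`, 0, "I"),
             vapply(sys$radicals[[2]]$nuclei, `[[`, 0, "I"))
  c(2L, 2L, as.integer(round(2 * spins + 1)))
}

#' Build spin-component operators on the full Hilbert space
#'
#' Constructs x/y/z spin operators for both electrons and every nucleus,
#' embedded into the full Hilbert space (Kronecker products with identity
#' padding). Factor ordering is (electron 1, electron 2, nuclei of radical 1
#' in list order, nuclei of radical 2 in list order); this ordering is fixed
#' so operator matrices are reproducible across runs.
#'
#' @param sys A [spin_system()].
#' @param max_dim Guard against accidental huge spaces; constructing systems
#'   above this total Hilbert dimension is an error. Default 4096.
#' @return List with `dim`, `electrons` (list of two lists with x/y/z complex
#'   matrices) and `nuclei` (list of two lists, one per radical, each entry a
#'   list with x/y/z and the `label`/`I` of the nucleus).
#' @export
build_spin_operators <- function(sys, max_dim = 4096) {
  stopifnot(inherits(sys, "spin_system"))
  dims <- factor_dims(sys)
  d <- prod(dims)
  if (d > max_dim)
    stop(sprintf("Hilbert dimension %d exceeds cap %d", d, max_dim))
  el <- lapply(1:2, function(i) {
    sm <- spin_matrices(0.5)
    lapply(sm, embed_operator, pos = i, dims = dims)
  })
  n1 <- length(sys$radicals[[1]]$nuclei)
  nuc <- lapply(1:2, function(i) {
    nn <- sys$radicals[[i]]$nuclei
    offset <- 2L + if (i == 2L) n1 else 0L
    lapply(seq_along(nn), function(j) {
      sm <- spin_matrices(nn[[j]]$I)
      ops <- lapply(sm, embed_operator, pos = offset + j, dims = dims)
      c(ops, list(label = nn[[j]]$label, I = nn[[j]]$I))
    })
  })
  list(dim = d, electrons = el, nuclei = nuc)
}

#' Singlet and triplet projection operators
#'
#' The electronic singlet projector is built from
#' |S> = (|ud> - |du>)/sqrt(2) in the Zeeman product basis of the two
#' electrons (this choice pins all sign conventions), the triplet projector
#' as its complement; both are tensored with the nuclear identity, so their
#' traces are Z and 3Z for nuclear dimension Z.
#'
#' @param sys A [spin_system()].
#' @return List with complex matrices `PS` and `PT` (PS + PT = identity) and
#'   the nuclear dimension `Z`.
#' @export
singlet_triplet_projectors <- function(sys) {
  dims <- factor_dims(sys)
  # Electron product basis |m1 m2> ordered (uu, ud, du, dd) by the kron
  # convention (factor 1 slowest).
  s <- c(0, 1, -1, 0) / sqrt(2)
  PSel <- outer(s, s) + 0i
  Z <- prod(dims[-(1:2)])
  Inuc <- diag(Z) + 0i
  PS <- kronecker(PSel, Inuc)
  PT <- kronecker(diag(4) - PSel, Inuc)
  list(PS = PS, PT = PT, Z = Z)
}

#' Static spin Hamiltonian (Zeeman + hyperfine), rad/ns
#'
#' H = sum_i mu_B/hbar B . g_i . S_i + sum_i sum_n I_{i,n} . A_{i,n} . S_i,
#' with B in mT, g the full 3x3 matrices, A in rad/ns. For B = (0,0,Bz) the
#' Zeeman part reduces to mu_B Bz/hbar (g_zx Sx + g_zy Sy + g_zz Sz) per
#' radical.
#'
#' @param sys A [spin_system()].
#' @param ops Operator set from [build_spin_operators()]; rebuilt if NULL.
#' @param B Optional field override (mT, scalar = z-component).
#' @return Hermitian complex matrix in rad/ns.
#' @export
build_hamiltonian <- function(sys, ops = NULL, B = NULL) {
  if (is.null(ops)) ops <- build_spin_operators(sys)
  if (is.null(B)) B <- sys$B
  if (length(B) == 1L) B <- c(0, 0, B)
  gamma <- sys$constants$gamma_mT_ns
  d <- ops$dim
  H <- matrix(0i, d, d)
  for (i in 1:2) {
    g <- sys$radicals[[i]]$g
    if (!all(is.finite(g))) stop("non-finite g tensor")
    # B . g -> row vector of weights on (Sx, Sy, Sz)
    w <- as.numeric(B %*% g) * gamma
    S <- ops$electrons[[i]]
    H <- H + w[1] * S$x + w[2] * S$y + w[3] * S$z
    for (j in seq_along(ops$nuclei[[i]])) {
      A <- sys$radicals[[i]]$nuclei[[j]]$A
      if (!all(is.finite(A))) stop("non-finite hyperfine tensor")
      In <- ops$nuclei[[i]][[j]]
      for (a in 1:3) for (b in 1:3) {
        if (A[a, b] != 0)
          H <- H + A[a, b] * (In[[a]] %*% S[[b]])
      }
    }
  }
  (H + Conj(t(H))) / 2
}

#' Initial density operator
#'
#' Triplet-born pairs start in the normalized triplet projector, singlet-born
#' in the normalized singlet projector, and F-pairs (random encounters of
#' independently generated radicals) in the maximally mixed state, which
#' carries singlet and triplet probabilities of 1/4 and 3/4.
#'
#' @param sys A [spin_system()].
#' @param proj Projector set from [singlet_triplet_projectors()]; rebuilt if
#'   NULL.
#' @param mode Override of `sys$initial`.
#' @return Hermitian positive semidefinite complex matrix with unit trace.
#' @export
initial_density <- function(sys, proj = NULL, mode = NULL) {
  if (is.null(proj)) proj <- singlet_triplet_projectors(sys)
  if (is.null(mode)) mode <- sys$initial
  d <- nrow(proj$PS)
  switch(mode,
         triplet = proj$PT / Re(sum(diag(proj$PT))),
         singlet = proj$PS / Re(sum(diag(proj$PS))),
         f_pair = diag(d) / d + 0i,
         stop(sprintf("unknown initial-state mode '%s'", mode)))
}

# Real trace of (possibly complex) matrix product trace(A %*% B), cheaply.
tr_prod <- function(A, B) Re(sum(A * t(B)))
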