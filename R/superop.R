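# Liouville-space helpers. Vectorization is column stacking:
# vec(A X B) = (t(B) %x% A) vec(X). All superoperators are complex
# d^2 x d^2 matrices acting on vec'd density operators.

vec_op <- function(M) as.vector(M)
unvec_op <- function(v, d = as.integer(sqrt(length(v)))) matrix(v, d, d)

# Superoperator for X -> A X
sop_left <- function(A) {
  d <- nrow(A)
  kronecker(diag(d) + 0i, A)
}

# Superoperator for X -> X B
sop_right <- function(B) {
  d <- nrow(B)
  kronecker(t(B), diag(d) + 0i)
}

# Superoperator for X -> [A, X]
sop_commutator <- function(A) sop_left(A) - sop_right(A)

# Superoperator for X -> {A, X}/2
sop_anticomm_half <- function(A) (sop_left(A) + sop_right(A)) / 2

# Superoperator for X -> A X B
sop_sandwich <- function(A, B) kronecker(t(B), A)
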