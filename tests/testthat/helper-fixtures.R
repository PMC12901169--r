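# Shared fixture generators, all seeded and built in code.

random_complex_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  })
}

random_hermitian <- function(n, seed) {
  A <- random_complex_matrix(n, seed)
  (A + Conj(t(A))) / 2
}

random_hermitian_psd <- function(n, seed, rank = n) {
  withr::with_seed(seed, {
    V <- matrix(complex(real = rnorm(rank * n), imaginary = rnorm(rank * n)),
                rank, n)
    (Conj(t(V)) %*% V + t(Conj(Conj(t(V)) %*% V))) / 2
  })
}

random_unitary <- function(n, seed) {
  qr.Q(qr(random_complex_matrix(n, seed)))
}

# a random strictly passive S-matrix with spectral scale `strength`
random_passive_smatrix <- function(n, seed, strength = 0.6) {
  A <- random_complex_matrix(n, seed)
  A <- (A + t(A)) / 2
  lam <- max(eigen(Conj(t(A)) %*% A, symmetric = TRUE,
                   only.values = TRUE)$values)
  smatrix(A * sqrt(strength / lam))
}

quad <- function(Q, x) Re(sum(Conj(x) * (Q %*% x)))
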