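# Internal numerics shared across modules.

#' Numerical tolerances used by ptxsar
#'
#' All validation tolerances are package-level configuration, read through
#' [base::options()] so a session can tighten or relax them globally.
#'
#' @param name One of `"passivity"` (slack on the largest eigenvalue of
#'   \eqn{S^H S} above 1 before a passivity warning; default `1e-6`),
#'   `"hermitian"` (relative asymmetry tolerated before a matrix is rejected
#'   as non-Hermitian; default `1e-9`), `"psd"` (relative negative-eigenvalue
#'   tolerance for positive semidefiniteness; default `1e-10`), or
#'   `"solver"` (target relative duality gap of the worst-case solver;
#'   default `1e-8`).
#' @return The tolerance, a positive scalar.
#' @examples
#' ptxsar_tol("passivity")
#' @export
ptxsar_tol <- function(name = c("passivity", "hermitian", "psd", "solver")) {
  name <- match.arg(name)
  default <- c(passivity = 1e-6, hermitian = 1e-9, psd = 1e-10, solver = 1e-8)
  getOption(paste0("ptxsar.tol_", name), unname(default[name]))
}

# largest |entry|, 0 for empty
max_abs <- function(M) if (length(M) == 0) 0 else max(abs(M))

is_square_matrix <- function(M) {
  is.matrix(M) && nrow(M) == ncol(M) && nrow(M) >= 1L
}

check_square_finite <- function(M, what = "matrix") {
  if (!is_square_matrix(M)) {
    abort(sprintf("`%s` must be a square matrix with at least one row.", what),
          class = "ptxsar_bad_input")
  }
  if (!all(is.finite(Re(M))) || !all(is.finite(Im(M)))) {
    abort(sprintf("`%s` contains non-finite entries.", what),
          class = "ptxsar_bad_input")
  }
  invisible(M)
}

# relative deviation from Hermitian symmetry
hermitian_asymmetry <- function(Q) {
  s <- max_abs(Q)
  if (s == 0) return(0)
  max_abs(Q - Conj(t(Q))) / s
}

is_hermitian <- function(Q, tol = ptxsar_tol("hermitian")) {
  hermitian_asymmetry(Q) <= tol
}

hermitianize <- function(Q) (Q + Conj(t(Q))) / 2

# x^H Q x as a real scalar (Q Hermitian)
quad_form <- function(Q, x) {
  Re(sum(Conj(x) * (Q %*% x)))
}

# eigenvalues of a Hermitian matrix, descending
hermitian_eigenvalues <- function(Q) {
  eigen(Q, symmetric = TRUE, only.values = TRUE)$values
}

# largest eigenvalue of S^H S
max_shs_eigenvalue <- function(S) {
  if (length(S) == 0) return(0)
  max(hermitian_eigenvalues(Conj(t(S)) %*% S))
}

spectral_norm_hermitian <- function(Q) max(abs(hermitian_eigenvalues(Q)))

# complex standard-normal matrix, row-major so that the first rows of a
# larger draw coincide with a smaller draw from the same seed state
rcnorm_rows <- function(n, p) {
  raw <- matrix(rnorm(2 * n * p), nrow = n, byrow = TRUE)
  raw[, seq_len(p), drop = FALSE] + 1i * raw[, p + seq_len(p), drop = FALSE]
}

as_complex_matrix <- function(M) {
  storage.mode(M) <- "complex"
  M
}
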