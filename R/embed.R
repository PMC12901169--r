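#' Real embedding of a Hermitian quadratic form
#'
#' Maps a complex Hermitian \eqn{N \times N} matrix \eqn{Q} to the real
#' symmetric \eqn{2N \times 2N} block matrix
#' \deqn{Q_{\mathbb{R}} = \begin{pmatrix} \Re Q & -\Im Q \\ \Im Q & \Re Q
#' \end{pmatrix}}
#' so that for every complex vector \eqn{x} with real stacking
#' \eqn{z = (\Re x; \Im x)}, \eqn{z^T Q_{\mathbb{R}} z = x^H Q x}.  This is
#' the standard reformulation turning the complex worst-case problem into a
#' real quadratically-constrained program; eigenvalues are preserved (with
#' doubled multiplicity).
#'
#' @param Q Complex Hermitian matrix (checked against
#'   `ptxsar_tol("hermitian")`).
#' @return Real symmetric matrix of dimension `2 * nrow(Q)`.
#' @examples
#' real_embed(matrix(c(1, 1i, -1i, 2), 2))
#' @export
real_embed <- function(Q) {
  Q <- as_complex_matrix(as.matrix(Q))
  check_square_finite(Q, "Q")
  if (!is_hermitian(Q)) {
    abort("`Q` must be Hermitian to admit a symmetric real embedding.",
          class = "ptxsar_not_hermitian")
  }
  Q <- hermitianize(Q)
  R <- Re(Q); I <- Im(Q)
  out <- rbind(cbind(R, -I), cbind(I, R))
  (out + t(out)) / 2
}

# inverse of the stacking: real 2N-vector -> complex N-vector
unembed_vector <- function(z) {
  n <- length(z) / 2L
  z[seq_len(n)] + 1i * z[n + seq_len(n)]
}
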