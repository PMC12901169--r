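#' Virtual observation point (VOP) set
#'
#' An ordered collection of \eqn{N \times N} Hermitian positive-semidefinite
#' SAR matrices.  For an excitation vector \eqn{x}, the local SAR supervised
#' by VOP \eqn{j} is the quadratic form \eqn{x^H Q_j x} (W/kg per unit
#' squared excitation amplitude); the maximum over the set upper-bounds local
#' SAR anywhere in the body.
#'
#' Matrices whose Hermitian asymmetry is below `ptxsar_tol("hermitian")`
#' (relative to the largest absolute entry) are symmetrized as
#' \eqn{(Q + Q^H)/2} on construction — file round-trips introduce harmless
#' asymmetry — and rejected above that tolerance.  Positive semidefiniteness
#' is enforced up to `ptxsar_tol("psd")` relative to the largest eigenvalue.
#'
#' @param matrices List of complex square matrices, all the same size.
#' @param labels Optional character vector of per-matrix labels.
#' @return An object of class `"vop_set"`: list with `matrices` (symmetrized),
#'   `n_channels`, `n_vops`, `labels`.
#' @examples
#' vops <- vop_set(list(diag(2) + 0i, matrix(c(1, 1i, -1i, 2), 2)))
#' vops$n_vops
#' @seealso [evaluate_sar()], [transform_vops()], [synth_vops()]
#' @export
vop_set <- function(matrices, labels = NULL) {
  if (!is.list(matrices) || length(matrices) == 0) {
    abort("`matrices` must be a non-empty list of square matrices.",
          class = "ptxsar_bad_input")
  }
  n <- nrow(as.matrix(matrices[[1]]))
  herm_tol <- ptxsar_tol("hermitian")
  psd_tol <- ptxsar_tol("psd")
  mats <- vector("list", length(matrices))
  for (j in seq_along(matrices)) {
    Q <- as_complex_matrix(as.matrix(matrices[[j]]))
    check_square_finite(Q, sprintf("matrices[[%d]]", j))
    if (nrow(Q) != n) {
      abort(sprintf("VOP %d is %d x %d but VOP 1 is %d x %d.",
                    j, nrow(Q), ncol(Q), n, n),
            class = "ptxsar_bad_input")
    }
    if (hermitian_asymmetry(Q) > herm_tol) {
      abort(sprintf("VOP %d is not Hermitian (relative asymmetry %.3g > %.3g).",
                    j, hermitian_asymmetry(Q), herm_tol),
            class = "ptxsar_not_hermitian")
    }
    Q <- hermitianize(Q)
    ev <- hermitian_eigenvalues(Q)
    if (min(ev) < -psd_tol * max(max(ev), 0)) {
      abort(sprintf(
        "VOP %d is not positive semidefinite (min eigenvalue %.3g, max %.3g).",
        j, min(ev), max(ev)),
        class = "ptxsar_not_psd")
    }
    mats[[j]] <- Q
  }
  if (!is.null(labels)) stopifnot(length(labels) == length(mats))
  structure(list(matrices = mats,
                 n_channels = n,
                 n_vops = length(mats),
                 labels = labels),
            class = "vop_set")
}

#' @export
print.vop_set <- function(x, ...) {
  cat(sprintf("<vop_set> %d VOPs on %d channels; max spectral norm %.4g\n",
              x$n_vops, x$n_channels,
              max(vapply(x$matrices, spectral_norm_hermitian, numeric(1)))))
  invisible(x)
}

as_vop_set <- function(v, arg = "vops") {
  if (inherits(v, "vop_set")) return(v)
  if (is.list(v)) return(vop_set(v))
  abort(sprintf("`%s` must be a vop_set or a list of Hermitian matrices.", arg),
        class = "ptxsar_bad_input")
}

#' Evaluate per-VOP SAR for an excitation vector
#'
#' Returns the quadratic form \eqn{x^H Q_j x} for every VOP in the set: the
#' local SAR each virtual observation point reports for the complex
#' excitation vector `x`.  SAR is invariant under a global phase of `x` and
#' scales with \eqn{|c|^2} when `x` is scaled by `c`.
#'
#' @param vops A [vop_set()].
#' @param x Complex vector of per-channel excitation amplitudes/phases,
#'   length `vops$n_channels`.
#' @return Real numeric vector, one SAR value per VOP (named by labels if
#'   present).
#' @examples
#' vops <- vop_set(list(diag(2) + 0i))
#' evaluate_sar(vops, c(1, 1))  # 2
#' @export
evaluate_sar <- function(vops, x) {
  vops <- as_vop_set(vops)
  x <- as.complex(x)
  if (length(x) != vops$n_channels) {
    abort(sprintf("`x` has length %d but the VOP set has %d channels.",
                  length(x), vops$n_channels),
          class = "ptxsar_bad_input")
  }
  out <- vapply(vops$matrices, quad_form, numeric(1), x = x)
  if (!is.null(vops$labels)) names(out) <- vops$labels
  out
}
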