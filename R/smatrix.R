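#' Scattering matrix of a multi-channel transmit array
#'
#' Wraps a complex \eqn{N \times N} S-parameter matrix (voltage-wave ratios,
#' 50 Ohm reference) describing reflection and inter-element coupling of an
#' RF transmit array at the coupler reference plane.  Channel ordering is the
#' input order; no reordering is attempted.  Reciprocity (symmetry of S) is
#' deliberately not enforced because measured S-parameters may violate it
#' slightly.
#'
#' Passivity — the largest eigenvalue of \eqn{S^H S} not exceeding 1 — is
#' checked at construction: a violation beyond `ptxsar_tol("passivity")`
#' raises a warning, not an error, since measured data can be marginally
#' non-passive.
#'
#' @param values Complex (or numeric) square matrix of S-parameters.
#' @param frequency_hz Optional positive scalar, the frequency the matrix was
#'   taken at (metadata only).
#' @param label Optional character label for reports.
#' @return An object of class `"smatrix"` with fields `values`, `n_channels`,
#'   `frequency_hz`, `label`.
#' @examples
#' S <- smatrix(diag(0.1 + 0i, 2), label = "toy")
#' S$n_channels
#' @seealso [validate_smatrix()], [reflected_power_spectrum()]
#' @export
smatrix <- function(values, frequency_hz = NULL, label = NULL) {
  check_square_finite(values, "values")
  values <- as_complex_matrix(as.matrix(values))
  if (!is.null(frequency_hz)) {
    stopifnot(is.numeric(frequency_hz), length(frequency_hz) == 1L,
              is.finite(frequency_hz), frequency_hz > 0)
  }
  obj <- structure(
    list(values = values,
         n_channels = nrow(values),
         frequency_hz = frequency_hz,
         label = label),
    class = "smatrix")
  lam <- max_shs_eigenvalue(values)
  if (lam > 1 + ptxsar_tol("passivity")) {
    warn(sprintf(
      "S-matrix%s is non-passive: max eigenvalue of S^H S = %.6g > 1.",
      if (is.null(label)) "" else paste0(" '", label, "'"), lam),
      class = "ptxsar_nonpassive")
  }
  obj
}

#' @export
print.smatrix <- function(x, ...) {
  cat(sprintf("<smatrix> %d channels%s%s\n", x$n_channels,
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              if (is.null(x$frequency_hz)) "" else
                sprintf(" @ %.6g MHz", x$frequency_hz / 1e6)))
  cat(sprintf("  max |S_ij| = %.4g, max eig(S^H S) = %.4g\n",
              max_abs(x$values), max_shs_eigenvalue(x$values)))
  invisible(x)
}

as_smatrix <- function(S, arg = "S") {
  if (inherits(S, "smatrix")) return(S)
  if (is.matrix(S)) return(suppressWarnings(smatrix(S)))
  abort(sprintf("`%s` must be an smatrix or a square complex matrix.", arg),
        class = "ptxsar_bad_input")
}

#' Validate an S-matrix
#'
#' Runs the structural and physical checks on an S-matrix and reports them
#' without modifying the object.  The passivity check flags `"warn"` (not
#' `"fail"`) when the largest eigenvalue of \eqn{S^H S} exceeds
#' \eqn{1 + } `ptxsar_tol("passivity")`, because slightly non-passive
#' measured data is still usable.
#'
#' @param S An [smatrix()] (or bare square complex matrix).
#' @return A tibble with one row per check: `check`, `status` (`"pass"`,
#'   `"warn"` or `"fail"`), `value` (the measured quantity) and `detail`.
#' @examples
#' validate_smatrix(smatrix(matrix(0 + 0i, 2, 2)))
#' @export
validate_smatrix <- function(S) {
  S <- as_smatrix(S)
  M <- S$values
  lam_max <- max_shs_eigenvalue(M)
  tol <- ptxsar_tol("passivity")
  tibble(
    check = c("square", "finite", "passivity", "max_abs_entry"),
    status = c(
      "pass",
      if (all(is.finite(Re(M))) && all(is.finite(Im(M)))) "pass" else "fail",
      if (lam_max <= 1 + tol) "pass" else "warn",
      "pass"),
    value = c(S$n_channels,
              sum(!is.finite(Re(M)) | !is.finite(Im(M))),
              lam_max,
              max_abs(M)),
    detail = c(
      sprintf("%d x %d", S$n_channels, S$n_channels),
      "non-finite entry count",
      sprintf("max eigenvalue of S^H S (tolerance 1 + %.1g)", tol),
      "largest |S_ij|"))
}

#' Reflected-power spectrum of an array
#'
#' Computes the eigenvalues of \eqn{S^H S}, sorted descending.  Each
#' eigenvalue is the fraction of total forward power reflected by the array
#' for the corresponding orthogonal excitation mode; the first entry is the
#' worst-case total reflected power fraction and is a standard quality
#' measure for the coupling of an array.
#'
#' @param S An [smatrix()] (or square complex matrix).
#' @return An object of class `"passivity_spectrum"`: list with
#'   `eigenvalues` (real, descending), `n_channels`, `label`.
#' @examples
#' reflected_power_spectrum(smatrix(diag(c(0.6, 0.3)) + 0i))$eigenvalues
#' @export
reflected_power_spectrum <- function(S) {
  S <- as_smatrix(S)
  ev <- sort(pmax(hermitian_eigenvalues(Conj(t(S$values)) %*% S$values), 0),
             decreasing = TRUE)
  structure(list(eigenvalues = ev,
                 n_channels = S$n_channels,
                 label = S$label),
            class = "passivity_spectrum")
}

#' @export
print.passivity_spectrum <- function(x, ...) {
  cat(sprintf("<passivity_spectrum> %d modes%s; worst-case reflected power %.3g\n",
              x$n_channels,
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$eigenvalues[1]))
  invisible(x)
}

#' @rdname reflected_power_spectrum
#' @param x A `passivity_spectrum`.
#' @param ... Unused.
#' @method tidy passivity_spectrum
#' @export
tidy.passivity_spectrum <- function(x, ...) {
  tibble(mode = seq_along(x$eigenvalues),
         reflected_power_fraction = x$eigenvalues,
         label = x$label %||% NA_character_)
}
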