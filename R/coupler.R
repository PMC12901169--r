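#' Directional coupler measurement model
#'
#' Parameters of the forward-signal measurement chain of a multi-channel
#' transmit system.  A directional coupler with finite directivity \eqn{D}
#' leaks the reflected wave into the forward measurement:
#' \eqn{a_{meas} = a_{act} + b / D}.  The reference-plane offset between the
#' S-parameter measurement and the coupler introduces a common phase
#' \eqn{\phi} and a cable attenuation factor \eqn{1/\mu} on the reflected
#' signal.
#'
#' A single global phase is used for all channels (cable lengths are near
#' identical in practice).  `attenuation_linear` defaults to 1 — coupler at
#' the S-parameter reference plane; cable attenuation is usually negligible
#' against the directivity — but is kept explicit because moving the coupler
#' towards the amplifier is equivalent to scaling the S-matrix by the square
#' of the attenuation.
#'
#' @param directivity_db Directivity in dB (voltage-ratio convention, see
#'   [linear_directivity()]).  Either a positive scalar applied to all
#'   channels or a vector with one value per channel (real hardware varies;
#'   the scalar is the common case).
#' @param phase_rad Reference-plane phase offset \eqn{\phi} in radians.
#' @param attenuation_linear Linear voltage attenuation factor \eqn{\mu \ge 1}
#'   of the cable between the two reference planes.
#' @return An object of class `"coupler_model"`.
#' @examples
#' coupler_model(25, phase_rad = pi)
#' @export
coupler_model <- function(directivity_db, phase_rad = 0, attenuation_linear = 1) {
  stopifnot(is.numeric(directivity_db), length(directivity_db) >= 1L,
            all(is.finite(directivity_db)), all(directivity_db > 0),
            is.numeric(phase_rad), length(phase_rad) == 1L, is.finite(phase_rad),
            is.numeric(attenuation_linear), length(attenuation_linear) == 1L,
            is.finite(attenuation_linear), attenuation_linear >= 1)
  structure(list(directivity_db = as.numeric(directivity_db),
                 phase_rad = as.numeric(phase_rad),
                 attenuation_linear = as.numeric(attenuation_linear)),
            class = "coupler_model")
}

#' @export
print.coupler_model <- function(x, ...) {
  cat(sprintf("<coupler_model> directivity %s dB, phase %.4g rad, attenuation %.4g\n",
              paste(format(x$directivity_db), collapse = "/"),
              x$phase_rad, x$attenuation_linear))
  invisible(x)
}

#' Convert a directivity in dB to a linear voltage ratio
#'
#' Directivity acts on the complex voltage-wave signals measured by the
#' coupler, so the dB value converts as \eqn{D = 10^{dB/20}} (voltage
#' convention).  A power convention (`10^(dB/10)`) would halve the effect of
#' the leaked reflected wave on the measured phasor.
#'
#' @param directivity_db Finite numeric vector of directivities in dB.
#' @return Linear voltage ratio(s) \eqn{10^{dB/20}}.
#' @examples
#' linear_directivity(c(0, 20, 25))  # 1, 10, 17.78
#' @export
linear_directivity <- function(directivity_db) {
  stopifnot(is.numeric(directivity_db), all(is.finite(directivity_db)))
  10^(directivity_db / 20)
}

#' Measurement error matrix
#'
#' The linear map from the actual to the measured excitation vector,
#' \deqn{M = \frac{1}{\mu} e^{i\phi} D^{-1} S + I,}
#' where \eqn{D^{-1}} is the inverse linear directivity (a diagonal matrix
#' when per-channel directivities are given), \eqn{\phi} the reference-plane
#' phase offset and \eqn{1/\mu} the cable attenuation.  For an ideally
#' matched and decoupled array (\eqn{S = 0}) or an ideal coupler
#' (\eqn{D \to \infty}) the error matrix is the identity.
#'
#' @param S An [smatrix()].
#' @param coupler A [coupler_model()].
#' @return An object of class `"error_matrix"`: list with `values`
#'   (complex \eqn{N \times N}) and `n_channels`.
#' @examples
#' S <- smatrix(matrix(0.5 + 0i, 1, 1))
#' build_error_matrix(S, coupler_model(20, phase_rad = pi))$values  # 0.95
#' @seealso [custom_error_matrix()], [transform_vops()]
#' @export
build_error_matrix <- function(S, coupler) {
  S <- as_smatrix(S)
  stopifnot(inherits(coupler, "coupler_model"))
  n <- S$n_channels
  d_lin <- linear_directivity(coupler$directivity_db)
  if (length(d_lin) == 1L) {
    inv_d <- 1 / d_lin
    leak <- inv_d * S$values
  } else {
    if (length(d_lin) != n) {
      abort(sprintf(
        "Per-channel directivity has length %d but the array has %d channels.",
        length(d_lin), n), class = "ptxsar_bad_input")
    }
    leak <- diag(1 / d_lin, n) %*% S$values
  }
  M <- (1 / coupler$attenuation_linear) * exp(1i * coupler$phase_rad) * leak +
    diag(1 + 0i, n)
  structure(list(values = M, n_channels = n), class = "error_matrix")
}

#' Wrap an arbitrary measurement error matrix
#'
#' The worst-case machinery applies to any linear measurement model, not
#' only directional couplers.  For example, sniffer coils monitoring the
#' current on each transmit element give an error matrix that is the
#' identity plus complex inter-channel correlation factors on the
#' off-diagonals.  This wraps a user matrix verbatim so the full pipeline
#' runs on such models.
#'
#' A singular matrix is accepted here; the worst-case solver then flags the
#' problem as unbounded when a drive with positive actual SAR but zero
#' measured SAR exists.
#'
#' @param values Square complex matrix with finite entries.
#' @return An `"error_matrix"`.
#' @examples
#' custom_error_matrix(diag(2) + 0i)
#' @export
custom_error_matrix <- function(values) {
  check_square_finite(values, "values")
  structure(list(values = as_complex_matrix(as.matrix(values)),
                 n_channels = nrow(values)),
            class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat(sprintf("<error_matrix> %d channels, ||M - I||_max = %.4g\n",
              x$n_channels, max_abs(x$values - diag(1 + 0i, x$n_channels))))
  invisible(x)
}

#' Transform a VOP set into its as-measured counterpart
#'
#' SAR computed from the measured excitation vector equals
#' \eqn{x_{act}^H (M^H Q_j M) x_{act}}, so measuring through an error matrix
#' \eqn{M} is equivalent to supervising with the congruence-transformed VOP
#' set \eqn{\tilde Q_j = M^H Q_j M}.  Congruence preserves Hermiticity and
#' positive semidefiniteness, so the output is again a valid VOP set in the
#' original order.
#'
#' @param vops A [vop_set()].
#' @param M An `"error_matrix"` (from [build_error_matrix()] or
#'   [custom_error_matrix()]).
#' @return A [vop_set()] of the transformed matrices, labels preserved.
#' @examples
#' vops <- vop_set(list(diag(2) + 0i))
#' transform_vops(vops, custom_error_matrix(0.5 * diag(2) + 0i))
#' @export
transform_vops <- function(vops, M) {
  vops <- as_vop_set(vops)
  stopifnot(inherits(M, "error_matrix"))
  if (M$n_channels != vops$n_channels) {
    abort(sprintf("Error matrix has %d channels but the VOP set has %d.",
                  M$n_channels, vops$n_channels),
          class = "ptxsar_bad_input")
  }
  Mv <- M$values
  MH <- Conj(t(Mv))
  out <- lapply(vops$matrices, function(Q) hermitianize(MH %*% Q %*% Mv))
  structure(list(matrices = out,
                 n_channels = vops$n_channels,
                 n_vops = vops$n_vops,
                 labels = vops$labels),
            class = "vop_set")
}

#' Worst-case single-channel SAR underestimation ratio
#'
#' For one transmitter with full reflection fraction `s11_magnitude`, the
#' measured forward signal is smallest when the leaked reflected wave
#' opposes the actual forward wave in phase, giving a measured amplitude
#' \eqn{1 - |s_{11}|/D} per unit forward amplitude.  Since single-channel
#' SAR scales with forward power, the worst-case ratio of actual to
#' measured-inferred SAR is
#' \deqn{r = (1 - |s_{11}|/D)^{-2}.}
#'
#' @param s11_magnitude Reflection coefficient magnitude in `[0, 1]`.
#' @param directivity_db Coupler directivity in dB (voltage convention).
#' @return The worst-case ratio \eqn{r \ge 1} (vectorized over either
#'   argument).
#' @examples
#' single_channel_worst_case(1, 20)  # 1/0.81
#' # underestimation as a fraction of actual SAR at 25 dB:
#' 1 - 1 / single_channel_worst_case(1, 25)  # ~0.1093
#' @export
single_channel_worst_case <- function(s11_magnitude, directivity_db) {
  stopifnot(is.numeric(s11_magnitude), all(is.finite(s11_magnitude)),
            all(s11_magnitude >= 0), all(s11_magnitude <= 1))
  d_lin <- linear_directivity(directivity_db)
  frac <- s11_magnitude / d_lin
  if (any(frac >= 1)) {
    abort(paste0("s11_magnitude / D_linear >= 1: the measured forward signal ",
                 "can vanish and the worst-case ratio is infinite."),
          class = "ptxsar_unbounded")
  }
  (1 - frac)^-2
}
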