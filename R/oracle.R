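#' Brute-force lower bound on the worst-case SAR ratio
#'
#' Independent verification instrument for [worst_case_ratio()]: samples
#' isotropic complex Gaussian excitation directions, normalizes each so that
#' the maximum measured-VOP quadratic form equals one (putting every sample
#' on the feasible boundary, where the maximum lives), evaluates the maximum
#' actual-VOP quadratic form, and applies deterministic local ascent to the
#' best candidates.  The result is a certified lower bound on the true
#' worst-case ratio.  Sampling is exponentially inefficient in the channel
#' count; this is a test instrument for small arrays (up to ~8 channels),
#' not a production solver.
#'
#' The sample stream is prefix-stable: for a fixed seed, the first
#' `n` samples of a larger request coincide with a smaller request, so the
#' bound is non-decreasing in `n_samples`.
#'
#' @param actual_vops,measured_vops [vop_set()] objects on the same channels.
#' @param n_samples Number of random excitation directions (>= 1).
#' @param seed Integer seed; identical seeds give identical results.
#' @param n_polish Number of top candidates refined by local ascent.
#' @param polish_iters Ascent iterations per candidate (step size halves on
#'   non-improvement).
#' @return An object of class `"oracle_result"`: `lower_bound_ratio`,
#'   `best_excitation` (feasible, unit measured SAR), `n_samples`, `seed`.
#' @examples
#' vops <- vop_set(list(diag(2) + 0i))
#' oracle_max_ratio(vops, vops, n_samples = 100, seed = 1)$lower_bound_ratio
#' @export
oracle_max_ratio <- function(actual_vops, measured_vops, n_samples, seed,
                             n_polish = 32L, polish_iters = 200L) {
  actual_vops <- as_vop_set(actual_vops, "actual_vops")
  measured_vops <- as_vop_set(measured_vops, "measured_vops")
  if (actual_vops$n_channels != measured_vops$n_channels) {
    abort("The two VOP sets act on different channel counts.",
          class = "ptxsar_bad_input")
  }
  stopifnot(is.numeric(n_samples), length(n_samples) == 1L)
  if (n_samples < 1) {
    abort("`n_samples` must be at least 1.", class = "ptxsar_bad_input")
  }
  n <- actual_vops$n_channels
  X <- withr::with_seed(seed, rcnorm_rows(n_samples, n))
  qforms <- function(mats) {
    vapply(mats, function(Q) {
      Re(rowSums((X %*% Q) * Conj(X)))
    }, numeric(nrow(X)))
  }
  den <- qforms(measured_vops$matrices)
  num <- qforms(actual_vops$matrices)
  if (n_samples == 1L) { den <- rbind(c(den)); num <- rbind(c(num)) }
  den_max <- apply(den, 1, max)
  num_max <- apply(num, 1, max)
  ok <- den_max > 0
  if (!any(ok)) {
    abort("Every sampled drive has zero measured SAR; the ratio is unbounded.",
          class = "ptxsar_unbounded")
  }
  ratios <- ifelse(ok, num_max / den_max, -Inf)
  ord <- order(ratios, decreasing = TRUE)
  best_i <- ord[1]
  best_x <- X[best_i, ] / sqrt(den_max[best_i])
  best <- ratios[best_i]
  for (i in head(ord, n_polish)) {
    if (!ok[i]) next
    pol <- ascend_ratio(X[i, ], actual_vops$matrices, measured_vops$matrices,
                        iters = polish_iters)
    if (!is.null(pol) && pol$value > best) {
      best <- pol$value
      best_x <- pol$x
    }
  }
  structure(list(lower_bound_ratio = best,
                 best_excitation = best_x,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "oracle_result")
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("<oracle_result> lower bound %.6g from %d samples (seed %d)\n",
              x$lower_bound_ratio, x$n_samples, x$seed))
  invisible(x)
}

#' Exact worst-case ratio for a single VOP pair
#'
#' With exactly one measured constraint, the worst-case ratio
#' \eqn{\max_x x^H Q x / x^H \tilde Q x} is the largest generalized
#' eigenvalue of the pencil \eqn{(Q, \tilde Q)}, computed stably via
#' Cholesky whitening of \eqn{\tilde Q}.
#'
#' @param Q Hermitian matrix (numerator form).
#' @param Qt Hermitian positive-definite matrix (denominator form).
#' @return The largest generalized eigenvalue, a real scalar.
#' @examples
#' generalized_eig_ratio(2 * diag(2) + 0i, diag(2) + 0i)  # 2
#' @export
generalized_eig_ratio <- function(Q, Qt) {
  Q <- as_complex_matrix(as.matrix(Q))
  Qt <- as_complex_matrix(as.matrix(Qt))
  if (!is_hermitian(Q) || !is_hermitian(Qt)) {
    abort("Both matrices must be Hermitian.", class = "ptxsar_not_hermitian")
  }
  ev <- hermitian_eigenvalues(Qt)
  if (min(ev) <= 0) {
    abort(paste0("`Qt` is singular or indefinite; with a rank-deficient ",
                 "denominator the worst-case ratio is unbounded (see the ",
                 "unbounded semantics of worst_case_ratio())."),
          class = "ptxsar_singular")
  }
  geneig_max_real(real_embed(Q), real_embed(Qt))$value
}
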