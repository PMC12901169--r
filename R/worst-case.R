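#' Worst-case SAR underestimation ratio between two VOP sets
#'
#' The convex-optimization comparison of two SAR matrix sets: the maximum,
#' over all complex excitation vectors, of actual SAR (max over the first
#' set) divided by supervised SAR (max over the second set),
#' \deqn{r = \max_j \max_x \frac{x^H Q_j x}{\max_k x^H \tilde Q_k x}.}
#' The inner maximization for each \eqn{Q_j} is a quadratic program with
#' ellipsoidal constraints, solved through its semidefinite relaxation; the
#' outer maximization over \eqn{j} is an exhaustive loop with ties broken by
#' lowest index.  The reported `ratio` is a certified upper bound and
#' `argmax_excitation` a feasible excitation achieving at least
#' `ratio * (1 - certificate_gap)`.
#'
#' @param actual_vops A [vop_set()]: the true SAR model.
#' @param measured_vops A [vop_set()] on the same channels: the SAR model as
#'   seen through the measurement (usually [transform_vops()] of
#'   `actual_vops` with an error matrix).
#' @param tol Target relative duality gap of the solver.
#' @return An object of class `"worst_case_result"` with fields `ratio`,
#'   `argmax_vop_index`, `argmax_excitation` (normalized to unit measured
#'   SAR), `solver_status`, `certificate_gap`, and `per_vop` (tibble of
#'   per-VOP bounds).
#' @examples
#' vops <- vop_set(list(diag(2) + 0i))
#' M <- custom_error_matrix(0.5 * diag(2) + 0i)
#' worst_case_ratio(vops, transform_vops(vops, M))$ratio  # 4
#' @seealso [max_ratio_at_phase()], [oracle_max_ratio()]
#' @export
worst_case_ratio <- function(actual_vops, measured_vops,
                             tol = ptxsar_tol("solver")) {
  actual_vops <- as_vop_set(actual_vops, "actual_vops")
  measured_vops <- as_vop_set(measured_vops, "measured_vops")
  if (actual_vops$n_channels != measured_vops$n_channels) {
    abort("The two VOP sets act on different channel counts.",
          class = "ptxsar_bad_input")
  }
  prep <- prepare_worst_case(actual_vops, measured_vops)
  Qt_r <- lapply(prep$Qt, real_embed)
  results <- vector("list", length(prep$Q))
  for (j in seq_along(prep$Q)) {
    results[[j]] <- solve_one_vop(prep$Q[[j]], prep$Qt, real_embed(prep$Q[[j]]),
                                  Qt_r, tol)
  }
  statuses <- vapply(results, function(r) r$status, character(1))
  if (any(statuses == "solver_failure")) {
    abort(sprintf("Worst-case solver failed on VOP index %d.",
                  which(statuses == "solver_failure")[1]),
          class = "ptxsar_solver_failure")
  }
  bounds <- vapply(results, function(r) r$bound, numeric(1))
  jstar <- which.max(bounds)        # which.max takes the lowest tied index
  x <- results[[jstar]]$x
  if (!is.null(prep$U)) x <- as.vector(prep$U %*% x)
  structure(list(
    ratio = bounds[jstar],
    argmax_vop_index = jstar,
    argmax_excitation = x,
    solver_status = statuses[jstar],
    certificate_gap = results[[jstar]]$gap,
    per_vop = tibble(vop_index = seq_along(bounds),
                     bound = bounds,
                     achieved = vapply(results, function(r) r$achieved,
                                       numeric(1)),
                     certificate_gap = vapply(results, function(r) r$gap,
                                              numeric(1)),
                     solver_status = statuses)),
    class = "worst_case_result")
}

#' @export
print.worst_case_result <- function(x, ...) {
  cat(sprintf(paste0("<worst_case_result> ratio %.6g (underestimation %.3g%% ",
                     "of actual), VOP %d, gap %.2g, %s\n"),
              x$ratio, (1 - 1 / x$ratio) * 100, x$argmax_vop_index,
              x$certificate_gap, x$solver_status))
  invisible(x)
}

#' @rdname worst_case_ratio
#' @param x A `worst_case_result`.
#' @param ... Unused.
#' @method tidy worst_case_result
#' @export
tidy.worst_case_result <- function(x, ...) x$per_vop

#' @rdname worst_case_ratio
#' @method glance worst_case_result
#' @export
glance.worst_case_result <- function(x, ...) {
  tibble(ratio = x$ratio,
         percent_of_actual = (1 - 1 / x$ratio) * 100,
         percent_of_measured = (x$ratio - 1) * 100,
         argmax_vop_index = x$argmax_vop_index,
         certificate_gap = x$certificate_gap,
         solver_status = x$solver_status)
}

#' Worst-case SAR error at one reference-plane phase offset
#'
#' Builds the coupler error matrix for the given phase offset, transforms
#' the VOP set into its as-measured counterpart and solves the worst-case
#' ratio of actual to measured SAR over all complex excitations.
#'
#' @inheritParams worst_case_ratio
#' @param vops A [vop_set()] (the actual SAR model).
#' @param S An [smatrix()].
#' @param coupler A [coupler_model()] (carries the phase offset).
#' @return A `"worst_case_result"`; see [worst_case_ratio()].
#' @examples
#' S <- smatrix(matrix(0.3 + 0i, 1, 1))
#' vops <- vop_set(list(matrix(1 + 0i, 1, 1)))
#' max_ratio_at_phase(vops, S, coupler_model(25, phase_rad = pi))
#' @export
max_ratio_at_phase <- function(vops, S, coupler, tol = ptxsar_tol("solver")) {
  vops <- as_vop_set(vops)
  M <- build_error_matrix(S, coupler)
  worst_case_ratio(vops, transform_vops(vops, M), tol = tol)
}

new_phase_sweep_result <- function(sweep, kind, directivity_db, n_steps,
                                   attenuation) {
  peak_i <- which.max(sweep$ratio)
  structure(list(sweep = sweep,
                 kind = kind,
                 directivity_db = directivity_db,
                 attenuation = attenuation,
                 n_steps = n_steps,
                 peak_phase_rad = sweep$phase_rad[peak_i],
                 peak_ratio = sweep$ratio[peak_i],
                 peak_percent_of_actual = sweep$percent_of_actual[peak_i]),
            class = "phase_sweep_result")
}

#' Sweep the worst-case SAR error over the reference-plane phase
#'
#' The maximum underestimation over the phase offset \eqn{\phi} is not a
#' convex problem, so \eqn{\phi} is swept on a uniform grid over
#' \eqn{[0, 2\pi)} (endpoint excluded; the default of 360 steps gives one
#' point per degree) and the worst case solved at every grid point.
#'
#' Underestimation percentages are reported in both conventions: as a
#' fraction of the actual SAR, \eqn{(1 - 1/r) \cdot 100} (the default
#' headline number), and as excess over the measured value,
#' \eqn{(r - 1) \cdot 100}.
#'
#' @inheritParams max_ratio_at_phase
#' @param directivity_db Coupler directivity in dB (scalar or per-channel).
#' @param n_steps Number of phase grid points (default 360).
#' @param attenuation Linear cable attenuation factor \eqn{\mu \ge 1}.
#' @return A `"phase_sweep_result"`: the per-phase tibble (`phase_rad`,
#'   `ratio`, `percent_of_actual`, `percent_of_measured`,
#'   `argmax_vop_index`, `certificate_gap`, `solver_status`) plus peak
#'   metadata (`peak_phase_rad`, `peak_ratio`, `peak_percent_of_actual`).
#' @examples
#' S <- smatrix(matrix(0.5 + 0i, 1, 1))
#' vops <- vop_set(list(matrix(1 + 0i, 1, 1)))
#' sw <- phase_sweep(vops, S, 25, n_steps = 36)
#' glance(sw)
#' @export
phase_sweep <- function(vops, S, directivity_db, n_steps = 360L,
                        attenuation = 1, tol = ptxsar_tol("solver")) {
  stopifnot(n_steps >= 1L)
  vops <- as_vop_set(vops)
  S <- as_smatrix(S)
  phases <- 2 * pi * (seq_len(n_steps) - 1L) / n_steps
  ratio <- gap <- numeric(n_steps)
  argmax <- integer(n_steps)
  status <- character(n_steps)
  for (i in seq_len(n_steps)) {
    res <- tryCatch(
      max_ratio_at_phase(vops, S,
                         coupler_model(directivity_db, phases[i], attenuation),
                         tol = tol),
      error = function(e) {
        abort(sprintf("Worst-case solve failed at phase %.6g rad: %s",
                      phases[i], conditionMessage(e)),
              class = class(e)[1], parent = e, phase_rad = phases[i])
      })
    ratio[i] <- res$ratio
    gap[i] <- res$certificate_gap
    argmax[i] <- res$argmax_vop_index
    status[i] <- res$solver_status
  }
  sweep <- tibble(phase_rad = phases,
                  ratio = ratio,
                  percent_of_actual = (1 - 1 / ratio) * 100,
                  percent_of_measured = (ratio - 1) * 100,
                  argmax_vop_index = argmax,
                  certificate_gap = gap,
                  solver_status = status)
  new_phase_sweep_result(sweep, "sar", directivity_db, n_steps, attenuation)
}

#' Worst-case total forward-power error at one phase offset
#'
#' The maximum ratio of actual to measured total forward power over all
#' excitations is \eqn{1 / \lambda_{min}(M^H M)} with \eqn{M} the error
#' matrix — equivalent to running the worst-case SAR machinery with a single
#' identity VOP.
#'
#' @inheritParams max_ratio_at_phase
#' @return The worst-case power ratio (a positive scalar).
#' @examples
#' S <- smatrix(matrix(1 + 0i, 1, 1))
#' power_error_at_phase(S, coupler_model(25, phase_rad = pi))  # ~1.1227
#' @export
power_error_at_phase <- function(S, coupler) {
  M <- build_error_matrix(S, coupler)$values
  lam_min <- min(hermitian_eigenvalues(Conj(t(M)) %*% M))
  if (lam_min <= 0) {
    abort("The error matrix is singular: measured power can vanish for a nonzero drive.",
          class = "ptxsar_singular")
  }
  1 / lam_min
}

#' Sweep the worst-case forward-power error over the reference-plane phase
#'
#' As [phase_sweep()] but with the total-forward-power error
#' (see [power_error_at_phase()]) as the per-phase kernel.
#'
#' @inheritParams phase_sweep
#' @return A `"phase_sweep_result"` of kind `"power"` (the
#'   `argmax_vop_index` column is `NA`: no VOP is involved).
#' @examples
#' sw <- power_error_sweep(smatrix(matrix(0.8 + 0i, 1, 1)), 25, n_steps = 36)
#' sw$peak_percent_of_actual
#' @export
power_error_sweep <- function(S, directivity_db, n_steps = 360L,
                              attenuation = 1) {
  stopifnot(n_steps >= 1L)
  S <- as_smatrix(S)
  phases <- 2 * pi * (seq_len(n_steps) - 1L) / n_steps
  ratios <- vapply(phases, function(phi) {
    tryCatch(
      power_error_at_phase(S, coupler_model(directivity_db, phi, attenuation)),
      error = function(e) {
        abort(sprintf("Power-error evaluation failed at phase %.6g rad: %s",
                      phi, conditionMessage(e)),
              class = class(e)[1], parent = e, phase_rad = phi)
      })
  }, numeric(1))
  sweep <- tibble(phase_rad = phases,
                  ratio = ratios,
                  percent_of_actual = (1 - 1 / ratios) * 100,
                  percent_of_measured = (ratios - 1) * 100,
                  argmax_vop_index = NA_integer_,
                  certificate_gap = 0,
                  solver_status = "exact")
  new_phase_sweep_result(sweep, "power", directivity_db, n_steps, attenuation)
}

#' @export
print.phase_sweep_result <- function(x, ...) {
  cat(sprintf(paste0("<phase_sweep_result:%s> %d phases, directivity %s dB; ",
                     "peak ratio %.6g (%.3g%% of actual) at phase %.4g rad\n"),
              x$kind, x$n_steps,
              paste(format(x$directivity_db), collapse = "/"),
              x$peak_ratio, x$peak_percent_of_actual, x$peak_phase_rad))
  invisible(x)
}

#' @rdname phase_sweep
#' @param x A `phase_sweep_result`.
#' @param ... Unused.
#' @method tidy phase_sweep_result
#' @export
tidy.phase_sweep_result <- function(x, ...) x$sweep

#' @rdname phase_sweep
#' @method glance phase_sweep_result
#' @export
glance.phase_sweep_result <- function(x, ...) {
  tibble(kind = x$kind,
         n_steps = x$n_steps,
         directivity_db = paste(format(x$directivity_db), collapse = "/"),
         attenuation = x$attenuation,
         peak_phase_rad = x$peak_phase_rad,
         peak_ratio = x$peak_ratio,
         peak_percent_of_actual = x$peak_percent_of_actual,
         peak_percent_of_measured = (x$peak_ratio - 1) * 100,
         max_certificate_gap = max(x$sweep$certificate_gap))
}
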