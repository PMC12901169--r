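# Internal worst-case quadratic-ratio solver.
#
# Inner problem (per actual VOP Q_j, real embedding):
#   maximize x^T Q_j x  subject to  x^T Qt_k x <= 1 for all measured VOPs.
# Semidefinite relaxation dual:
#   minimize sum(lambda)  s.t.  sum_k lambda_k Qt_k >= Q_j,  lambda >= 0,
# solved by log-det barrier path following (Newton in the K dual variables).
# Both sum(lambda) at any strictly feasible dual point and the largest
# generalized eigenvalue of (Q_j, Qt(w)) at normalized weights w are sound
# upper bounds on the true maximum; the reported bound is their minimum.
# A feasible excitation is extracted from the generalized eigenvector and
# polished by deterministic local ascent; the relative distance between
# bound and achieved value is the certificate gap.

# largest generalized eigenvalue of (A, B), A,B real symmetric, B PD
geneig_max_real <- function(A, B) {
  R <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(R)) {
    abort("Denominator matrix is not positive definite.",
          class = "ptxsar_singular")
  }
  Ui <- backsolve(R, diag(nrow(B)))
  W <- t(Ui) %*% A %*% Ui
  e <- eigen((W + t(W)) / 2, symmetric = TRUE)
  z <- Ui %*% e$vectors[, 1]
  list(value = e$values[1], vector = as.numeric(z))
}

# Barrier method for the dual SDP; Ar and Bt_list are real symmetric
# embeddings.  Returns strictly feasible lambda (so sum(lambda) is a valid
# bound) and convergence status.
sdr_dual_barrier <- function(Ar, Bt_list, tol = ptxsar_tol("solver")) {
  K <- length(Bt_list)
  n <- nrow(Ar)
  Bsum <- Reduce(`+`, Bt_list)
  g0 <- geneig_max_real(Ar, Bsum)$value
  if (g0 <= 0) {            # numerator form non-positive everywhere
    return(list(lambda = rep(max(g0, 0) + 1e-12, K), converged = TRUE))
  }
  lambda <- rep(1.05 * g0, K)
  nu <- n + K               # barrier parameter of the LMI plus orthant
  t_bar <- nu / (0.5 * sum(lambda))
  barrier_val <- function(lam, t_val) {
    F <- Reduce(`+`, Map(`*`, lam, Bt_list)) - Ar
    R <- tryCatch(chol(F), error = function(e) NULL)
    if (is.null(R) || any(lam <= 0)) return(list(val = Inf))
    list(val = t_val * sum(lam) - 2 * sum(log(diag(R))) - sum(log(lam)),
         R = R)
  }
  converged <- TRUE
  for (outer in seq_len(40L)) {
    for (newton in seq_len(60L)) {
      F <- Reduce(`+`, Map(`*`, lambda, Bt_list)) - Ar
      R <- tryCatch(chol(F), error = function(e) NULL)
      if (is.null(R)) { converged <- FALSE; break }
      Fi <- chol2inv(R)
      G <- lapply(Bt_list, function(B) Fi %*% B)
      grad <- t_bar - vapply(G, function(g) sum(diag(g)), numeric(1)) -
        1 / lambda
      H <- matrix(0, K, K)
      for (k in seq_len(K)) {
        for (l in k:K) {
          H[k, l] <- H[l, k] <- sum(G[[k]] * t(G[[l]]))
        }
      }
      diag(H) <- diag(H) + 1 / lambda^2
      step <- tryCatch(-solve(H + diag(1e-14 * max(diag(H)), K), grad),
                       error = function(e) NULL)
      if (is.null(step)) { converged <- FALSE; break }
      decrement <- -sum(grad * step)
      if (decrement < 1e-11) break
      f0 <- t_bar * sum(lambda) - 2 * sum(log(diag(R))) - sum(log(lambda))
      alpha <- 1
      repeat {
        cand <- lambda + alpha * step
        bv <- barrier_val(cand, t_bar)
        if (is.finite(bv$val) && bv$val <= f0 - 0.25 * alpha * decrement) {
          lambda <- cand
          break
        }
        alpha <- alpha / 2
        if (alpha < 1e-14) break
      }
      if (alpha < 1e-14) break
    }
    if (nu / t_bar < tol * max(sum(lambda), 1e-12)) break
    t_bar <- t_bar * 20
  }
  list(lambda = lambda, converged = converged)
}

# Deterministic local ascent on f(x) = max_j x^H Q_j x / max_k x^H Qt_k x,
# keeping x on the measured-SAR boundary.  Step halves on non-improvement.
ascend_ratio <- function(x, Q_list, Qt_list, iters = 200L, step0 = 0.2) {
  normalize <- function(v) {
    den <- max(vapply(Qt_list, quad_form, numeric(1), x = v))
    if (den <= 0) return(NULL)
    v / sqrt(den)
  }
  x <- normalize(x)
  if (is.null(x)) return(NULL)
  value <- function(v) max(vapply(Q_list, quad_form, numeric(1), x = v))
  f <- value(x)
  alpha <- step0
  for (it in seq_len(iters)) {
    nums <- vapply(Q_list, quad_form, numeric(1), x = x)
    dens <- vapply(Qt_list, quad_form, numeric(1), x = x)
    jstar <- which.max(nums)
    kstar <- which.max(dens)
    d <- Q_list[[jstar]] %*% x - nums[jstar] * (Qt_list[[kstar]] %*% x)
    dn <- sqrt(Re(sum(Conj(d) * d)))
    if (dn < 1e-14) break
    cand <- normalize(x + alpha * (d / dn))
    if (!is.null(cand) && value(cand) > f) {
      x <- cand
      f <- value(cand)
      alpha <- alpha * 1.5
    } else {
      alpha <- alpha / 2
      if (alpha < 1e-12) break
    }
  }
  list(x = x, value = f)
}

# Scale normalization plus common-null-space deflation for a pair of VOP
# sets.  Detects directions with positive actual SAR but zero measured SAR
# (unbounded underestimation) and otherwise projects onto the range of the
# summed measured set.
prepare_worst_case <- function(actual, measured) {
  norms <- vapply(actual$matrices, spectral_norm_hermitian, numeric(1))
  scale <- max(norms)
  if (scale <= 0) {
    abort("All actual VOP matrices are zero.", class = "ptxsar_bad_input")
  }
  Q <- lapply(actual$matrices, function(M) M / scale)
  Qt <- lapply(measured$matrices, function(M) M / scale)
  Ssum <- Reduce(`+`, Qt)
  e <- eigen(Ssum, symmetric = TRUE)
  maxev <- max(e$values, 0)
  if (maxev <= 0) {
    abort(paste0("All measured VOP matrices vanish while actual SAR is ",
                 "positive: the worst-case ratio is unbounded."),
          class = "ptxsar_unbounded")
  }
  keep <- e$values > 1e-12 * maxev
  U <- NULL
  if (!all(keep)) {
    V0 <- e$vectors[, !keep, drop = FALSE]
    leak <- max(vapply(Q, function(Qj) {
      max_abs(Conj(t(V0)) %*% Qj %*% V0)
    }, numeric(1)))
    if (leak > 1e-10) {
      abort(paste0("A drive direction exists with positive actual SAR but ",
                   "zero measured SAR for every VOP: the worst-case ",
                   "underestimation is unbounded (singular error matrix or ",
                   "rank-deficient VOP set)."),
            class = "ptxsar_unbounded")
    }
    U <- e$vectors[, keep, drop = FALSE]
    Q <- lapply(Q, function(M) hermitianize(Conj(t(U)) %*% M %*% U))
    Qt <- lapply(Qt, function(M) hermitianize(Conj(t(U)) %*% M %*% U))
  }
  list(Q = Q, Qt = Qt, U = U, scale = scale)
}

# Solve the inner maximization for one actual VOP against the measured set.
solve_one_vop <- function(Qc, Qt_c, Qr, Qt_r, tol = ptxsar_tol("solver")) {
  if (spectral_norm_hermitian(Qc) < 1e-14) {
    n <- nrow(Qc)
    x <- rep(0 + 0i, n)
    return(list(bound = 0, x = x, achieved = 0, gap = 0, status = "optimal"))
  }
  if (length(Qt_r) == 1L) {
    # single constraint: the dual weight simplex is a point and the bound
    # is exactly the largest generalized eigenvalue of (Q, Qt)
    ge <- geneig_max_real(Qr, Qt_r[[1]])
    bound <- ge$value
    converged <- TRUE
  } else {
    dual <- sdr_dual_barrier(Qr, Qt_r, tol)
    w <- dual$lambda / sum(dual$lambda)
    Bw <- Reduce(`+`, Map(`*`, w, Qt_r))
    ge <- geneig_max_real(Qr, Bw)
    bound <- min(sum(dual$lambda), ge$value)
    converged <- dual$converged
  }
  x0 <- unembed_vector(ge$vector)
  pol <- ascend_ratio(x0, list(Qc), Qt_c, iters = 150L)
  if (is.null(pol)) {
    return(list(bound = bound, x = x0, achieved = NA_real_, gap = NA_real_,
                status = "solver_failure"))
  }
  gap <- max(0, (bound - pol$value) / max(bound, 1e-300))
  status <- if (converged) "optimal" else "stalled"
  list(bound = bound, x = pol$x, achieved = pol$value, gap = gap,
       status = status)
}
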