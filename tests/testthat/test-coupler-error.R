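test_that("directivity converts on the voltage-dB convention", {
  expect_equal(linear_directivity(0), 1)
  expect_equal(linear_directivity(20), 10)
  expect_equal(linear_directivity(25), 17.7828, tolerance = 1e-5)
})

test_that("error matrix follows M = (1/mu) e^{i phi} D^{-1} S + I", {
  n <- 3
  S0 <- smatrix(matrix(0 + 0i, n, n))
  expect_equal(build_error_matrix(S0, coupler_model(25, 1.3))$values,
               diag(1 + 0i, n))

  # an (effectively) ideal coupler leaves the measurement untouched
  S <- random_passive_smatrix(n, seed = 3)
  M_ideal <- build_error_matrix(S, coupler_model(400, 0.7))$values
  expect_lt(max(abs(M_ideal - diag(1 + 0i, n))), 1e-15)

  # scalar 1-channel case forced by the signal model: 1 + e^{i pi} 0.5/10
  m <- build_error_matrix(smatrix(matrix(0.5 + 0i, 1, 1)),
                          coupler_model(20, phase_rad = pi))$values
  expect_equal(m[1, 1], 0.95 + 0i, tolerance = 1e-12)

  # explicit formula, with attenuation
  cp <- coupler_model(25, phase_rad = 0.4, attenuation_linear = 1.2)
  M <- build_error_matrix(S, cp)$values
  expect_equal(M, (1 / 1.2) * exp(0.4i) * S$values / 10^(25 / 20) + diag(n),
               tolerance = 1e-14)

  # per-channel directivities act as a diagonal left factor on S
  cpv <- coupler_model(c(20, 25, 30), phase_rad = 1.1)
  Mv <- build_error_matrix(S, cpv)$values
  expect_equal(Mv, exp(1.1i) * diag(1 / linear_directivity(c(20, 25, 30))) %*%
                 S$values + diag(n), tolerance = 1e-14)
  expect_error(build_error_matrix(S, coupler_model(c(20, 25))),
               class = "ptxsar_bad_input")
})

test_that("error matrix is 2*pi periodic and converges to identity", {
  S <- random_passive_smatrix(4, seed = 9)
  M1 <- build_error_matrix(S, coupler_model(25, 0.77))$values
  M2 <- build_error_matrix(S, coupler_model(25, 0.77 + 2 * pi))$values
  expect_equal(M1, M2, tolerance = 1e-14)

  dev <- vapply(c(20, 40, 80, 120, 200), function(db) {
    max(abs(build_error_matrix(S, coupler_model(db, 1))$values - diag(4)))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[length(dev)], 1e-9)
})

test_that("transform_vops is the congruence with the error matrix", {
  vops <- vop_set(lapply(1:2, function(j) random_hermitian_psd(2, seed = j)))
  expect_equal(transform_vops(vops, custom_error_matrix(diag(2) + 0i))$matrices,
               vops$matrices)
  sc <- transform_vops(vops, custom_error_matrix(3 * diag(2) + 0i))
  expect_equal(sc$matrices[[1]], 9 * vops$matrices[[1]], tolerance = 1e-12)

  M <- custom_error_matrix(random_complex_matrix(2, seed = 42))
  tv <- transform_vops(vops, M)
  withr::with_seed(8, {
    for (rep in 1:100) {
      x <- complex(real = rnorm(2), imaginary = rnorm(2))
      expect_equal(evaluate_sar(tv, x),
                   evaluate_sar(vops, as.vector(M$values %*% x)),
                   tolerance = 1e-10)
    }
  })
  expect_error(transform_vops(vops, custom_error_matrix(diag(3) + 0i)),
               class = "ptxsar_bad_input")
})

test_that("congruence preserves Hermiticity and positive semidefiniteness", {
  for (n in c(2, 5, 16)) {
    vops <- vop_set(lapply(1:3, function(j) {
      random_hermitian_psd(n, seed = 10 * n + j, rank = sample(1:n, 1))
    }))
    M <- custom_error_matrix(random_complex_matrix(n, seed = n))
    out <- transform_vops(vops, M)   # vop_set() re-validates both invariants
    for (Q in out$matrices) {
      expect_lt(max(abs(Q - Conj(t(Q)))), 1e-9 * max(abs(Q)))
      ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-10 * max(ev))
    }
  }
})

test_that("custom error matrices run through the full pipeline", {
  vops <- vop_set(lapply(1:2, function(j) random_hermitian_psd(2, seed = j)))
  ideal <- worst_case_ratio(vops, transform_vops(vops,
                                                 custom_error_matrix(diag(2) + 0i)))
  expect_equal(ideal$ratio, 1, tolerance = 1e-6)

  eps <- matrix(c(1, 0, 0.1, 1), 2) + 0i   # identity plus one off-diagonal
  pert <- worst_case_ratio(vops, transform_vops(vops, custom_error_matrix(eps)))
  expect_true(is.finite(pert$ratio) && pert$ratio > 0)
  orc <- oracle_max_ratio(vops, transform_vops(vops, custom_error_matrix(eps)),
                          n_samples = 5000, seed = 2)
  expect_gte(pert$ratio * (1 + 1e-8), orc$lower_bound_ratio)
  expect_lt(pert$ratio - orc$lower_bound_ratio, 0.02 * pert$ratio)

  expect_error(custom_error_matrix(matrix(0, 2, 3)),
               class = "ptxsar_bad_input")
})

test_that("single-channel worst case matches the phase-grid minimum", {
  expect_equal(single_channel_worst_case(0, 25), 1)
  expect_equal(single_channel_worst_case(1, 20), 1 / 0.81, tolerance = 1e-12)

  # oracle: minimize |1 + e^{i phi} s/D|^2 on a dense grid and invert
  phi <- seq(0, 2 * pi, length.out = 2e5)
  for (case in list(c(1, 20), c(1, 25), c(0.6, 25))) {
    d <- case[1] / linear_directivity(case[2])
    grid_min <- min(abs(1 + exp(1i * phi) * d)^2)
    expect_equal(single_channel_worst_case(case[1], case[2]), 1 / grid_min,
                 tolerance = 1e-8)
  }

  # underestimation fraction at 25 dB ties the dB convention down
  expect_equal(1 - 1 / single_channel_worst_case(1, 25), 0.1093,
               tolerance = 1e-3)

  # strictly increasing in |s11|, strictly decreasing in directivity
  expect_true(all(diff(single_channel_worst_case(seq(0, 0.99, 0.01), 25)) > 0))
  expect_true(all(diff(single_channel_worst_case(0.8, seq(10, 60, 2))) < 0))

  expect_error(single_channel_worst_case(1, 0), class = "ptxsar_unbounded")
})
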