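test_that("real embedding preserves Hermitian quadratic forms", {
  A <- matrix(c(2, 1, 1, 3), 2) + 0i       # real symmetric
  E <- real_embed(A)
  expect_equal(E, rbind(cbind(Re(A), -Im(A)), cbind(Im(A), Re(A))))
  expect_equal(E[1:2, 3:4], matrix(0, 2, 2))

  expect_equal(real_embed(matrix(1.5 + 0i, 1, 1)), 1.5 * diag(2))

  Q <- random_hermitian(4, seed = 21)
  Er <- real_embed(Q)
  expect_equal(Er, t(Er))
  withr::with_seed(3, {
    for (rep in 1:100) {
      x <- complex(real = rnorm(4), imaginary = rnorm(4))
      z <- c(Re(x), Im(x))
      expect_equal(drop(t(z) %*% Er %*% z), quad(Q, x), tolerance = 1e-10)
    }
  })
  expect_error(real_embed(random_complex_matrix(3, seed = 1)),
               class = "ptxsar_not_hermitian")
})

test_that("ideal measurement gives ratio one and simple cases are exact", {
  vops <- vop_set(lapply(1:3, function(j) random_hermitian_psd(3, seed = j)))
  S0 <- smatrix(matrix(0 + 0i, 3, 3))
  res <- max_ratio_at_phase(vops, S0, coupler_model(25, 1.2))
  expect_equal(res$ratio, 1, tolerance = 1e-6)

  # measured bound a quarter of actual forces ratio 4 (1-channel)
  q <- vop_set(list(matrix(1 + 0i, 1, 1)))
  qt <- vop_set(list(matrix(0.25 + 0i, 1, 1)))
  r4 <- worst_case_ratio(q, qt)
  expect_equal(r4$ratio, 4, tolerance = 1e-10)
  expect_equal(quad(qt$matrices[[1]], r4$argmax_excitation), 1,
               tolerance = 1e-8)
})

test_that("solver agrees with the sampling oracle on a coupled instance", {
  S <- random_passive_smatrix(2, seed = 31, strength = 0.7)
  vops <- vop_set(lapply(1:3, function(j) random_hermitian_psd(2, seed = 40 + j)))
  cp <- coupler_model(25, phase_rad = 1.0)
  res <- max_ratio_at_phase(vops, S, cp)
  measured <- transform_vops(vops, build_error_matrix(S, cp))
  orc <- oracle_max_ratio(vops, measured, n_samples = 2e4, seed = 5)
  expect_gte(res$ratio * (1 + 1e-8), orc$lower_bound_ratio)
  expect_lt((res$ratio - orc$lower_bound_ratio) / res$ratio, 0.02)
  # the certificate is honest: the reported excitation achieves the bound
  # up to the reported gap
  ach <- quad(vops$matrices[[res$argmax_vop_index]], res$argmax_excitation) /
    max(evaluate_sar(measured, res$argmax_excitation))
  expect_gte(ach, res$ratio * (1 - res$certificate_gap) - 1e-9)
})

test_that("with one VOP the ratio is the largest generalized eigenvalue", {
  for (seed in 1:10) {
    Q <- random_hermitian_psd(3, seed = seed)
    Qt <- random_hermitian_psd(3, seed = 100 + seed)
    r <- worst_case_ratio(vop_set(list(Q)), vop_set(list(Qt)))
    expect_equal(r$ratio, generalized_eig_ratio(Q, Qt), tolerance = 1e-9)
  }
})

test_that("the ratio is scale invariant and one in the ideal-coupler limit", {
  S <- random_passive_smatrix(3, seed = 17)
  vops <- vop_set(lapply(1:3, function(j) random_hermitian_psd(3, seed = 50 + j)))
  cp <- coupler_model(25, 0.9)
  base <- max_ratio_at_phase(vops, S, cp)$ratio
  scaled <- vop_set(lapply(vops$matrices, function(Q) 137.5 * Q))
  expect_equal(max_ratio_at_phase(scaled, S, cp)$ratio, base,
               tolerance = 1e-8)
  expect_equal(max_ratio_at_phase(vops, S, coupler_model(300, 0.9))$ratio, 1,
               tolerance = 1e-6)
})

test_that("phase-level and set-level entry points share one code path", {
  S <- random_passive_smatrix(2, seed = 77)
  vops <- vop_set(lapply(1:2, function(j) random_hermitian_psd(2, seed = 60 + j)))
  cp <- coupler_model(30, 2.2)
  a <- max_ratio_at_phase(vops, S, cp)
  b <- worst_case_ratio(vops, transform_vops(vops, build_error_matrix(S, cp)))
  expect_identical(a$ratio, b$ratio)
  expect_identical(a$argmax_excitation, b$argmax_excitation)
})

test_that("a null measured direction with positive actual SAR is unbounded", {
  vops <- vop_set(list(diag(2) + 0i))
  Msing <- custom_error_matrix(diag(c(1, 0)) + 0i)
  expect_error(worst_case_ratio(vops, transform_vops(vops, Msing)),
               class = "ptxsar_unbounded")
  # but a harmless common null direction is deflated away: actual SAR also
  # vanishes along e2, so the solve proceeds
  vops2 <- vop_set(list(diag(c(1, 0)) + 0i))
  r <- worst_case_ratio(vops2, transform_vops(vops2, Msing))
  expect_equal(r$ratio, 1, tolerance = 1e-8)
})

test_that("power error equals the identity-VOP worst case", {
  S0 <- smatrix(matrix(0 + 0i, 2, 2))
  expect_equal(power_error_at_phase(S0, coupler_model(25, 0)), 1)

  # 1-channel full reflection at opposed phase, 25 dB: M = 0.943766
  m <- build_error_matrix(smatrix(matrix(1 + 0i, 1, 1)),
                          coupler_model(25, pi))$values[1, 1]
  expect_equal(Re(m), 0.943766, tolerance = 1e-6)
  expect_equal(power_error_at_phase(smatrix(matrix(1 + 0i, 1, 1)),
                                    coupler_model(25, pi)),
               1.12272, tolerance = 1e-5)

  for (seed in 1:5) {
    S <- random_passive_smatrix(4, seed = 200 + seed, strength = 0.8)
    cp <- coupler_model(25, phase_rad = seed)
    pe <- power_error_at_phase(S, cp)
    M <- build_error_matrix(S, cp)$values
    ident <- vop_set(list(diag(4) + 0i))
    rid <- worst_case_ratio(ident, vop_set(list(Conj(t(M)) %*% M)))
    expect_lt(abs(pe - rid$ratio) / pe, 1e-4)
  }

  # a (non-physical) fully anti-aligned reflection cancels the measured
  # signal exactly: the error matrix is singular and must be flagged
  d <- linear_directivity(20)
  S_sing <- suppressWarnings(smatrix(diag(-d, 2) + 0i))
  expect_error(power_error_at_phase(S_sing, coupler_model(20, 0)),
               class = "ptxsar_singular")
})

test_that("power-error sweep hits the aligned-reflection closed form", {
  sw0 <- power_error_sweep(smatrix(matrix(0 + 0i, 3, 3)), 25, n_steps = 36)
  expect_true(all(abs(sw0$sweep$ratio - 1) < 1e-12))

  # unitary S: every mode reaches opposed phase somewhere on the grid, so
  # the peak matches the scalar worst case (1 - (1 - 1/D)^2) * 100
  U <- random_unitary(4, seed = 55)
  swu <- power_error_sweep(suppressWarnings(smatrix(U)), 40, n_steps = 360)
  d <- 1 / linear_directivity(40)
  expect_equal(swu$peak_percent_of_actual, (1 - (1 - d)^2) * 100,
               tolerance = 1e-3)

  # 2*pi periodicity of the kernel
  S <- random_passive_smatrix(3, seed = 91)
  expect_equal(power_error_at_phase(S, coupler_model(25, 0.3)),
               power_error_at_phase(S, coupler_model(25, 0.3 + 2 * pi)),
               tolerance = 1e-12)
})

test_that("phase sweeps record grid, peak and solver metadata", {
  expect_identical(eval(formals(phase_sweep)$n_steps), 360L)
  expect_identical(eval(formals(power_error_sweep)$n_steps), 360L)

  vops <- vop_set(lapply(1:2, function(j) random_hermitian_psd(2, seed = 70 + j)))
  S0 <- smatrix(matrix(0 + 0i, 2, 2))
  sw <- phase_sweep(vops, S0, 25, n_steps = 12)
  expect_equal(sw$sweep$phase_rad, 2 * pi * (0:11) / 12)
  expect_true(all(abs(sw$sweep$ratio - 1) < 1e-6))
  expect_equal(sw$peak_ratio, max(sw$sweep$ratio))

  g <- glance(sw)
  expect_equal(g$peak_ratio, sw$peak_ratio)
  expect_s3_class(tidy(sw), "tbl_df")
  expect_s3_class(autoplot(sw), "ggplot")
})
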