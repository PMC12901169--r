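test_that("validate_smatrix reports passivity and entry magnitude", {
  rep0 <- validate_smatrix(smatrix(matrix(0 + 0i, 3, 3)))
  expect_true(all(rep0$status == "pass"))
  expect_equal(rep0$value[rep0$check == "passivity"], 0)

  # lossless full reflection sits exactly on the passivity boundary
  rep1 <- validate_smatrix(smatrix(diag(3) + 0i))
  expect_identical(rep1$status[rep1$check == "passivity"], "pass")
  expect_equal(rep1$value[rep1$check == "passivity"], 1, tolerance = 1e-12)

  # a row scaled beyond 1 is flagged as a warning-level check, and the
  # eigenvalue is reported (diag(2.25, 1, 1) of S^H S)
  V <- diag(3) + 0i
  V[1, ] <- 1.5 * V[1, ]
  expect_warning(S <- smatrix(V), class = "ptxsar_nonpassive")
  rep2 <- validate_smatrix(S)
  expect_identical(rep2$status[rep2$check == "passivity"], "warn")
  expect_equal(rep2$value[rep2$check == "passivity"], 2.25, tolerance = 1e-12)
  expect_equal(rep2$value[rep2$check == "max_abs_entry"], 1.5)
})

test_that("reflected power spectrum equals squared singular values", {
  expect_equal(reflected_power_spectrum(smatrix(matrix(0 + 0i, 2, 2)))$eigenvalues,
               c(0, 0))
  U <- random_unitary(4, seed = 11)
  expect_equal(reflected_power_spectrum(suppressWarnings(smatrix(U)))$eigenvalues,
               rep(1, 4), tolerance = 1e-12)
  expect_equal(reflected_power_spectrum(smatrix(diag(c(0.6, 0.3)) + 0i))$eigenvalues,
               c(0.36, 0.09))
  for (n in c(2, 5, 17, 32)) {
    S <- random_passive_smatrix(n, seed = 100 + n, strength = 0.8)
    spec <- reflected_power_spectrum(S)
    expect_equal(spec$eigenvalues, sort(svd(S$values)$d^2, decreasing = TRUE),
                 tolerance = 1e-10)
    expect_length(spec$eigenvalues, n)
    expect_true(all(spec$eigenvalues >= -1e-10))
  }
  expect_error(smatrix(matrix(0 + 0i, 2, 3)), class = "ptxsar_bad_input")
})

test_that("evaluate_sar computes quadratic forms per VOP", {
  vops <- vop_set(list(diag(3) + 0i, 2 * diag(3) + 0i))
  expect_equal(evaluate_sar(vops, rep(0 + 0i, 3)), c(0, 0))
  expect_equal(evaluate_sar(vop_set(list(diag(4) + 0i)), rep(1, 4)), 4)

  # hand expansion: Q = [[1, -i], [i, 1]] has eigenpair (2, (1, i));
  # x = (1, i) gives x^H Q x = 2 * |x|^2 = 4
  Q <- matrix(c(1, 1i, -1i, 1), 2)
  x <- c(1, 1i)
  brute <- Re(Conj(x) %*% Q %*% x)[1]
  expect_equal(brute, 4)
  expect_equal(evaluate_sar(vop_set(list(Q)), x), 4)

  expect_error(evaluate_sar(vops, c(1, 2)), class = "ptxsar_bad_input")
})

test_that("SAR is invariant under global phase and quadratic in amplitude", {
  vops <- vop_set(lapply(1:3, function(j) random_hermitian_psd(4, seed = j)))
  withr::with_seed(5, {
    for (rep in 1:10) {
      x <- complex(real = rnorm(4), imaginary = rnorm(4))
      theta <- runif(1, 0, 2 * pi)
      c_amp <- rnorm(1)
      base <- evaluate_sar(vops, x)
      expect_equal(evaluate_sar(vops, exp(1i * theta) * x), base,
                   tolerance = 1e-10)
      expect_equal(evaluate_sar(vops, c_amp * x), c_amp^2 * base,
                   tolerance = 1e-10)
    }
  })
})

test_that("vop_set enforces Hermiticity and positive semidefiniteness", {
  # harmless asymmetry is symmetrized away
  Q <- random_hermitian_psd(3, seed = 7)
  Qa <- Q
  Qa[1, 2] <- Qa[1, 2] + 1e-12 * max(abs(Q))
  v <- vop_set(list(Qa))
  expect_lt(max(abs(v$matrices[[1]] - Conj(t(v$matrices[[1]])))), 1e-15)

  # gross asymmetry and indefiniteness are rejected
  Qbad <- Q
  Qbad[1, 2] <- Qbad[1, 2] + 0.5 * max(abs(Q))
  expect_error(vop_set(list(Qbad)), class = "ptxsar_not_hermitian")
  expect_error(vop_set(list(-diag(2) + 0i)), class = "ptxsar_not_psd")
  expect_error(vop_set(list()), class = "ptxsar_bad_input")
  expect_error(vop_set(list(diag(2) + 0i, diag(3) + 0i)),
               class = "ptxsar_bad_input")
})
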