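test_that("partial-fraction coefficients follow the eigenvalue-gap products", {
  expect_equal(theta_coefficients(c(-1, -3)), c(1 / 2, -1 / 2))
  expect_equal(theta_coefficients(-2.5), 1) # empty product
  lams <- c(-0.3, -1.7, -4.2, -9)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(theta_coefficients(lams)[perm], theta_coefficients(lams[perm]))
  expect_error(theta_coefficients(c(-1, -1 + 1e-12)), "repeated")
})

test_that("cofactor columns build the adjugate of lambda*I - A", {
  A <- matrix(c(1.2, -0.7, 3.1, 0.4), 2L, 2L, byrow = TRUE)
  # lam = 0: adjugate of -A is [[-d, b], [c, -a]]
  expect_equal(cofactor_columns(A, 0),
               matrix(c(-0.4, -0.7, 3.1, -1.2), 2L, 2L, byrow = TRUE))
  set.seed(3)
  B <- matrix(rnorm(25), 5L, 5L)
  lam <- 2.3 # not an eigenvalue
  M <- lam * diag(5L) - B
  expect_equal(cofactor_columns(B, lam) / det(M), solve(M), tolerance = 1e-10)
  expect_equal(cofactor_columns(B, lam, selector = 4L),
               adjugate_oracle(M)[4L, , drop = FALSE], tolerance = 1e-8)
})

test_that("the spectral solution matches decoupled modes and the initial condition", {
  A <- diag(c(-1, -2))
  ts <- c(0, 0.5, 1, 2)
  y <- spectral_solution(A, c(1, 1), ts)
  expect_equal(y, cbind(exp(-ts), exp(-2 * ts)), tolerance = 1e-12,
               ignore_attr = TRUE)
  set.seed(8)
  B <- random_metzler(6L)
  e0 <- stats::runif(6L)
  y0 <- spectral_solution(B, e0, 0, selector = c(2L, 5L))
  expect_equal(as.numeric(y0), e0[c(2L, 5L)], tolerance = 1e-10)
})

test_that("spectral solution equals the matrix-exponential oracle on random Metzler matrices", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(3:8, 1L)
    A <- random_metzler(n)
    e0 <- stats::runif(n)
    ts <- c(0, 0.3, 1, 4)
    y <- spectral_solution(A, e0, ts)
    expect_false(attr(y, "fallback"))
    expect_lt(max(abs(y - expm_oracle(A, e0, ts))), 1e-8)
  }
})

test_that("the single-nonzero-entry shortcut equals the general spectral path", {
  set.seed(23)
  A <- random_metzler(6L)
  e0 <- numeric(6L)
  e0[3L] <- 2.5
  ts <- c(0.2, 1.1)
  direct <- spectral_solution(A, e0, ts)
  # force the general path with a second, zero-weight support point
  eps_e0 <- e0
  eps_e0[1L] <- 1e-300
  general <- spectral_solution(A, eps_e0, ts)
  expect_equal(direct, general, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("repeated eigenvalues trigger the matrix-exponential fallback", {
  A <- matrix(c(-1, 0, 1, -1), 2L, 2L) # Jordan block, defective
  y <- spectral_solution(A, c(1, 0), c(0, 1, 2))
  expect_true(attr(y, "fallback"))
  expect_equal(y, expm_oracle(A, c(1, 0), c(0, 1, 2)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("large dense adjugates fall back to the regularized det*inverse path", {
  set.seed(29)
  A <- random_metzler(15L)
  lam <- eigen(A, only.values = TRUE)$values
  lam <- Re(lam[which.max(Re(lam))])
  adj <- cofactor_columns(A, lam) # singular shift: +/- eps averaging
  M <- lam * diag(15L) - A
  # defining identity, at the looser tolerance of the regularized path
  expect_lt(max(abs(adj %*% M)), 1e-6 * max(abs(adj)))
  # off the spectrum the exact det*inv route is used
  expect_equal(cofactor_columns(A, 1.5), adjugate_oracle(1.5 * diag(15L) - A),
               tolerance = 1e-8)
})

test_that("Usmani inverse and adjugate match dense linear algebra", {
  expect_equal(tridiagonal_inverse(diag(3L)), diag(3L), ignore_attr = TRUE)
  expect_equal(tridiagonal_adjugate(diag(3L)), diag(3L), ignore_attr = TRUE)
  T2 <- matrix(c(2, 1, 1, 2), 2L, 2L)
  expect_equal(tridiagonal_inverse(T2),
               matrix(c(2, -1, -1, 2), 2L, 2L) / 3, ignore_attr = TRUE)
  S <- matrix(c(1, 1, 1, 1), 2L, 2L) # singular
  expect_equal(tridiagonal_adjugate(S),
               matrix(c(1, -1, -1, 1), 2L, 2L), ignore_attr = TRUE)
  expect_error(tridiagonal_inverse(S), "singular")
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:12, 1L)
    T <- random_tridiagonal(n)
    expect_lt(max(abs(tridiagonal_inverse(T) - solve(T))), 1e-10)
    expect_lt(max(abs(tridiagonal_adjugate(T) %*% T - det(T) * diag(n))),
              1e-10 * max(1, abs(det(T))))
    expect_equal(attr(tridiagonal_adjugate(T), "det"), det(T),
                 tolerance = 1e-10)
  }
})

test_that("Usmani handles vanishing off-diagonals", {
  T <- diag(c(2, 3, 4))
  T[1L, 2L] <- 0.5 # other couplings zero
  expect_equal(tridiagonal_inverse(T), solve(T), ignore_attr = TRUE)
})

test_that("chain rate matrices have real simple spectra and Usmani-consistent shifts", {
  set.seed(37)
  kf <- stats::runif(7)
  kb <- stats::runif(7)
  kd <- stats::runif(8)
  A <- linear_structure(chain_network(kf, kb, k_d = kd, k_s = 0.1))$A
  lams <- eigen(A, only.values = TRUE)$values
  expect_lt(max(abs(Im(lams))), 1e-9)
  expect_true(cmexact:::eigen_simple(Re(lams)))
  for (zeta in c(0.7, -0.2, 2.5)) {
    T <- zeta * diag(8L) - A
    expect_lt(max(abs(tridiagonal_adjugate(T) - adjugate_oracle(T))),
              1e-10 * max(abs(adjugate_oracle(T))))
  }
})

test_that("relaxation time is six slow time constants", {
  expect_equal(relaxation_time(diag(c(0, -0.5, -2))), 12)
  expect_equal(relaxation_time(matrix(-3, 1L, 1L)), 2)
  set.seed(43)
  A <- random_metzler(5L)
  expect_equal(relaxation_time(2 * A), relaxation_time(A) / 2)
  expect_error(relaxation_time(matrix(0, 2L, 2L)), "zero")
})
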