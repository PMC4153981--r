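# Shared fixtures and independent oracles for the test suite.

# the printed 10-state generator of the autoactivation case study (x 1/100)
autoactivation_generator_printed <- function() {
  matrix(c(
    -76, 10, 0, 0, 0, 0, 0, 0, 0, 0,
    30, -93, 0, 0, 0, 30, 0, 0, 0, 0,
    0, 0, -39, 0, 0, 0, 0, 0, 0, 0,
    26, 40, 0, -48, 0, 0, 10, 0, 0, 0,
    20, 0, 39, 0, -26, 0, 0, 0, 0, 0,
    0, 30, 0, 0, 0, -90, 0, 0, 0, 0,
    0, 13, 0, 15, 0, 60, -50, 0, 0, 0,
    0, 0, 0, 13, 0, 0, 40, -20, 0, 0,
    0, 0, 0, 20, 26, 0, 0, 0, -13, 0,
    0, 0, 0, 0, 0, 0, 0, 20, 13, 0), 10, 10, byrow = TRUE) / 100
}

# random Metzler matrix with strictly negative column excess (a proper rate
# matrix plus degradation), almost surely simple spectrum
random_metzler <- function(n) {
  A <- matrix(stats::runif(n * n), n, n)
  diag(A) <- 0
  diag(A) <- -colSums(A) - stats::runif(n, 0.1, 1)
  A
}

# well-conditioned random tridiagonal matrix (diagonally dominant)
random_tridiagonal <- function(n) {
  T <- diag(stats::runif(n, 2, 4) * sample(c(-1, 1), n, replace = TRUE))
  if (n > 1L) {
    up <- stats::runif(n - 1L, -1, 1)
    lo <- stats::runif(n - 1L, -1, 1)
    T[cbind(seq_len(n - 1L), seq(2L, n))] <- up
    T[cbind(seq(2L, n), seq_len(n - 1L))] <- lo
  }
  T
}

# dense matrix-exponential propagation (independent of the spectral path)
expm_oracle <- function(A, e0, times) {
  t(vapply(times, function(t)
    as.numeric(Matrix::expm(Matrix::Matrix(A * t)) %*% e0),
    numeric(length(e0))))
}

# dense adjugate oracle via det * inverse (valid off the spectrum only)
adjugate_oracle <- function(M) det(M) * solve(M)

# long-time stiff ODE integration of dc/dt = A c + b (deSolve oracle)
ode_longtime <- function(A, c0, t_end, b = NULL) {
  if (is.null(b)) b <- numeric(nrow(A))
  out <- suppressWarnings(deSolve::ode(
    y = c0, times = c(0, t_end),
    func = function(t, y, p) list(as.numeric(A %*% y) + b),
    parms = NULL, method = "bdf",
    jacfunc = function(t, y, p) A, jactype = "fullusr",
    rtol = 1e-10, atol = 1e-12, maxsteps = 1e6))
  as.numeric(out[2L, -1L])
}

# brute-force CME reference distributions for a small monomolecular network
cme_reference <- function(net, xi, times, cap = NULL) {
  ss <- enumerate_states(net, xi, cap = cap)
  gen <- build_generator(net, ss)
  solve_cme(gen, as.integer(xi), times, method = "expm")
}
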