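test_that("product-Poisson pmf matches closed forms and sums to one", {
  expect_equal(poisson_pmf(0L, 0), 1)
  expect_equal(poisson_pmf(1L, 1), exp(-1))
  expect_equal(poisson_pmf(c(-1L, 0L) , c(0.5, 0.5)), 0) # off support
  sup <- as.matrix(expand.grid(0:60, 0:60))
  expect_equal(sum(poisson_pmf(sup, c(1.3, 0.7))), 1, tolerance = 1e-12)
})

test_that("multinomial pmf matches the binomial case and brute-force enumeration", {
  expect_equal(multinomial_pmf(1L, 1L, 0.3), 0.3)
  expect_equal(multinomial_pmf(0L, 1L, 0.3), 0.7)
  expect_equal(multinomial_pmf(c(2L, 2L), 3L, c(0.2, 0.5)), 0) # |s| > xi
  sup <- cmexact:::simplex_states(2L, 3L)
  expect_equal(sum(multinomial_pmf(sup, 3L, c(0.2, 0.5))), 1, tolerance = 1e-14)
  # cross-check each atom against stats::dmultinom with the remainder category
  for (i in seq_len(nrow(sup)))
    expect_equal(multinomial_pmf(sup[i, ], 3L, c(0.2, 0.5)),
                 stats::dmultinom(c(sup[i, ], 3L - sum(sup[i, ])),
                                  prob = c(0.2, 0.5, 0.3)))
  expect_error(multinomial_pmf(c(1L, 0L), 2L, c(0.8, 0.4)), "<= 1")
})

test_that("lattice convolution has delta identity, commutes, and adds Poisson rates", {
  p <- poisson_dist(c(0.8, 1.4))
  d0 <- delta_dist(c(0L, 0L))
  expect_equal(tv_distance(convolve_dist(p, d0), p), 0)
  p2 <- poisson_dist(c(0.5, 0.2))
  ab <- convolve_dist(p, p2)
  ba <- convolve_dist(p2, p)
  expect_equal(tv_distance(ab, ba), 0)
  expect_lt(tv_distance(ab, poisson_dist(c(1.3, 1.6))), 1e-10)
})

test_that("q-vectors start at the unit vector, stay substochastic, and reach equilibrium", {
  set.seed(7)
  kf <- stats::runif(3, 0.3, 1)
  kb <- stats::runif(3, 0.3, 1)
  net <- chain_network(kf, kb)
  A <- linear_structure(net)$A
  q0 <- q_parameters(A, 2L, 0)
  expect_equal(as.numeric(q0), c(0, 1, 0, 0))
  ts <- seq(0, 30, length.out = 12)
  for (j in 1:4) {
    q <- q_parameters(A, j, ts)
    expect_true(all(q >= 0 & q <= 1 + 1e-9))
    expect_true(all(rowSums(q) <= 1 + 1e-9))
  }
  # long-time limit is the conservative equilibrium with unit total,
  # independently confirmed by stiff ODE integration
  qi <- q_parameters(A, 1L, Inf)
  expect_equal(as.numeric(qi), chain_equilibrium(kf, kb, 1), tolerance = 1e-9)
  e1 <- c(1, 0, 0, 0)
  expect_equal(as.numeric(qi), ode_longtime(A, e1, 400), tolerance = 1e-7)
})

test_that("nu is zero without synthesis and relaxes to -A^-1 b with it", {
  net <- chain_network(0.6, 0.4)
  ls <- linear_structure(net)
  expect_equal(as.numeric(nu_parameters(ls$A, ls$b, c(0, 1, 10))),
               rep(0, 6))
  open <- chain_network(0.6, 0.4, k_d = c(0.2, 0.3), k_s = c(0.5, 0.1))
  lo <- linear_structure(open)
  expect_equal(as.numeric(nu_parameters(lo$A, lo$b, 0)), c(0, 0))
  nubar <- unname(-solve(lo$A, lo$b))
  expect_equal(as.numeric(nu_parameters(lo$A, lo$b, 500)), nubar,
               tolerance = 1e-10)
  expect_equal(as.numeric(nu_parameters(lo$A, lo$b, Inf)), nubar)
  # singular A with synthesis has no steady state
  expect_error(nu_parameters(ls$A, c(1, 0), 1), "singular")
})

test_that("the convolution solution matches the direct CME solve on closed chains", {
  net <- chain_network(c(0.7, 0.3), c(0.2, 0.5))
  xi <- c(3L, 1L, 1L)
  tf <- relaxation_time(linear_structure(net))
  times <- seq(0, tf, length.out = 5L)
  ref <- cme_reference(net, xi, times)
  for (i in seq_along(times)) {
    full <- full_distribution(net, xi, times[i])
    expect_lt(tv_distance(full, ref[[i]]), 1e-8)
  }
  expect_equal(dist_prob(full_distribution(net, xi, 0), xi), 1)
})

test_that("the convolution solution matches the CME on open chains and rings", {
  open <- chain_network(0.5, 0.35, k_d = c(0.4, 0.3), k_s = c(0.45, 0.15))
  xi <- c(2L, 1L)
  times <- c(0.4, 2.5, 8)
  ref <- cme_reference(open, xi, times, cap = 16L)
  for (i in seq_along(times))
    expect_lt(tv_distance(full_distribution(open, xi, times[i]), ref[[i]]),
              1e-8)
  ring <- ring_network(c(0.6, 0.2, 0.9), c(0.3, 0.8, 0.4))
  xir <- c(2L, 2L, 0L)
  timesr <- c(0.7, 3, 12)
  refr <- cme_reference(ring, xir, timesr)
  for (i in seq_along(timesr))
    expect_lt(tv_distance(full_distribution(ring, xir, timesr[i]), refr[[i]]),
              1e-8)
})

test_that("restricted-parameter marginals equal summed full distributions", {
  net <- chain_network(c(0.8, 0.25), c(0.15, 0.6), k_d = 0.1, k_s = 0.2)
  xi <- c(2L, 0L, 3L)
  for (t in c(0.5, 2, 7)) {
    full <- full_distribution(net, xi, t)
    for (sub in list(1L, 3L, c(1L, 3L), c(1L, 2L, 3L))) {
      mg <- marginal_distribution(net, xi, sub, t)
      expect_lt(tv_distance(project_dist(full, sub), mg), 1e-9)
    }
  }
})

test_that("chain equilibrium matches the closed form, the null space, and log-space scaling", {
  expect_equal(chain_equilibrium(0.4, 0.4, 10), c(5, 5))
  kf1 <- 0.7; kb1 <- 0.2
  expect_equal(chain_equilibrium(kf1, kb1, 3)[1L], 3 * kb1 / (kf1 + kb1))
  set.seed(13)
  kf <- stats::runif(5, 0.1, 1); kb <- stats::runif(5, 0.1, 1)
  ce <- chain_equilibrium(kf, kb, 9)
  A <- linear_structure(chain_network(kf, kb))$A
  expect_lt(max(abs(A %*% ce)), 1e-10)
  expect_equal(sum(ce), 9)
  # rate products spanning hundreds of orders of magnitude stay finite
  n <- 120L
  huge <- chain_equilibrium(rep(10, n - 1L), rep(0.1, n - 1L), 1)
  expect_true(all(is.finite(huge)) && abs(sum(huge) - 1) < 1e-12)
})

test_that("ring equilibrium is uniform under symmetry and solves A cbar = 0", {
  expect_equal(ring_equilibrium(rep(0.3, 4), rep(0.3, 4), 8), rep(2, 4))
  set.seed(17)
  kf <- stats::runif(4, 0.2, 1); kb <- stats::runif(4, 0.2, 1)
  re <- ring_equilibrium(kf, kb, 6)
  A <- linear_structure(ring_network(kf, kb))$A
  expect_lt(max(abs(A %*% re)), 1e-10)
  expect_equal(sum(re), 6)
  expect_equal(re, ode_longtime(A, c(6, 0, 0, 0), 300), tolerance = 1e-7)
})
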