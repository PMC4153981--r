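test_that("closed-network enumeration counts every combination within the conserved total", {
  cs <- autoactivation()
  expect_equal(nrow(enumerate_states(cs$network, c(2, 1))$states), 10L)
  expect_equal(nrow(enumerate_states(cs$network, c(10, 10))$states), 231L)
  # no molecules and no synthesis: the empty state only
  expect_equal(nrow(enumerate_states(cs$network, c(0, 0))$states), 1L)
})

test_that("open networks require a cap and enumerate the reachable box", {
  net <- chain_network(0.4, 0.2, k_d = 0.1, k_s = 0.3)
  expect_error(enumerate_states(net, c(1, 1)), "cap")
  ss <- enumerate_states(net, c(1, 1), cap = 3)
  expect_equal(nrow(ss$states), 16L) # all of [0,3]^2 is reachable
  expect_true(all(ss$states >= 0L & ss$states <= 3L))
})

test_that("an explicit state ordering must be a permutation of the enumerated set", {
  cs <- autoactivation()
  ss <- enumerate_states(cs$network, c(2, 1), ordering = cs$ordering)
  expect_identical(unname(ss$states), unname(cs$ordering))
  bad <- cs$ordering
  bad[1L, ] <- c(9L, 9L)
  expect_error(enumerate_states(cs$network, c(2, 1), ordering = bad),
               "permutation")
})

test_that("the autoactivation generator reproduces the published matrix", {
  cs <- autoactivation()
  ss <- enumerate_states(cs$network, cs$initial, ordering = cs$ordering)
  gen <- build_generator(cs$network, ss)
  expect_lt(max(abs(as.matrix(gen$matrix) - autoactivation_generator_printed())),
            1e-12)
})

test_that("generator columns balance outflow on complete closed spaces", {
  cs <- autoactivation()
  ss <- enumerate_states(cs$network, c(3, 2))
  gen <- build_generator(cs$network, ss)
  A <- as.matrix(gen$matrix)
  expect_lt(max(abs(colSums(A))), 1e-14)
  expect_true(all(A[row(A) != col(A)] >= 0))
  # diagonal is exactly minus the total outflow propensity of each state
  outflow <- apply(ss$states, 1L, function(s) sum(propensities(cs$network, s)))
  expect_equal(diag(A), -outflow)
})

test_that("a truncated birth-death generator matches hand enumeration", {
  net <- reaction_network("S", list(
    reaction(NULL, c(S = 1), 0.7, "zeroth"),
    reaction(c(S = 1), NULL, 0.4, "unary")))
  ss <- enumerate_states(net, 0L, cap = 2L)
  gen <- build_generator(net, ss)
  # states 0,1,2; birth 0.7 up, death 0.4*s down; birth out of state 2 leaks
  byhand <- matrix(c(
    -0.7, 0.4, 0,
    0.7, -1.1, 0.8,
    0, 0.7, -1.5), 3L, 3L, byrow = TRUE)
  expect_equal(as.matrix(gen$matrix), byhand, tolerance = 1e-15)
})

test_that("solve_cme returns p0 at t = 0 and absorbs into extinction", {
  cs <- autoactivation()
  ss <- enumerate_states(cs$network, cs$initial, ordering = cs$ordering)
  gen <- build_generator(cs$network, ss)
  sol <- solve_cme(gen, cs$initial, c(0, 200))
  expect_equal(dist_prob(sol[[1L]], c(2L, 1L)), 1)
  expect_gt(dist_prob(sol[[2L]], c(0L, 0L)), 1 - 1e-8) # (0,0) absorbs
  expect_equal(total_mass(sol[[2L]]), 1, tolerance = 1e-9)
})

test_that("spectral and matrix-exponential CME solves agree on a random generator", {
  set.seed(11)
  net <- reaction_network(c("X", "Y"), list(
    reaction(c(X = 1), c(Y = 1), 0.8, "unary"),
    reaction(c(Y = 1), c(X = 1), 0.3, "unary"),
    reaction(c(X = 1), NULL, 0.2, "unary")))
  ss <- enumerate_states(net, c(2, 0)) # 6 states
  gen <- build_generator(net, ss)
  p0 <- c(2L, 0L)
  times <- c(0, 0.4, 1.3, 5)
  sp <- solve_cme(gen, p0, times, method = "spectral")
  ex <- solve_cme(gen, p0, times, method = "expm")
  for (i in seq_along(times)) {
    d <- max(abs(dist_prob(sp[[i]], ss$states) - dist_prob(ex[[i]], ss$states)))
    expect_lt(d, 1e-8)
  }
})

test_that("stored mass is conserved on closed spaces and non-increasing on truncated ones", {
  cs <- autoactivation()
  ss <- enumerate_states(cs$network, cs$initial)
  gen <- build_generator(cs$network, ss)
  masses <- vapply(solve_cme(gen, cs$initial, c(0, 1, 3, 10)), total_mass,
                   numeric(1))
  expect_equal(masses, rep(1, 4), tolerance = 1e-9)
  open <- chain_network(0.4, 0.2, k_d = 0.05, k_s = 0.9)
  ssb <- enumerate_states(open, c(1, 1), cap = 6)
  genb <- build_generator(open, ssb)
  mb <- vapply(solve_cme(genb, c(1L, 1L), c(0, 1, 4, 12), method = "expm"),
               total_mass, numeric(1))
  expect_true(all(diff(mb) < 1e-12))
  # leaked mass is accounted, not lost
  leaks <- vapply(solve_cme(genb, c(1L, 1L), c(4), method = "expm"),
                  function(d) total_mass(d) + d$truncation_mass, numeric(1))
  expect_equal(leaks, 1, tolerance = 1e-9)
})

test_that("lumping reproduces the published selection-matrix pattern", {
  cs <- autoactivation()
  ss <- enumerate_states(cs$network, cs$initial, ordering = cs$ordering)
  sel <- selection_matrix(ss, "A")
  expect_identical(sel$counts[, 1L], 0:3)
  printed_C <- matrix(c(
    0, 0, 1, 0, 1, 0, 0, 0, 1, 1,
    1, 0, 0, 1, 0, 0, 0, 1, 0, 0,
    0, 1, 0, 0, 0, 0, 1, 0, 0, 0,
    0, 0, 0, 0, 0, 1, 0, 0, 0, 0), 4L, 10L, byrow = TRUE)
  expect_identical(unname(sel$matrix), matrix(as.integer(printed_C), 4L, 10L))
  # lumping preserves mass and equals multiplication by C
  gen <- build_generator(cs$network, ss)
  p <- solve_cme(gen, cs$initial, 0.8)[[1L]]
  lum <- lump_probabilities(ss, p, "A")
  expect_equal(total_mass(lum), total_mass(p))
  expect_equal(dist_prob(lum, matrix(0:3, ncol = 1L)),
               as.numeric(sel$matrix %*% p$mass))
  # point mass projects to a point mass
  expect_equal(dist_prob(lump_probabilities(ss, delta_dist(c(2L, 1L)), 2L), 1L), 1)
})
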