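#' Product-Poisson probability mass function
#'
#' `P(s, nu) = exp(-|nu|) prod_k nu_k^{s_k} / s_k!` - independent Poisson
#' counts per species, evaluated in log space. Negative counts have zero
#' probability.
#'
#' @param s integer count vector, or a matrix of count vectors (rows).
#' @param nu nonnegative Poisson parameter vector.
#' @return probability (vector if `s` is a matrix).
#' @export
poisson_pmf <- function(s, nu) {
  if (any(nu < 0)) stop("'nu' must be nonnegative")
  if (is.vector(s)) s <- matrix(s, nrow = 1L)
  if (ncol(s) != length(nu)) stop("dimension mismatch between 's' and 'nu'")
  apply(s, 1L, function(row) {
    if (any(row < 0)) return(0)
    exp(sum(stats::dpois(row, nu, log = TRUE)))
  })
}

#' Multinomial probability mass function with explicit failure category
#'
#' `M(s, xi, q)` distributes `xi` indistinguishable molecules over the
#' categories of `q` plus an implicit remainder category of probability
#' `1 - |q|`; zero whenever `|s| > xi`. Evaluated in log space.
#'
#' @param s integer count vector, or matrix of count vectors (rows).
#' @param xi nonnegative integer number of trials.
#' @param q category probabilities, `q >= 0`, `|q| <= 1`.
#' @param tol slack allowed on `|q| <= 1` before rejection.
#' @return probability (vector if `s` is a matrix).
#' @export
multinomial_pmf <- function(s, xi, q, tol = 1e-9) {
  if (any(q < -tol)) stop("'q' must be nonnegative")
  q <- pmax(q, 0)
  if (sum(q) > 1 + tol) stop("'q' must satisfy |q| <= 1")
  rest <- max(1 - sum(q), 0)
  if (xi < 0 || xi != round(xi)) stop("'xi' must be a nonnegative integer")
  if (is.vector(s)) s <- matrix(s, nrow = 1L)
  if (ncol(s) != length(q)) stop("dimension mismatch between 's' and 'q'")
  apply(s, 1L, function(row) {
    tot <- sum(row)
    if (any(row < 0) || tot > xi) return(0)
    if (any(row > 0 & q == 0)) return(0)
    if (xi - tot > 0 && rest == 0) return(0)
    lp <- lgamma(xi + 1) - lgamma(xi - tot + 1) - sum(lgamma(row + 1))
    lp <- lp + if (xi - tot > 0) (xi - tot) * log(rest) else 0
    pos <- row > 0
    lp <- lp + sum(row[pos] * log(q[pos]))
    exp(lp)
  })
}

#' Truncated product-Poisson lattice distribution
#'
#' Support is the smallest box capturing per-axis cumulative mass at least
#' `1 - tol`; the remainder is reported as truncation mass, never
#' renormalized.
#'
#' @param nu nonnegative parameter vector.
#' @param tol per-axis truncation tolerance.
#' @param species optional dimension names.
#' @return a [lattice_dist()].
#' @export
poisson_dist <- function(nu, tol = 1e-12, species = NULL) {
  n <- length(nu)
  caps <- vapply(nu, function(v) stats::qpois(1 - tol, v), numeric(1))
  sup <- as.matrix(expand.grid(lapply(caps, function(cp) 0:cp)))
  dimnames(sup) <- NULL
  mass <- poisson_pmf(sup, nu)
  lattice_dist(sup, mass, truncation_mass = max(0, 1 - sum(mass)),
               species = species)
}

#' Multinomial lattice distribution
#'
#' Full (untruncated) support `{s >= 0 : |s| <= xi}`.
#'
#' @param xi nonnegative integer number of trials.
#' @param q category probabilities (see [multinomial_pmf()]).
#' @param species optional dimension names.
#' @return a [lattice_dist()].
#' @export
multinomial_dist <- function(xi, q, species = NULL) {
  n <- length(q)
  sup <- simplex_states(n, xi)
  mass <- multinomial_pmf(sup, xi, q)
  lattice_dist(sup, mass, species = species)
}

#' Multinomial parameter vectors q^j(t)
#'
#' Solves `dq/dt = A q`, `q(0) = e_j` (the j-th unit vector) through the
#' spectral closed form; these are the per-species category probabilities of
#' the Multinomial factors in the exact monomolecular CME solution. Columns
#' of the stacked q-vectors are substochastic for all `t >= 0`. Rounding-level
#' negatives are clipped to zero; anything below `-1e-12` raises an error.
#'
#' @param A rate matrix of a monomolecular network (or a
#'   `linear_structure`).
#' @param j source-species index.
#' @param times nonnegative time points (may include `Inf` when `A` is the
#'   singular matrix of a conservative chain/ring, where the limit is the
#'   shared equilibrium direction).
#' @param subset optional indices: return only these entries (the marginal
#'   selection q-tilde).
#' @return matrix with `length(times)` rows.
#' @export
q_parameters <- function(A, j, times, subset = NULL) {
  if (inherits(A, "linear_structure")) A <- A$A
  n <- nrow(A)
  if (j < 1L || j > n) stop("'j' out of range")
  e0 <- numeric(n)
  e0[j] <- 1
  finite <- is.finite(times)
  out <- matrix(NA_real_, length(times),
                if (is.null(subset)) n else length(subset))
  if (any(finite)) {
    y <- spectral_solution(A, e0, times[finite], selector = subset)
    out[finite, ] <- clip_negatives(y)
  }
  if (any(!finite)) {
    qi <- equilibrium_direction(A)
    if (!is.null(subset)) qi <- qi[subset]
    out[!finite, ] <- matrix(qi, sum(!finite), length(qi), byrow = TRUE)
  }
  out
}

equilibrium_direction <- function(A, zero_tol = 1e-10) {
  # unit-total equilibrium of dq/dt = A q for a singular, conservative A
  lams <- eigen(A, only.values = TRUE)$values
  if (min(abs(lams)) > zero_tol * max(abs(lams)))
    stop("'A' is nonsingular; q(t) decays to zero, there is no ",
         "nontrivial infinite-time limit")
  ns <- null_vector(A)
  ns / sum(ns)
}

null_vector <- function(A) {
  sv <- svd(A)
  v <- sv$v[, ncol(A)]
  if (sum(v) < 0) v <- -v
  pmax(v, 0)
}

clip_negatives <- function(y, tol = 1e-12) {
  if (min(y) < -tol)
    stop("parameter vector went negative beyond rounding tolerance (",
         format(min(y)), "); the spectrum may be ill-conditioned")
  pmax(y, 0)
}

#' Poisson parameter vector nu(t)
#'
#' Solves `dnu/dt = A nu + b`, `nu(0) = 0`: the Poisson intensity
#' contributed by synthesis reactions. With `b = 0` the result is
#' identically zero; otherwise `A` must be invertible and
#' `nu(t) = nubar - exp(At) nubar` with `nubar = -A^{-1} b`.
#'
#' @param A rate matrix (or a `linear_structure`, in which case `b` is taken
#'   from it).
#' @param b synthesis rate vector.
#' @param times nonnegative time points (`Inf` allowed: the limit is
#'   `nubar`).
#' @param subset optional indices to keep (the marginal selection nu-tilde).
#' @return matrix with `length(times)` rows.
#' @export
nu_parameters <- function(A, b = NULL, times, subset = NULL) {
  if (inherits(A, "linear_structure")) {
    if (is.null(b)) b <- A$b
    A <- A$A
  }
  n <- nrow(A)
  if (length(b) != n) stop("'b' must have length nrow(A)")
  keep <- if (is.null(subset)) seq_len(n) else subset
  if (all(b == 0)) return(matrix(0, length(times), length(keep)))
  nubar <- tryCatch(-solve(A, b), error = function(e)
    stop("'A' is singular but b != 0: nu(t) has no steady state ",
         "(unbounded synthesis)", call. = FALSE))
  out <- matrix(NA_real_, length(times), length(keep))
  finite <- is.finite(times)
  if (any(finite)) {
    y <- spectral_solution(A, nubar, times[finite], selector = subset)
    out[finite, ] <- clip_negatives(
      matrix(nubar[keep], sum(finite), length(keep), byrow = TRUE) - y)
  }
  if (any(!finite))
    out[!finite, ] <- matrix(nubar[keep], sum(!finite), length(keep), byrow = TRUE)
  out
}

#' Exact CME solution of a monomolecular network
#'
#' The probability distribution at time `t` of a monomolecular network
#' started from the deterministic state `xi` is the convolution of one
#' product-Poisson distribution with parameter `nu(t)` and one Multinomial
#' per initially populated species, with `xi_j` trials and category
#' probabilities `q^j(t)`. Species with `xi_j = 0` contribute a point mass
#' at zero and are skipped.
#'
#' @param net a [mono_network()].
#' @param xi nonnegative integer initial counts (deterministic initial
#'   state).
#' @param t single nonnegative time (`Inf` allowed for conservative
#'   networks).
#' @param tol Poisson truncation tolerance (see [poisson_dist()]).
#' @return a [lattice_dist()] over all species.
#' @export
full_distribution <- function(net, xi, t, tol = 1e-12) {
  stopifnot(inherits(net, "mono_network"))
  mono_convolution(net, xi, t, subset = NULL, tol = tol)
}

#' Exact marginal distribution for selected species
#'
#' Same convolution as [full_distribution()] but with every parameter vector
#' restricted to the species of interest: the marginal over a subset is
#' available directly, without ever forming (or summing) the full
#' distribution. For a chain queried on its first and last species this
#' reduces an n-species problem to two dimensions.
#'
#' @param net a [mono_network()].
#' @param xi nonnegative integer initial counts.
#' @param subset species names or indices of interest.
#' @param t single nonnegative time (`Inf` allowed for conservative
#'   networks).
#' @param tol Poisson truncation tolerance.
#' @return a [lattice_dist()] over the selected species.
#' @export
marginal_distribution <- function(net, xi, subset, t, tol = 1e-12) {
  stopifnot(inherits(net, "mono_network"))
  if (is.character(subset)) subset <- match(subset, net$species)
  if (length(subset) == 0L || anyNA(subset))
    stop("'subset' must select at least one declared species")
  mono_convolution(net, xi, t, subset = subset, tol = tol)
}

mono_convolution <- function(net, xi, t, subset, tol) {
  if (length(t) != 1L || t < 0) stop("'t' must be a single nonnegative time")
  n <- length(net$species)
  xi <- as.integer(xi)
  if (length(xi) != n || any(xi < 0)) stop("'xi' must be nonnegative counts")
  ls <- linear_structure(net)
  keep <- if (is.null(subset)) seq_len(n) else subset
  sp <- net$species[keep]
  nu <- nu_parameters(ls$A, ls$b, t, subset = subset)[1L, ]
  out <- if (any(nu > 0)) poisson_dist(nu, tol = tol, species = sp) else
    delta_dist(integer(length(keep)), species = sp)
  for (j in which(xi > 0)) {
    qj <- q_parameters(ls$A, j, t, subset = subset)[1L, ]
    out <- convolve_dist(out, multinomial_dist(xi[j], qj, species = sp))
  }
  colnames(out$support) <- sp
  out
}

#' Equilibrium of a conservative unbranched chain
#'
#' For the pure conversion chain (no synthesis, no degradation) the rate
#' matrix is singular and the equilibrium is set by the conserved total:
#' species `k` receives a share proportional to
#' `prod(k_b[k..n-1]) * prod(k_f[1..k-1])`. Products are accumulated as sums
#' of logs so long chains cannot overflow.
#'
#' @param k_f forward rates, length `n - 1`, all positive.
#' @param k_b backward rates, length `n - 1`, all positive.
#' @param total conserved initial total count.
#' @return equilibrium vector of length `n` summing to `total`.
#' @export
chain_equilibrium <- function(k_f, k_b, total) {
  n <- length(k_f) + 1L
  if (length(k_b) != n - 1L) stop("'k_b' must have length n - 1")
  if (any(k_f <= 0) || any(k_b <= 0)) stop("rates must be positive")
  lf <- cumsum(c(0, log(k_f)))            # lf[k] = sum log k_f[1..k-1]
  lb <- rev(cumsum(c(0, rev(log(k_b)))))  # lb[k] = sum log k_b[k..n-1]
  lw <- lb + lf
  lw <- lw - max(lw)
  w <- exp(lw)
  total * w / sum(w)
}

#' Equilibrium of a conservative monomolecular ring
#'
#' For the ring topology the equilibrium share of species `k` is the `k`-th
#' row sum of the inverse of the linear-rate map `G`, normalized over all
#' entries and scaled by the conserved total. When `G` is singular (the
#' detailed-balance case, e.g. a fully symmetric ring) the unique
#' equilibrium direction is recovered from the null space of the rate
#' matrix instead.
#'
#' @param k_f forward rates, length `n` (`k_f[n]` drives `S_n -> S_1`).
#' @param k_b backward rates, length `n` (`k_b[n]` drives `S_1 -> S_n`).
#' @param total conserved initial total count.
#' @return equilibrium vector of length `n` summing to `total`.
#' @export
ring_equilibrium <- function(k_f, k_b, total) {
  n <- length(k_f)
  if (length(k_b) != n) stop("'k_f' and 'k_b' must both have length n")
  G <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    G[i, i] <- k_f[i]
    G[i, i + 1L] <- -k_b[i]
  }
  G[n, n] <- k_f[n]
  G[n, 1L] <- -k_b[n]
  build_ring_A <- function(k_f, k_b) {
    nxt <- c(seq(2L, n), 1L)
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      A[nxt[i], i] <- A[nxt[i], i] + k_f[i]
      A[i, nxt[i]] <- A[i, nxt[i]] + k_b[i]
    }
    diag(A) <- diag(A) - colSums(A)
    A
  }
  # row sums of G^-1 are one linear solve; equilibrate rows first since
  # calcium-binding rates can span tens of orders of magnitude
  d <- apply(abs(G), 1L, max)
  if (any(d == 0)) stop("ring has a species with no outgoing conversions")
  x <- tryCatch(solve(G / d, 1 / d), error = function(e) NULL)
  if (is.null(x)) {
    # G is singular exactly when the ring satisfies detailed balance (e.g.
    # all forward rates equal to their backward partners); the equilibrium
    # is still unique per conservation class and sits in the null space of
    # the rate matrix
    A <- build_ring_A(k_f, k_b)
    if (Matrix::rankMatrix(A)[1L] < n - 1L)
      stop("degenerate ring: equilibrium direction is not unique")
    x <- null_vector(A)
  }
  total * x / sum(x)
}
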