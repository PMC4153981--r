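#' Enumerate the finite state space of a reaction network
#'
#' For a closed network (one where no reaction increases the total molecule
#' count) the state space implied by an initial condition is every
#' nonnegative integer vector whose total does not exceed the initial total
#' - including combinations that are never dynamically visited, which then
#' simply carry zero probability. Open networks (with synthesis) have an
#' infinite state space and must be truncated with `cap`; the space is then
#' the reachability closure of the initial state inside the rectangle
#' `[0, cap]^n`.
#'
#' @param net a [reaction_network()] or [mono_network()].
#' @param initial nonnegative integer vector of initial counts, in species
#'   order.
#' @param cap per-species truncation bound for open networks (scalar or
#'   length n); ignored for closed networks.
#' @param ordering optional explicit state ordering: a w-by-n integer matrix
#'   containing exactly the enumerated set. The default order is graded
#'   lexicographic (by total count, then lexicographic).
#' @return an object of class `state_space`: list with `states` (w-by-n
#'   integer matrix), `species`, and a key-based `index`.
#' @export
enumerate_states <- function(net, initial, cap = NULL, ordering = NULL) {
  if (inherits(net, "mono_network")) net <- as_reaction_network(net)
  n <- length(net$species)
  initial <- as.integer(initial)
  if (length(initial) != n || any(initial < 0))
    stop("'initial' must be nonnegative counts for every species")
  N <- stoichiometric_matrix(net)
  closed <- all(colSums(N) <= 0)
  states <- if (closed) {
    simplex_states(n, sum(initial))
  } else {
    if (is.null(cap))
      stop("open network (some reaction increases the total count): ",
           "a truncation 'cap' is required, the state space is infinite")
    cap <- rep_len(as.integer(cap), n)
    if (any(cap < initial)) stop("'cap' must be at least the initial counts")
    reachable_states(N, net, initial, cap)
  }
  states <- states[grlex_order(states), , drop = FALSE]
  if (!is.null(ordering)) {
    ordering <- as.matrix(ordering)
    storage.mode(ordering) <- "integer"
    if (!setequal(state_keys(ordering), state_keys(states)) ||
        nrow(ordering) != nrow(states))
      stop("'ordering' must be a permutation of the enumerated state set")
    states <- ordering
  }
  colnames(states) <- net$species
  state_space(states, net$species)
}

state_space <- function(states, species) {
  keys <- state_keys(states)
  structure(list(states = states, species = species,
                 index = stats::setNames(seq_len(nrow(states)), keys)),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space> w =", nrow(x$states), "states,",
      length(x$species), "species\n")
  invisible(x)
}

simplex_states <- function(n, total) {
  # all nonnegative integer n-vectors with sum <= total
  grid <- as.matrix(expand.grid(rep(list(0:total), n)))[, n:1, drop = FALSE]
  grid <- grid[rowSums(grid) <= total, , drop = FALSE]
  storage.mode(grid) <- "integer"
  dimnames(grid) <- NULL
  grid
}

reachable_states <- function(N, net, initial, cap) {
  key <- function(m) state_keys(m)
  seen <- new.env(parent = emptyenv())
  frontier <- matrix(initial, nrow = 1L)
  assign(key(frontier), TRUE, envir = seen)
  acc <- list(frontier)
  while (nrow(frontier) > 0L) {
    nxt <- list()
    for (i in seq_len(nrow(frontier))) {
      s <- frontier[i, ]
      a <- propensities(net, s)
      for (k in which(a > 0)) {
        t <- s + N[, k]
        if (any(t < 0) || any(t > cap)) next
        kk <- paste(t, collapse = ",")
        if (!exists(kk, envir = seen, inherits = FALSE)) {
          assign(kk, TRUE, envir = seen)
          nxt <- c(nxt, list(t))
        }
      }
    }
    frontier <- if (length(nxt)) do.call(rbind, nxt) else
      matrix(integer(0), 0L, length(initial))
    if (nrow(frontier)) acc <- c(acc, list(frontier))
  }
  out <- do.call(rbind, acc)
  storage.mode(out) <- "integer"
  out
}

grlex_order <- function(states) {
  do.call(order, c(list(rowSums(states)), as.data.frame(states)))
}

#' Assemble the CME generator matrix
#'
#' The w-by-w rate matrix of the continuous-time Markov chain over the state
#' space: column `i` holds, off the diagonal, the propensity of each
#' reaction taking state `i` to its target state, and on the diagonal minus
#' the total outflow propensity of state `i`. Transitions whose target falls
#' outside the space contribute only to the diagonal; the resulting
#' probability leak is tracked downstream as truncation mass.
#'
#' @param net a [reaction_network()] or [mono_network()].
#' @param ss a [enumerate_states()] state space for `net`.
#' @return an object of class `cme_generator`: list with the sparse `matrix`
#'   (a `dgCMatrix`) and the `state_space`.
#' @export
build_generator <- function(net, ss) {
  if (inherits(net, "mono_network")) net <- as_reaction_network(net)
  stopifnot(inherits(ss, "state_space"))
  states <- ss$states
  w <- nrow(states)
  N <- stoichiometric_matrix(net)
  ii <- list(); jj <- list(); xx <- list()
  diag_acc <- numeric(w)
  for (k in seq_along(net$reactions)) {
    r <- net$reactions[[k]]
    a <- propensity_all(r, states, net$species)
    live <- which(a > 0)
    if (!length(live)) next
    targets <- states[live, , drop = FALSE] +
      matrix(N[, k], nrow = length(live), ncol = ncol(states), byrow = TRUE)
    idx <- unname(ss$index[state_keys(targets)])
    inside <- !is.na(idx)
    diag_acc[live] <- diag_acc[live] - a[live]
    if (any(inside)) {
      ii <- c(ii, list(idx[inside]))
      jj <- c(jj, list(live[inside]))
      xx <- c(xx, list(a[live][inside]))
    }
  }
  A <- Matrix::sparseMatrix(
    i = c(unlist(ii), seq_len(w)),
    j = c(unlist(jj), seq_len(w)),
    x = c(unlist(xx), diag_acc),
    dims = c(w, w)
  )
  structure(list(matrix = A, state_space = ss), class = "cme_generator")
}

propensity_all <- function(r, states, species) {
  k <- r$rate
  idx <- match(names(r$reactants), species)
  switch(r$kind,
    zeroth = rep(k, nrow(states)),
    unary = k * states[, idx],
    bimolecular = k * states[, idx[1L]] * states[, idx[2L]],
    dimerization = k * states[, idx] * (states[, idx] - 1) / 2
  )
}

#' @export
print.cme_generator <- function(x, ...) {
  cat("<cme_generator> w =", nrow(x$matrix), "states,",
      length(x$matrix@x), "stored entries\n")
  invisible(x)
}

#' Solve the chemical master equation
#'
#' Propagates an initial distribution through `dp/dt = A p`. When the
#' generator's eigenvalues are simple (within tolerance) the closed-form
#' spectral solution of [spectral_solution()] is used; otherwise, or on
#' request, a scaling-and-squaring matrix exponential. Mass leaving a
#' truncated space accumulates in each output's `truncation_mass`.
#'
#' @param gen a [build_generator()] object.
#' @param p0 initial distribution: a [lattice_dist()] supported on the state
#'   space, or an integer state vector (taken as a point mass).
#' @param times nonnegative, nondecreasing time points.
#' @param method `"auto"` (spectral when eigenvalues are simple and the
#'   adjugate path is exact — tridiagonal or `w <= 12` — else matrix
#'   exponential), `"spectral"` (forced), or `"expm"`.
#' @param leak_tol validation tolerance on the total mass of `p0`.
#' @return list of [lattice_dist()], one per time point; attribute
#'   `"fallback"` records whether the matrix-exponential path was used.
#' @export
solve_cme <- function(gen, p0, times, method = c("auto", "spectral", "expm"),
                      leak_tol = 1e-9) {
  method <- match.arg(method)
  stopifnot(inherits(gen, "cme_generator"))
  ss <- gen$state_space
  w <- nrow(ss$states)
  if (!inherits(p0, "lattice_dist")) p0 <- delta_dist(p0, species = ss$species)
  idx <- unname(ss$index[state_keys(p0$support)])
  if (anyNA(idx)) stop("'p0' has support outside the generator's state space")
  if (abs(sum(p0$mass) + p0$truncation_mass - 1) > leak_tol)
    stop("'p0' is not a probability distribution (mass does not sum to 1)")
  if (is.unsorted(times)) stop("'times' must be nondecreasing")
  v0 <- numeric(w)
  v0[idx] <- p0$mass
  A <- as.matrix(gen$matrix)
  # auto takes the spectral route only where the adjugate evaluation is
  # exact (Usmani, or dense cofactor expansion up to n = 12); larger dense
  # generators are served faster and more accurately by the exponential
  use_spectral <- method == "spectral" ||
    (method == "auto" && (w <= 12L || is_tridiagonal(A)) &&
       eigen_simple(clean_spectrum(eigen(A, only.values = TRUE)$values, A)))
  if (use_spectral) {
    Y <- spectral_solution(A, v0, times)
    fb <- attr(Y, "fallback")
  } else {
    Y <- expm_solution(A, v0, times)
    fb <- TRUE
  }
  out <- lapply(seq_along(times), function(i) {
    m <- pmax(Y[i, ], 0)
    lattice_dist(ss$states, m,
                 truncation_mass = p0$truncation_mass + max(0, 1 - p0$truncation_mass - sum(m)),
                 species = ss$species)
  })
  attr(out, "fallback") <- isTRUE(fb)
  out
}

#' Lump full-state probabilities into per-species marginal counts
#'
#' Sums the probability of all states agreeing on a subset of species; the
#' matrix form of this operation is multiplication by a 0/1 selection
#' matrix with one row per projected count vector.
#'
#' @param ss the [enumerate_states()] state space of `p`.
#' @param p a [lattice_dist()] over the full states (e.g. one element of
#'   [solve_cme()] output).
#' @param subset species names or indices to keep.
#' @return a [lattice_dist()] over the selected species' counts, with the
#'   same total mass as `p`.
#' @export
lump_probabilities <- function(ss, p, subset) {
  stopifnot(inherits(ss, "state_space"), inherits(p, "lattice_dist"))
  if (is.character(subset)) subset <- match(subset, ss$species)
  project_dist(p, subset)
}

#' Selection (lumping) matrix for a subset of species
#'
#' The 0/1 matrix whose rows pick out, for every projected count vector in
#' graded lexicographic order, the full states that agree with it on the
#' selected species.
#'
#' @param ss a [enumerate_states()] state space.
#' @param subset species names or indices.
#' @return list with the 0/1 `matrix` (rows ordered as `counts`) and the
#'   projected count vectors `counts`.
#' @export
selection_matrix <- function(ss, subset) {
  if (is.character(subset)) subset <- match(subset, ss$species)
  proj <- ss$states[, subset, drop = FALSE]
  keys <- state_keys(proj)
  uniq <- proj[!duplicated(keys), , drop = FALSE]
  uniq <- uniq[grlex_order(uniq), , drop = FALSE]
  C <- matrix(0L, nrow(uniq), nrow(ss$states))
  ukeys <- state_keys(uniq)
  C[cbind(match(keys, ukeys), seq_len(nrow(ss$states)))] <- 1L
  list(matrix = C, counts = uniq)
}
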