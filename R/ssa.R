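#' Gillespie direct-method trajectory
#'
#' Simulates one exact jump trajectory of the Markov chain underlying the
#' CME: exponential waiting times with rate equal to the total propensity,
#' reaction choice proportional to the individual propensities (two uniform
#' draws per step). Halts at `t_final` or when every propensity vanishes.
#'
#' @param net a [reaction_network()] or [mono_network()].
#' @param s0 nonnegative integer initial counts.
#' @param t_final positive simulation horizon.
#' @param seed optional integer seed (restores the caller's RNG state on
#'   exit).
#' @return an object of class `ssa_trajectory`: list with `jump_times`
#'   (strictly increasing, excludes 0), `states` (matrix of states *after*
#'   each jump; the initial state is row 0, stored as `s0`), `s0`, `seed`.
#' @export
ssa_trajectory <- function(net, s0, t_final, seed = NULL) {
  if (inherits(net, "mono_network")) net <- as_reaction_network(net)
  if (t_final <= 0) stop("'t_final' must be positive")
  s0 <- as.integer(s0)
  if (any(s0 < 0)) stop("'s0' must be nonnegative")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
  }
  eng <- ssa_engine(net)
  s <- s0
  t <- 0
  jt <- numeric(0)
  st <- list()
  a <- eng$prop(s)
  repeat {
    a0 <- sum(a)
    if (a0 <= 0) break
    t <- t + stats::rexp(1L, a0) # inversion of one uniform
    if (t >= t_final) break
    k <- pick_reaction(a, a0)
    s <- s + eng$Ncols[[k]]
    a <- eng$update(a, s, k)
    jt <- c(jt, t)
    st <- c(st, list(s))
  }
  structure(list(jump_times = jt,
                 states = if (length(st)) do.call(rbind, st) else
                   matrix(integer(0), 0L, length(s0)),
                 s0 = s0, seed = seed),
            class = "ssa_trajectory")
}

pick_reaction <- function(a, a0) {
  u <- stats::runif(1L) * a0
  cum <- cumsum(a)
  min(which(cum >= u))
}

ssa_engine <- function(net) {
  N <- stoichiometric_matrix(net)
  m <- ncol(N)
  Ncols <- lapply(seq_len(m), function(k) N[, k])
  kinds <- vapply(net$reactions, `[[`, character(1), "kind")
  rates <- vapply(net$reactions, `[[`, numeric(1), "rate")
  linear <- all(kinds %in% c("zeroth", "unary"))
  if (linear) {
    # a = w0 + W s; after reaction k the propensity change is the constant
    # column W N[, k], precomputed once
    n <- nrow(N)
    W <- matrix(0, m, n)
    for (k in seq_len(m)) {
      r <- net$reactions[[k]]
      if (r$kind == "unary")
        W[k, match(names(r$reactants), net$species)] <- rates[k]
    }
    w0 <- ifelse(kinds == "zeroth", rates, 0)
    dA <- lapply(Ncols, function(nc) as.numeric(W %*% nc))
    list(
      Ncols = Ncols,
      prop = function(s) w0 + as.numeric(W %*% s),
      update = function(a, s, k) pmax(a + dA[[k]], 0)
    )
  } else {
    prop <- function(s) {
      st <- stats::setNames(as.numeric(s), net$species)
      vapply(net$reactions, propensity, numeric(1), state = st)
    }
    list(Ncols = Ncols, prop = prop, update = function(a, s, k) prop(s))
  }
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
}

set_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Ensemble of SSA runs recorded on a time grid
#'
#' Runs the direct method `runs` times (replicate `r` is seeded with
#' `seed + r - 1`) and records the state at each grid time with a
#' left-continuous lookup, without storing full trajectories.
#'
#' @param net a [reaction_network()] or [mono_network()].
#' @param s0 initial counts.
#' @param times nonnegative, increasing grid of recording times.
#' @param runs number of replicates.
#' @param seed integer base seed.
#' @return integer array `[runs, length(times), n]` of recorded counts, with
#'   species as the third dimension's names.
#' @export
ssa_ensemble <- function(net, s0, times, runs, seed = 1L) {
  if (inherits(net, "mono_network")) net <- as_reaction_network(net)
  if (is.unsorted(times, strictly = FALSE) || any(times < 0))
    stop("'times' must be nonnegative and nondecreasing")
  s0 <- as.integer(s0)
  n <- length(s0)
  eng <- ssa_engine(net)
  nt <- length(times)
  out <- array(0L, dim = c(runs, nt, n),
               dimnames = list(NULL, NULL, net$species))
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  t_final <- max(times)
  for (rpl in seq_len(runs)) {
    set.seed(seed + rpl - 1L)
    s <- s0
    t <- 0
    a <- eng$prop(s)
    gi <- 1L # next grid index to fill
    repeat {
      a0 <- sum(a)
      tnext <- if (a0 > 0) t + stats::rexp(1L, a0) else Inf
      # grid times passed strictly before the next jump get the current
      # state (left-continuous: a grid time equal to a jump time reads the
      # pre-jump state)
      while (gi <= nt && times[gi] <= tnext) {
        out[rpl, gi, ] <- s
        gi <- gi + 1L
      }
      if (gi > nt) break
      if (!is.finite(tnext)) break # absorbed: remaining grid filled below
      t <- tnext
      k <- pick_reaction(a, a0)
      s <- s + eng$Ncols[[k]]
      a <- eng$update(a, s, k)
    }
    while (gi <= nt) { # absorbed before the end of the grid
      out[rpl, gi, ] <- s
      gi <- gi + 1L
    }
  }
  out
}

#' Empirical marginal distributions from SSA output
#'
#' Relative state frequencies over a subset of species at each grid time,
#' either from a [ssa_ensemble()] array or from a list of
#' [ssa_trajectory()] objects (looked up left-continuously).
#'
#' @param runs a `[runs, times, species]` array from [ssa_ensemble()], or a
#'   list of `ssa_trajectory` objects.
#' @param times the grid times (must match the array's second dimension).
#' @param subset species names or indices to keep (default: all).
#' @return list of [lattice_dist()], one per time, each with total mass 1.
#' @export
empirical_marginal <- function(runs, times, subset = NULL) {
  if (is.list(runs) && all(vapply(runs, inherits, logical(1), "ssa_trajectory"))) {
    n <- length(runs[[1L]]$s0)
    arr <- array(0L, dim = c(length(runs), length(times), n))
    for (r in seq_along(runs)) {
      tr <- runs[[r]]
      full <- rbind(tr$s0, tr$states)
      for (ti in seq_along(times)) {
        arr[r, ti, ] <- full[sum(tr$jump_times < times[ti]) + 1L, ]
      }
    }
    runs <- arr
  }
  if (!is.array(runs) || length(dim(runs)) != 3L)
    stop("'runs' must be an ensemble array or a list of trajectories")
  if (dim(runs)[2L] != length(times)) stop("'times' does not match the ensemble grid")
  nsp <- dim(runs)[3L]
  if (is.null(subset)) subset <- seq_len(nsp)
  if (is.character(subset)) subset <- match(subset, dimnames(runs)[[3L]])
  lapply(seq_along(times), function(ti) {
    sub <- runs[, ti, subset, drop = FALSE]
    m <- matrix(sub, nrow = dim(runs)[1L], ncol = length(subset))
    keys <- state_keys(m)
    tab <- table(keys)
    sup <- m[!duplicated(keys), , drop = FALSE]
    lattice_dist(sup, as.numeric(tab[state_keys(sup)]) / nrow(m))
  })
}

#' Error between analytical and empirical distribution sequences
#'
#' The log10 of the time-averaged L1 distance between two matched sequences
#' of distributions: `log10( (1/eta) sum_i sum_y |F_A(y, t_i) - F_S(y, t_i)| )`.
#' Identical sequences return `-Inf`, a documented floor, rather than an
#' error.
#'
#' @param analytic,empirical lists of [lattice_dist()] on matched time grids
#'   (same length eta) and lattices.
#' @return a single number (possibly `-Inf`).
#' @export
distribution_error <- function(analytic, empirical) {
  if (length(analytic) != length(empirical))
    stop("mismatched time grids: the two sequences differ in length")
  l1 <- mapply(function(p, q) 2 * tv_distance(p, q), analytic, empirical)
  m <- mean(l1)
  if (m == 0) -Inf else log10(m)
}
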