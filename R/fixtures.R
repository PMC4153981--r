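#' Protein autoactivation case study
#'
#' A two-species closed network in which a protein `P` is activated
#' autocatalytically and both forms degrade:
#' `P + A -> 2A` (k = 0.15), `2A -> P + A` (k = 0.1), `P -> 0` (k = 0.13),
#' `A -> 0` (k = 0.2), all stochastic rates in 1/s. Started from 2 molecules
#' of `P` and 1 of `A` the CME has 10 states; the case study ships the
#' published explicit state ordering for that initial condition so the
#' generator matrix can be reproduced entry for entry. The output of
#' interest is the number of active molecules, species `A`.
#'
#' @param initial initial counts `c(P, A)` (default `c(2, 1)`; the explicit
#'   ordering is only attached for the default).
#' @return an object of class `case_study`: list with `network`, `initial`,
#'   `ordering` (or `NULL`), `subset`, `label`.
#' @export
autoactivation <- function(initial = c(P = 2, A = 1)) {
  net <- reaction_network(
    species = c("P", "A"),
    reactions = list(
      reaction(c(P = 1, A = 1), c(A = 2), 0.15, "bimolecular"),
      reaction(c(A = 2), c(P = 1, A = 1), 0.10, "dimerization"),
      reaction(c(P = 1), NULL, 0.13, "unary"),
      reaction(c(A = 1), NULL, 0.20, "unary")
    )
  )
  ordering <- NULL
  if (all(initial == c(2, 1))) {
    ordering <- matrix(c(
      2L, 1L,
      1L, 2L,
      3L, 0L,
      1L, 1L,
      2L, 0L,
      0L, 3L,
      0L, 2L,
      0L, 1L,
      1L, 0L,
      0L, 0L), ncol = 2L, byrow = TRUE,
      dimnames = list(NULL, c("P", "A")))
  }
  case_study(net, initial, ordering = ordering, subset = "A",
             label = "protein autoactivation")
}

case_study <- function(network, initial, ordering = NULL, subset = NULL,
                       label = "", params = list()) {
  structure(list(network = network, initial = initial, ordering = ordering,
                 subset = subset, label = label, params = params),
            class = "case_study")
}

#' @export
print.case_study <- function(x, ...) {
  cat("<case_study>", x$label, "\n")
  print(x$network)
  cat("initial:", paste(x$initial, collapse = ", "), "\n")
  invisible(x)
}

#' Randomized (or fixed-rate) unbranched monomolecular chain
#'
#' The benchmark chain protocol: `S_1 <-> ... <-> S_n`, optionally with
#' per-species synthesis and degradation. In the randomized variant every
#' rate is drawn uniformly from `[0, 1]` and every initial count is an
#' integer drawn uniformly from `{1, ..., 10}`, reproducibly from `seed`.
#' The fixed variant uses the benchmark rate set
#' `k_f = 1.396, k_b = 0.465, k_d = 0.851, k_s = 0.398` (1/s) for every
#' species and 10 initial molecules each.
#'
#' @param n number of species (>= 2).
#' @param seed integer seed for the randomized variant.
#' @param with_synth_deg include synthesis and degradation reactions.
#' @param fixed use the fixed benchmark rate set instead of random draws.
#' @return a `case_study` whose `network` is a [mono_network()].
#' @export
random_chain <- function(n, seed = 1L, with_synth_deg = TRUE, fixed = FALSE) {
  if (n < 2L) stop("'n' must be at least 2")
  if (fixed) {
    net <- chain_network(k_f = rep(1.396, n - 1L), k_b = rep(0.465, n - 1L),
                         k_d = if (with_synth_deg) 0.851 else 0,
                         k_s = if (with_synth_deg) 0.398 else 0)
    initial <- rep(10L, n)
  } else {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
    net <- chain_network(k_f = stats::runif(n - 1L), k_b = stats::runif(n - 1L),
                         k_d = if (with_synth_deg) stats::runif(n) else 0,
                         k_s = if (with_synth_deg) stats::runif(n) else 0)
    initial <- sample(1:10, n, replace = TRUE)
  }
  case_study(net, initial, subset = c(1L, n),
             label = sprintf("%s monomolecular chain (n = %d)",
                             if (fixed) "fixed-rate" else "randomized", n))
}

#' Ryanodine-receptor calcium gating ring
#'
#' A four-state ring model of a ryanodine-receptor (RyR) calcium channel:
#' `S_1` inactive, `S_2`, `S_3` closed intermediates, `S_4` open. Calcium
#' binding steps are proportional to the (constant) number of surrounding
#' calcium ions `kappa` or its square; the base rates (1/ms) are taken from
#' the Stern RyR parameterization, with `gamma = 1e-3 / (N V)` converting
#' the deterministic constants to stochastic units for a volume `V` (default
#' one microlitre). Effective conversion rates:
#' forward `(0.06, 0.005 kappa, 35 gamma^2 kappa^2, 0.5 gamma kappa)`,
#' backward `(35 gamma^2 kappa^2, 0.5 gamma, 0.06, 0.005)`. There is no
#' synthesis or degradation of gates, so `b = 0` and the Poisson factor of
#' the exact solution is degenerate at zero. All `gates` start inactive.
#'
#' @param kappa number of calcium ions (constant during gate operation).
#' @param volume reaction volume in litres.
#' @param gates number of gates (trials of the Multinomial), default 100.
#' @return a `case_study` whose `network` is a [mono_network()] ring; the
#'   effective rate vectors are stored in `params`.
#' @export
ryr_ring <- function(kappa, volume = 1e-6, gates = 100L) {
  if (kappa <= 0) stop("'kappa' must be positive")
  if (volume <= 0) stop("'volume' must be positive")
  gamma <- 1e-3 / (AVOGADRO * volume)
  k_f <- c(0.06, 0.005 * kappa, 35 * gamma^2 * kappa^2, 0.5 * gamma * kappa)
  k_b <- c(35 * gamma^2 * kappa^2, 0.5 * gamma, 0.06, 0.005)
  net <- ring_network(k_f, k_b)
  case_study(net, initial = c(gates, 0L, 0L, 0L), subset = c(1L, 4L),
             label = sprintf("RyR gating ring (kappa = %g)", kappa),
             params = list(k_f = k_f, k_b = k_b, kappa = kappa,
                           gamma = gamma, gates = gates))
}

#' Steady-state marginal of the RyR ring over (inactive, open)
#'
#' With all gates initially inactive and no gate synthesis, the
#' infinite-time marginal over `(S_1, S_4)` collapses to a single
#' Multinomial with the gate count as trials and the equilibrium shares of
#' `S_1` and `S_4` as category probabilities (computed with the exact ring
#' equilibrium formula).
#'
#' @param cs a [ryr_ring()] case study.
#' @return a [lattice_dist()] over `(S_1, S_4)`.
#' @export
ryr_steady_marginal <- function(cs) {
  stopifnot(inherits(cs, "case_study"), !is.null(cs$params$k_f))
  q_inf <- ring_equilibrium(cs$params$k_f, cs$params$k_b, total = 1)
  multinomial_dist(cs$params$gates, q_inf[c(1L, 4L)],
                   species = c("S1", "S4"))
}
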