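#' Define a monomolecular reaction network
#'
#' A monomolecular (first-order) network is built only from conversions
#' `S_i -> S_j`, syntheses `0 -> S_i` and degradations `S_i -> 0`. All rates
#' are stochastic and in 1/time units (syntheses in molecules/time). For
#' these networks the mean dynamics are linear, `dc/dt = A c + b`, and the
#' CME has an exact Poisson/Multinomial convolution solution (see
#' [full_distribution()]).
#'
#' @param species character vector of species names (declaration order fixes
#'   all matrix orderings).
#' @param conversions data frame with columns `from`, `to` (species names or
#'   indices) and `rate`; self-conversions are rejected.
#' @param synthesis named numeric vector of synthesis rates (omitted species
#'   get 0).
#' @param degradation named numeric vector of degradation rates (omitted
#'   species get 0).
#' @return an object of class `mono_network`.
#' @examples
#' mono_network(c("S1", "S2"),
#'              conversions = data.frame(from = "S1", to = "S2", rate = 0.4),
#'              degradation = c(S2 = 0.1))
#' @export
mono_network <- function(species, conversions = NULL, synthesis = NULL,
                         degradation = NULL) {
  if (!is.character(species) || length(species) < 1L || anyDuplicated(species))
    stop("'species' must be distinct names")
  n <- length(species)
  cv <- if (is.null(conversions)) {
    data.frame(from = integer(0), to = integer(0), rate = numeric(0))
  } else {
    if (!all(c("from", "to", "rate") %in% names(conversions)))
      stop("'conversions' needs columns from, to, rate")
    data.frame(from = resolve_species(conversions$from, species),
               to = resolve_species(conversions$to, species),
               rate = as.numeric(conversions$rate))
  }
  if (any(cv$from == cv$to)) stop("self-conversions (i -> i) are not allowed")
  if (any(cv$rate < 0)) stop("conversion rates must be nonnegative")
  fill <- function(x, what) {
    out <- stats::setNames(numeric(n), species)
    if (!is.null(x)) {
      if (is.null(names(x)) || !all(names(x) %in% species))
        stop("'", what, "' must be named by declared species")
      if (any(x < 0)) stop("'", what, "' rates must be nonnegative")
      out[names(x)] <- x
    }
    out
  }
  structure(list(species = species, conversions = cv,
                 synthesis = fill(synthesis, "synthesis"),
                 degradation = fill(degradation, "degradation")),
            class = "mono_network")
}

resolve_species <- function(x, species) {
  if (is.numeric(x)) {
    if (any(x < 1 | x > length(species))) stop("species index out of range")
    return(as.integer(x))
  }
  i <- match(x, species)
  if (anyNA(i)) stop("unknown species: ", paste(x[is.na(i)], collapse = ", "))
  i
}

#' @export
print.mono_network <- function(x, ...) {
  cat("<mono_network> ", length(x$species), " species, ",
      nrow(x$conversions), " conversions\n", sep = "")
  if (nrow(x$conversions))
    for (i in seq_len(nrow(x$conversions)))
      cat(sprintf("  %s -> %s  (k = %g)\n", x$species[x$conversions$from[i]],
                  x$species[x$conversions$to[i]], x$conversions$rate[i]))
  if (any(x$synthesis > 0))
    cat("  synthesis:", paste(sprintf("%s=%g", x$species, x$synthesis)[x$synthesis > 0],
                              collapse = ", "), "\n")
  if (any(x$degradation > 0))
    cat("  degradation:", paste(sprintf("%s=%g", x$species, x$degradation)[x$degradation > 0],
                                collapse = ", "), "\n")
  invisible(x)
}

#' Convert a monomolecular network to a general reaction network
#'
#' Expands the conversion/synthesis/degradation description into explicit
#' unary and zeroth-order [reaction()] objects, in the order conversions,
#' syntheses, degradations.
#'
#' @param net a [mono_network()].
#' @return a [reaction_network()].
#' @export
as_reaction_network <- function(net) {
  stopifnot(inherits(net, "mono_network"))
  sp <- net$species
  rx <- list()
  cv <- net$conversions
  for (i in seq_len(nrow(cv)))
    rx <- c(rx, list(reaction(stats::setNames(1L, sp[cv$from[i]]),
                              stats::setNames(1L, sp[cv$to[i]]),
                              cv$rate[i], "unary")))
  for (i in which(net$synthesis > 0))
    rx <- c(rx, list(reaction(NULL, stats::setNames(1L, sp[i]),
                              net$synthesis[[i]], "zeroth")))
  for (i in which(net$degradation > 0))
    rx <- c(rx, list(reaction(stats::setNames(1L, sp[i]), NULL,
                              net$degradation[[i]], "unary")))
  if (length(rx) == 0L) stop("network has no reactions")
  reaction_network(sp, rx)
}

#' Linear (A, b) structure of a monomolecular network
#'
#' Factorizes the mean dynamics `dc/dt = A c + b` of a monomolecular network
#' as `A = N_L G` (stoichiometry of the linear reactions times the
#' linear-rate map) and `b = N_0 v_0` (synthesis stoichiometry times
#' synthesis rates). `A` is always Metzler (nonnegative off-diagonals) and
#' its column `j` sums to minus the degradation rate of species `j`.
#'
#' @param net a [mono_network()].
#' @return an object of class `linear_structure`: a list with the n-by-n
#'   matrix `A`, the length-n vector `b`, and the factors `N_L`, `G`, `N_0`,
#'   `v_0`.
#' @export
linear_structure <- function(net) {
  stopifnot(inherits(net, "mono_network"))
  n <- length(net$species)
  cv <- net$conversions
  deg <- which(net$degradation > 0)
  mL <- nrow(cv) + length(deg)
  NL <- matrix(0, n, mL)
  G <- matrix(0, mL, n)
  j <- 0L
  for (i in seq_len(nrow(cv))) {
    j <- j + 1L
    NL[cv$from[i], j] <- -1
    NL[cv$to[i], j] <- 1
    G[j, cv$from[i]] <- cv$rate[i]
  }
  for (i in deg) {
    j <- j + 1L
    NL[i, j] <- -1
    G[j, i] <- net$degradation[[i]]
  }
  syn <- which(net$synthesis > 0)
  N0 <- matrix(0, n, length(syn))
  v0 <- numeric(length(syn))
  for (k in seq_along(syn)) {
    N0[syn[k], k] <- 1
    v0[k] <- net$synthesis[[syn[k]]]
  }
  A <- if (mL > 0) NL %*% G else matrix(0, n, n)
  b <- if (length(syn)) as.numeric(N0 %*% v0) else numeric(n)
  dimnames(A) <- list(net$species, net$species)
  names(b) <- net$species
  structure(list(A = A, b = b, N_L = NL, G = G, N_0 = N0, v_0 = v0),
            class = "linear_structure")
}

#' @export
print.linear_structure <- function(x, ...) {
  cat("<linear_structure> n =", nrow(x$A), "\nA:\n")
  print(x$A)
  cat("b:", x$b, "\n")
  invisible(x)
}

#' Unbranched monomolecular chain
#'
#' Builds the chain `S_1 <-> S_2 <-> ... <-> S_n` with optional per-species
#' synthesis and degradation. With synthesis/degradation the rate matrix is
#' the tridiagonal matrix with diagonal `-(k_b{i-1} + k_f{i} + k_d{i})`;
#' without them the columns of `A` sum to zero and `A` is singular.
#'
#' @param k_f forward rates, length `n - 1`.
#' @param k_b backward rates, length `n - 1`.
#' @param k_d degradation rates, scalar or length `n` (default 0).
#' @param k_s synthesis rates, scalar or length `n` (default 0).
#' @param species optional species names (default `S1 ... Sn`).
#' @return a [mono_network()].
#' @export
chain_network <- function(k_f, k_b, k_d = 0, k_s = 0, species = NULL) {
  n <- length(k_f) + 1L
  if (length(k_b) != n - 1L) stop("'k_b' must have length n - 1")
  if (n < 2L) stop("a chain needs at least 2 species")
  k_d <- rep_len(k_d, n)
  k_s <- rep_len(k_s, n)
  if (is.null(species)) species <- paste0("S", seq_len(n))
  cv <- data.frame(
    from = c(seq_len(n - 1L), seq(2L, n)),
    to = c(seq(2L, n), seq_len(n - 1L)),
    rate = c(k_f, k_b)
  )
  cv <- cv[cv$rate > 0, , drop = FALSE]
  mono_network(species, cv,
               synthesis = stats::setNames(k_s, species),
               degradation = stats::setNames(k_d, species))
}

#' Ring of monomolecular reactions
#'
#' The chain `S_1 <-> ... <-> S_n` closed by `S_n <-> S_1`. `k_f[n]` is the
#' rate of `S_n -> S_1` and `k_b[n]` that of `S_1 -> S_n`, so the rate
#' matrix has corner entries `A[1, n] = k_f[n]` and `A[n, 1] = k_b[n]`.
#'
#' @param k_f forward rates, length `n`.
#' @param k_b backward rates, length `n`.
#' @param species optional species names.
#' @return a [mono_network()].
#' @export
ring_network <- function(k_f, k_b, species = NULL) {
  n <- length(k_f)
  if (length(k_b) != n) stop("'k_f' and 'k_b' must both have length n")
  if (n < 3L) stop("a ring needs at least 3 species")
  if (is.null(species)) species <- paste0("S", seq_len(n))
  nxt <- c(seq(2L, n), 1L)
  cv <- data.frame(
    from = c(seq_len(n), nxt),
    to = c(nxt, seq_len(n)),
    rate = c(k_f, k_b)
  )
  cv <- cv[cv$rate > 0, , drop = FALSE]
  mono_network(species, cv)
}
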