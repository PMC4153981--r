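#' Avogadro constant [molecules/mol]
#'
#' Used when converting between deterministic (concentration-based) and
#' stochastic (molecule-count) rate constants.
#' @export
AVOGADRO <- 6.02214e23

#' Define a single mass-action reaction
#'
#' A reaction is described by its reactant and product stoichiometry, a
#' stochastic rate constant and a declared kind. Four mass-action kinds are
#' supported: zeroth order (`0 -> products`), unary (`S_i -> products`),
#' bimolecular between distinct species (`S_i + S_j -> products`), and
#' dimerization (`2 S_i -> products`). The kind is declared, not inferred,
#' but is validated against the reactant stoichiometry so that unit mistakes
#' surface early.
#'
#' @param reactants named integer vector of reactant stoichiometric
#'   coefficients (may be empty or `NULL` for a zeroth-order reaction).
#' @param products named integer vector of product stoichiometric
#'   coefficients (may be empty).
#' @param rate nonnegative stochastic rate constant (propensity units).
#' @param kind one of `"zeroth"`, `"unary"`, `"bimolecular"`,
#'   `"dimerization"`.
#' @return an object of class `reaction`.
#' @examples
#' reaction(c(P = 1, A = 1), c(A = 2), 0.15, "bimolecular")
#' @export
reaction <- function(reactants = NULL, products = NULL, rate,
                     kind = c("zeroth", "unary", "bimolecular", "dimerization")) {
  kind <- match.arg(kind)
  reactants <- check_stoich(reactants, "reactants")
  products <- check_stoich(products, "products")
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stop("'rate' must be a single nonnegative number")
  tot <- sum(reactants)
  ok <- switch(kind,
    zeroth = tot == 0L,
    unary = tot == 1L,
    bimolecular = tot == 2L && length(reactants) == 2L && all(reactants == 1L),
    dimerization = tot == 2L && length(reactants) == 1L && reactants[[1L]] == 2L
  )
  if (!ok)
    stop("reaction kind '", kind, "' is inconsistent with reactant stoichiometry")
  structure(
    list(reactants = reactants, products = products, rate = rate, kind = kind),
    class = "reaction"
  )
}

check_stoich <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(stats::setNames(integer(0), character(0)))
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("'", what, "' must be a named vector (species names)")
  if (anyDuplicated(names(x)))
    stop("duplicated species in '", what, "'")
  if (any(x != round(x)) || any(x < 0)) stop("'", what, "' must be nonnegative integers")
  x <- x[x > 0]
  stats::setNames(as.integer(x), names(x))
}

#' Assemble a reaction network
#'
#' @param species character vector of species names; its order fixes the
#'   row/entry order of every state vector and matrix derived from the
#'   network.
#' @param reactions list of [reaction()] objects.
#' @return an object of class `reaction_network` with `n` species and `m`
#'   reactions.
#' @export
reaction_network <- function(species, reactions) {
  if (!is.character(species) || length(species) < 1L || anyDuplicated(species))
    stop("'species' must be distinct names, length >= 1")
  if (!is.list(reactions) || length(reactions) < 1L ||
      !all(vapply(reactions, inherits, logical(1), "reaction")))
    stop("'reactions' must be a non-empty list of reaction() objects")
  used <- unique(unlist(lapply(reactions, function(r) c(names(r$reactants), names(r$products)))))
  unknown <- setdiff(used, species)
  if (length(unknown))
    stop("species not declared in 'species': ", paste(unknown, collapse = ", "))
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", length(x$species), " species, ",
      length(x$reactions), " reactions\n", sep = "")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  for (r in x$reactions) {
    side <- function(st) if (length(st) == 0L) "0" else
      paste(ifelse(st > 1L, paste0(st, " "), ""), names(st), sep = "", collapse = " + ")
    cat(sprintf("  %s -> %s   (k = %g, %s)\n",
                side(r$reactants), side(r$products), r$rate, r$kind))
  }
  invisible(x)
}

#' Reaction propensity
#'
#' Probability per unit time that a reaction fires in a given state:
#' `k` for zeroth order, `k * s_i` for unary, `k * s_i * s_j` for
#' bimolecular with distinct reactants, and `k * s_i * (s_i - 1) / 2` for
#' dimerization.
#'
#' @param reaction a [reaction()].
#' @param state named nonnegative integer vector of molecule counts covering
#'   all reactant species.
#' @return nonnegative propensity.
#' @examples
#' r <- reaction(c(P = 1, A = 1), c(A = 2), 0.15, "bimolecular")
#' propensity(r, c(P = 2, A = 1)) # 0.3
#' @export
propensity <- function(reaction, state) {
  if (!inherits(reaction, "reaction")) stop("'reaction' must be a reaction() object")
  need <- names(reaction$reactants)
  if (length(need) && (is.null(names(state)) || !all(need %in% names(state))))
    stop("'state' must name all reactant species")
  if (any(state < 0)) stop("negative molecule counts are not a valid state")
  if (any(state != round(state))) stop("molecule counts must be integers")
  k <- reaction$rate
  switch(reaction$kind,
    zeroth = k,
    unary = k * state[[need]],
    bimolecular = k * state[[need[1L]]] * state[[need[2L]]],
    dimerization = k * state[[need]] * (state[[need]] - 1) / 2
  )
}

#' Propensity vector of all reactions in a state
#'
#' @param net a [reaction_network()].
#' @param state nonnegative integer vector of counts, in `net$species` order
#'   (names optional).
#' @return numeric vector of length `m`.
#' @export
propensities <- function(net, state) {
  state <- as_state(net, state)
  vapply(net$reactions, propensity, numeric(1), state = state)
}

as_state <- function(net, state) {
  n <- length(net$species)
  if (length(state) != n) stop("state length must equal the number of species")
  stats::setNames(as.numeric(state), net$species)
}

#' Stoichiometric matrix
#'
#' The n-by-m matrix of net molecule changes, entry `(i, k)` equal to the
#' product minus reactant coefficient of species `i` in reaction `k`.
#'
#' @param net a [reaction_network()].
#' @return integer matrix with species as row names.
#' @export
stoichiometric_matrix <- function(net) {
  n <- length(net$species)
  m <- length(net$reactions)
  N <- matrix(0L, n, m, dimnames = list(net$species, NULL))
  for (k in seq_len(m)) {
    r <- net$reactions[[k]]
    N[names(r$reactants), k] <- N[names(r$reactants), k] - r$reactants
    N[names(r$products), k] <- N[names(r$products), k] + r$products
  }
  N
}

#' Convert between deterministic and stochastic rate constants
#'
#' Deterministic (concentration, molar) rate constants relate to stochastic
#' (molecule-count propensity) constants through the reaction volume `V`
#' (litres) and the Avogadro constant `N`: zeroth order `k = N V delta`,
#' unary `k = delta`, bimolecular `k = delta / (N V)`, dimerization
#' `k = 2 delta / (N V)`.
#'
#' @param rate rate constant to convert.
#' @param kind reaction kind, as in [reaction()].
#' @param volume reaction volume in litres, positive.
#' @param to direction of conversion: `"stochastic"` takes a deterministic
#'   constant to propensity units, `"deterministic"` inverts it.
#' @return converted rate constant.
#' @examples
#' convert_rate(0.5, "unary", 1e-15) # 0.5, unchanged
#' @export
convert_rate <- function(rate, kind = c("zeroth", "unary", "bimolecular", "dimerization"),
                         volume, to = c("stochastic", "deterministic")) {
  kind <- match.arg(kind)
  to <- match.arg(to)
  if (!is.numeric(volume) || length(volume) != 1L || is.na(volume) || volume <= 0)
    stop("'volume' must be a positive number of litres")
  nv <- AVOGADRO * volume
  f <- switch(kind, zeroth = nv, unary = 1, bimolecular = 1 / nv, dimerization = 2 / nv)
  if (to == "stochastic") rate * f else rate / f
}
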