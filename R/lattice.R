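#' Probability distribution on an integer lattice
#'
#' A probability mass function over integer count vectors with an explicit,
#' truncated support. Mass known to lie outside the stored support is kept
#' in `truncation_mass` rather than renormalized away, so truncation errors
#' stay auditable through convolutions and CME solves.
#'
#' @param support integer matrix, one state per row (a vector is taken as a
#'   one-dimensional support).
#' @param mass nonnegative masses matching the rows of `support`.
#' @param truncation_mass nonnegative mass outside the support.
#' @param species optional dimension (species) names.
#' @return an object of class `lattice_dist`.
#' @export
lattice_dist <- function(support, mass, truncation_mass = 0, species = NULL) {
  if (is.vector(support)) support <- matrix(support, ncol = 1L)
  support <- as.matrix(support)
  storage.mode(support) <- "integer"
  if (nrow(support) != length(mass)) stop("'mass' must match the rows of 'support'")
  if (any(mass < -1e-12)) stop("negative probability mass")
  mass <- pmax(mass, 0)
  if (anyDuplicated(state_keys(support))) {
    agg <- rowsum(mass, state_keys(support), reorder = FALSE)
    keep <- !duplicated(state_keys(support))
    support <- support[keep, , drop = FALSE]
    mass <- as.numeric(agg[state_keys(support), 1L])
  }
  if (!is.null(species)) colnames(support) <- species
  structure(list(support = support, mass = as.numeric(mass),
                 truncation_mass = max(0, truncation_mass)),
            class = "lattice_dist")
}

state_keys <- function(m) {
  if (ncol(m) == 1L) as.character(m[, 1L]) else
    do.call(paste, c(as.data.frame(m), sep = ","))
}

#' Point mass at a single count vector
#' @param x integer count vector.
#' @param species optional names.
#' @return a [lattice_dist()].
#' @export
delta_dist <- function(x, species = NULL) {
  lattice_dist(matrix(as.integer(x), nrow = 1L), 1, species = species)
}

#' @export
print.lattice_dist <- function(x, n = 10L, ...) {
  cat("<lattice_dist> ", nrow(x$support), " support points in ",
      ncol(x$support), " dimension(s), mass ", format(sum(x$mass)),
      ", truncation ", format(x$truncation_mass), "\n", sep = "")
  o <- order(x$mass, decreasing = TRUE)
  show <- head(o, n)
  for (i in show)
    cat("  (", paste(x$support[i, ], collapse = ","), ")  ",
        format(x$mass[i]), "\n", sep = "")
  if (nrow(x$support) > n) cat("  ...\n")
  invisible(x)
}

#' Total stored mass of a lattice distribution
#' @param d a [lattice_dist()].
#' @return sum of the stored masses (excludes `truncation_mass`).
#' @export
total_mass <- function(d) sum(d$mass)

#' Total variation distance between two lattice distributions
#'
#' Half the L1 distance over the union of supports; truncation masses are
#' not compared.
#' @param p,q [lattice_dist()] objects of equal dimension.
#' @return nonnegative number.
#' @export
tv_distance <- function(p, q) {
  if (ncol(p$support) != ncol(q$support)) stop("dimension mismatch")
  kp <- state_keys(p$support)
  kq <- state_keys(q$support)
  keys <- union(kp, kq)
  a <- stats::setNames(numeric(length(keys)), keys)
  a[kp] <- p$mass
  b <- stats::setNames(numeric(length(keys)), keys)
  b[kq] <- q$mass
  sum(abs(a - b)) / 2
}

#' Probability of selected count vectors
#' @param d a [lattice_dist()].
#' @param states integer matrix of query states (rows) or a single vector.
#' @return numeric vector of probabilities (0 off support).
#' @export
dist_prob <- function(d, states) {
  if (is.vector(states)) states <- matrix(as.integer(states), nrow = 1L)
  i <- match(state_keys(states), state_keys(d$support))
  out <- numeric(nrow(states))
  out[!is.na(i)] <- d$mass[i[!is.na(i)]]
  out
}

#' Mean count vector of a lattice distribution
#' @param d a [lattice_dist()].
#' @return numeric vector of per-dimension means (of the stored mass).
#' @export
dist_mean <- function(d) as.numeric(crossprod(d$support, d$mass))

dense_box <- function(d) {
  lo <- apply(d$support, 2L, min)
  hi <- apply(d$support, 2L, max)
  dims <- hi - lo + 1L
  arr <- numeric(prod(dims))
  stride <- cumprod(c(1L, dims[-length(dims)]))
  idx <- as.integer((d$support - rep(lo, each = nrow(d$support))) %*% stride) + 1L
  arr[idx] <- arr[idx] + d$mass
  list(arr = arr, lo = lo, dims = dims, stride = stride)
}

#' Convolution of two lattice distributions
#'
#' Discrete convolution `sum_z p1(z) p2(s - z)` over the (truncated)
#' supports; truncation masses add. This is the composition rule behind the
#' Poisson/Multinomial CME solution: the distribution of a sum of
#' independent lattice variables.
#'
#' @param p1,p2 [lattice_dist()] objects of equal dimension.
#' @return a [lattice_dist()].
#' @export
convolve_dist <- function(p1, p2) {
  if (ncol(p1$support) != ncol(p2$support)) stop("dimension mismatch")
  if (nrow(p1$support) > nrow(p2$support)) return(convolve_dist(p2, p1))
  b2 <- dense_box(p2)
  lo1 <- apply(p1$support, 2L, min)
  lo <- lo1 + b2$lo
  hi <- apply(p1$support, 2L, max) + b2$lo + b2$dims - 1L
  dims <- hi - lo + 1L
  stride <- cumprod(c(1L, dims[-length(dims)]))
  out <- numeric(prod(dims))
  # positions of p2's box cells inside the output box, before shifting
  base <- cell_offsets(b2$dims, stride) + as.integer((b2$lo - lo) %*% stride) + 1L
  nz <- which(b2$arr > 0)
  for (i in seq_len(nrow(p1$support))) {
    sh <- as.integer(p1$support[i, ] %*% stride)
    out[base[nz] + sh] <- out[base[nz] + sh] + p1$mass[i] * b2$arr[nz]
  }
  keep <- which(out > 0)
  sup <- offsets_to_states(keep - 1L, dims, lo)
  colnames(sup) <- colnames(p1$support)
  lattice_dist(sup, out[keep],
               truncation_mass = p1$truncation_mass + p2$truncation_mass)
}

cell_offsets <- function(dims, stride) {
  # flat offsets (0-based) of every cell of a box with given dims, in the
  # coordinate system defined by 'stride'
  idx <- 0L
  for (d in seq_along(dims))
    idx <- outer(idx, (seq_len(dims[d]) - 1L) * stride[d], "+")
  as.integer(idx)
}

offsets_to_states <- function(off, dims, lo) {
  n <- length(dims)
  m <- matrix(0L, length(off), n)
  for (d in seq_len(n)) {
    m[, d] <- off %% dims[d] + lo[d]
    off <- off %/% dims[d]
  }
  m
}

#' Project a lattice distribution onto a subset of dimensions
#'
#' Sums the mass over all states agreeing on the selected dimensions; the
#' lattice analogue of multiplying by a 0/1 selection matrix.
#'
#' @param d a [lattice_dist()].
#' @param subset indices (or names) of the dimensions to keep.
#' @return a [lattice_dist()] over the selected dimensions with the same
#'   total mass.
#' @export
project_dist <- function(d, subset) {
  if (is.character(subset)) subset <- match(subset, colnames(d$support))
  if (length(subset) == 0L || anyNA(subset) ||
      any(subset < 1L | subset > ncol(d$support)))
    stop("'subset' must select valid dimensions")
  sup <- d$support[, subset, drop = FALSE]
  lattice_dist(sup, d$mass, truncation_mass = d$truncation_mass)
}
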