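#' Partial-fraction coefficients of a simple spectrum
#'
#' For pairwise distinct eigenvalues, the coefficient attached to the
#' `l`-th spectral term is `1 / prod_{k != l} (lambda_l - lambda_k)`. For a
#' single eigenvalue the empty product gives 1.
#'
#' @param eigenvalues numeric or complex vector of eigenvalues.
#' @param tol relative gap (fraction of the spectral radius) below which two
#'   eigenvalues are treated as repeated.
#' @return vector of coefficients, same length and type as `eigenvalues`.
#' @export
theta_coefficients <- function(eigenvalues, tol = 1e-8) {
  n <- length(eigenvalues)
  if (n == 0L) stop("need at least one eigenvalue")
  if (!eigen_simple(eigenvalues, tol))
    stop("repeated (or numerically coincident) eigenvalues: ",
         "partial-fraction coefficients are undefined", call. = FALSE)
  vapply(seq_len(n), function(l) {
    1 / prod(eigenvalues[l] - eigenvalues[-l])
  }, if (is.complex(eigenvalues)) complex(1) else numeric(1))
}

eigen_simple <- function(lams, tol = 1e-8) {
  n <- length(lams)
  if (n < 2L) return(TRUE)
  scale <- max(abs(lams), 1e-300)
  d <- abs(outer(lams, lams, "-"))
  min(d[upper.tri(d)]) > tol * scale
}

is_tridiagonal <- function(A) {
  n <- nrow(A)
  if (n != ncol(A)) return(FALSE)
  if (n <= 2L) return(TRUE)
  all(A[abs(row(A) - col(A)) > 1L] == 0)
}

#' Adjugate of a square matrix
#'
#' The transpose of the cofactor matrix, satisfying
#' `adj(M) %*% M = det(M) * I` including at singular `M`. Tridiagonal input
#' is dispatched to the O(n^2) Usmani recursion; dense input uses cofactor
#' expansion (determinants of minors) up to `n = 12` and `det * inverse`
#' with a two-point regularized shift beyond that.
#'
#' @param M square numeric or complex matrix.
#' @return the adjugate matrix.
#' @export
adjugate <- function(M) {
  n <- nrow(M)
  if (n != ncol(M)) stop("'M' must be square")
  if (n == 1L) return(matrix(1 + 0 * M[1L, 1L], 1L, 1L))
  if (!is.complex(M) && is_tridiagonal(M)) return(tridiagonal_adjugate(M))
  if (n <= 12L) return(adjugate_cofactor(M))
  adjugate_detinv(M)
}

adjugate_cofactor <- function(M) {
  n <- nrow(M)
  adj <- M * 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    # adj[j, i] = cofactor m_ij of M
    adj[j, i] <- (-1)^(i + j) * det_any(M[-i, -j, drop = FALSE])
  }
  adj
}

det_any <- function(M) {
  if (nrow(M) == 0L) return(1)
  if (is.complex(M)) det_complex(M) else det(M)
}

det_complex <- function(M) {
  # complex LU with partial pivoting (base det() is real-only)
  n <- nrow(M)
  d <- 1 + 0i
  for (k in seq_len(n)) {
    p <- which.max(Mod(M[k:n, k])) + k - 1L
    if (Mod(M[p, k]) == 0) return(0 + 0i)
    if (p != k) {
      M[c(k, p), ] <- M[c(p, k), ]
      d <- -d
    }
    d <- d * M[k, k]
    if (k < n) {
      rows <- (k + 1L):n
      M[rows, ] <- M[rows, ] - outer(M[rows, k] / M[k, k], M[k, ])
    }
  }
  d
}

adjugate_detinv <- function(M) {
  scale <- max(abs(M), 1)
  dt <- det_any(M)
  if (abs(dt) > (1e-10 * scale)^nrow(M) * 1e10 && kappa_ok(M)) {
    return(dt * solve(M))
  }
  # near-singular: the adjugate is a polynomial in a diagonal shift, so
  # averaging the two O(eps) evaluations at +/- eps cancels the linear term
  eps <- scale * 1e-5
  I <- diag(nrow(M))
  a1 <- det_any(M + eps * I) * solve(M + eps * I)
  a2 <- det_any(M - eps * I) * solve(M - eps * I)
  (a1 + a2) / 2
}

kappa_ok <- function(M) {
  k <- tryCatch(kappa(M, exact = FALSE), error = function(e) Inf)
  is.finite(k) && k < 1e12
}

#' Selected rows of the adjugate of `lambda I - A`
#'
#' Builds the cofactor-column matrix of the spectral solution: the selector
#' applied to the adjugate of `lambda * I - A`. At an eigenvalue `lambda`
#' this matrix is proportional to the spectral projector, which is why the
#' closed-form solution of `dy/dt = A y` can be written as a sum of
#' `exp(lambda_l t)` terms weighted by these matrices.
#'
#' @param A square matrix.
#' @param lam scalar shift (typically an eigenvalue of `A`).
#' @param selector `NULL` for all rows, an index vector of rows, or a 0/1
#'   selection matrix with `n` columns.
#' @return matrix with `length(selector)` (or `n`) rows and `n` columns.
#' @export
cofactor_columns <- function(A, lam, selector = NULL) {
  n <- nrow(A)
  M <- diag(n) * lam - A
  adj <- adjugate(M)
  attr(adj, "det") <- NULL
  apply_selector(adj, selector)
}

apply_selector <- function(x, selector) {
  if (is.null(selector)) return(x)
  if (is.matrix(selector)) {
    if (ncol(selector) != nrow(x)) stop("selector has wrong number of columns")
    return(selector %*% x)
  }
  x[selector, , drop = FALSE]
}

#' Closed-form solution of a linear ODE via its spectrum
#'
#' Solves `dy/dt = A y`, `y(0) = e0`, returning `C y(t)` on a time grid as
#' the spectral sum `sum_l theta_l exp(lambda_l t) M(lambda_l) e0`, where
#' `M(lambda)` are selected rows of the adjugate of `lambda I - A` (see
#' [cofactor_columns()]) and `theta_l` are the partial-fraction coefficients
#' of the simple spectrum ([theta_coefficients()]). When `e0` has a single
#' nonzero entry only the matching adjugate column is used. If the computed
#' eigenvalues are not simple within tolerance the function falls back to a
#' scaling-and-squaring matrix exponential and flags it in the
#' `"fallback"` attribute.
#'
#' @param A square real matrix.
#' @param e0 initial condition vector.
#' @param times nonnegative time points.
#' @param selector rows of interest (see [cofactor_columns()]); `NULL`
#'   keeps all.
#' @param tol eigenvalue-simplicity tolerance (relative gap).
#' @return numeric matrix, `length(times)` rows; attribute `"fallback"` is
#'   `TRUE` when the matrix-exponential path was used.
#' @export
spectral_solution <- function(A, e0, times, selector = NULL, tol = 1e-8) {
  n <- nrow(A)
  if (length(e0) != n) stop("'e0' must have length nrow(A)")
  eg <- eigen(A, only.values = TRUE)$values
  lams <- clean_spectrum(eg, A)
  if (!eigen_simple(lams, tol)) {
    y <- expm_solution(A, e0, times, selector)
    attr(y, "fallback") <- TRUE
    return(y)
  }
  th <- theta_coefficients(lams, tol)
  nz <- which(e0 != 0)
  cols <- vapply(seq_along(lams), function(l) {
    M <- cofactor_columns(A, lams[l], selector)
    if (length(nz) == 1L) {
      th[l] * M[, nz] * e0[nz]          # single-column shortcut
    } else {
      th[l] * as.vector(M %*% e0)
    }
  }, rep(if (is.complex(lams)) complex(1) else numeric(1),
         if (is.null(selector)) n else
           if (is.matrix(selector)) nrow(selector) else length(selector)))
  cols <- matrix(cols, ncol = length(lams))
  y <- exp(outer(times, lams)) %*% t(cols)
  if (is.complex(y)) {
    if (max(abs(Im(y))) > 1e-6 * max(1, abs(Re(y))))
      warning("non-negligible imaginary parts in spectral solution")
    y <- Re(y)
  }
  if (any(times == 0)) # the t = 0 value is the data, not a spectral sum
    y[times == 0, ] <- rep(apply_selector(cbind(e0), selector)[, 1L],
                           each = sum(times == 0))
  attr(y, "fallback") <- FALSE
  y
}

clean_spectrum <- function(lams, A) {
  # tridiagonal Metzler matrices are similar to Hermitian ones, so their
  # spectrum is provably real: discard rounding-level imaginary parts
  if (is.complex(lams)) {
    scale <- max(abs(lams), 1e-300)
    real_proved <- is_tridiagonal(A) && all(A[row(A) != col(A)] >= 0)
    if (max(abs(Im(lams))) < 1e-9 * scale || real_proved) lams <- Re(lams)
  }
  lams
}

expm_solution <- function(A, e0, times, selector = NULL) {
  out <- lapply(times, function(t) {
    v <- as.numeric(Matrix::expm(Matrix::Matrix(A * t)) %*% e0)
    apply_selector(matrix(v, ncol = 1L), selector)[, 1L]
  })
  do.call(rbind, out)
}

#' Inverse of a tridiagonal matrix by the Usmani recursion
#'
#' Computes all entries of the inverse from the two three-term recursions
#' `theta_i = T[i,i] theta_{i-1} - T[i-1,i] T[i,i-1] theta_{i-2}` (leading
#' principal minors, so `theta_n = det(T)`) and the mirrored `phi`
#' recursion, in O(n^2) total.
#'
#' @param T square tridiagonal matrix.
#' @param tol relative tolerance on `det(T)` below which the matrix is
#'   declared singular.
#' @return the inverse matrix, with `det(T)` in attribute `"det"`.
#' @export
tridiagonal_inverse <- function(T, tol = 1e-12) {
  r <- usmani_recursions(T)
  scale <- max(abs(T), 1e-300)^nrow(T)
  if (!is.finite(r$theta[nrow(T) + 1L]) ||
      abs(r$theta[nrow(T) + 1L]) <= tol * scale)
    stop("matrix is singular to working precision (theta_n ~ 0)")
  adj <- usmani_entries(T, r)
  out <- adj / r$theta[nrow(T) + 1L]
  attr(out, "det") <- r$theta[nrow(T) + 1L]
  out
}

#' Adjugate of a tridiagonal matrix by the Usmani recursion
#'
#' Same recursions as [tridiagonal_inverse()] but without the division by
#' `det(T)`, so singular matrices are permitted. This is the workhorse for
#' evaluating the cofactor matrices `M(lambda)` of the spectral solution at
#' eigenvalues, where `lambda I - A` is singular by construction.
#'
#' @param T square tridiagonal matrix.
#' @return the adjugate matrix, with `det(T)` in attribute `"det"`.
#' @export
tridiagonal_adjugate <- function(T) {
  r <- usmani_recursions(T)
  adj <- usmani_entries(T, r)
  attr(adj, "det") <- r$theta[nrow(T) + 1L]
  adj
}

usmani_recursions <- function(T) {
  n <- nrow(T)
  if (n != ncol(T)) stop("'T' must be square")
  if (!is_tridiagonal(T)) stop("'T' must be tridiagonal")
  dg <- diag(T)
  up <- if (n > 1L) T[cbind(seq_len(n - 1L), seq(2L, n))] else numeric(0)
  lo <- if (n > 1L) T[cbind(seq(2L, n), seq_len(n - 1L))] else numeric(0)
  theta <- numeric(n + 1L)  # theta[i + 1] = theta_i, theta_0 = 1
  theta[1L] <- 1
  theta[2L] <- dg[1L]
  if (n > 1L) for (i in seq(2L, n))
    theta[i + 1L] <- dg[i] * theta[i] - up[i - 1L] * lo[i - 1L] * theta[i - 1L]
  phi <- numeric(n + 2L)    # phi[i] = phi_i, phi_{n+1} = 1
  phi[n + 1L] <- 1
  phi[n] <- dg[n]
  if (n > 1L) for (i in seq(n - 1L, 1L))
    phi[i] <- dg[i] * phi[i + 1L] - up[i] * lo[i] * phi[i + 2L]
  list(theta = theta, phi = phi, up = up, lo = lo)
}

usmani_entries <- function(T, r) {
  n <- nrow(T)
  adj <- matrix(0, n, n)
  # prefix products are safe only when no off-diagonal vanishes
  fast <- all(r$up != 0) && all(r$lo != 0)
  cup <- if (fast) cumprod(c(1, r$up)) else NULL
  clo <- if (fast) cumprod(c(1, r$lo)) else NULL
  pup <- function(i, j) if (fast) cup[j] / cup[i] else prod(r$up[seq(i, j - 1L)])
  plo <- function(i, j) if (fast) clo[i] / clo[j] else prod(r$lo[seq(j, i - 1L)])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- if (i < j) {
      (-1)^(i + j) * r$theta[i] * r$phi[j + 1L] * pup(i, j)
    } else if (i == j) {
      r$theta[i] * r$phi[i + 1L]
    } else {
      (-1)^(i + j) * r$theta[j] * r$phi[i + 1L] * plo(i, j)
    }
  }
  adj
}

#' Relaxation time of a linear system
#'
#' The horizon `6 / |lambda_max|`, where `lambda_max` is the nonzero
#' eigenvalue of `A` closest to zero: after about six times the slowest
#' relevant time constant the transient distributions have equilibrated.
#'
#' @param A square matrix (or a `linear_structure`).
#' @param zero_tol relative magnitude below which an eigenvalue counts as
#'   zero.
#' @return positive time.
#' @export
relaxation_time <- function(A, zero_tol = 1e-10) {
  if (inherits(A, "linear_structure")) A <- A$A
  lams <- eigen(A, only.values = TRUE)$values
  mags <- sort(abs(lams))
  scale <- max(mags, 1e-300)
  # conservative systems (zero column sums) carry one structural zero
  # eigenvalue whose computed magnitude can exceed zero_tol on badly scaled
  # matrices: drop exactly one
  conservative <- max(abs(colSums(A))) <= 1e-12 * max(abs(A))
  if (conservative) mags <- mags[-1L]
  mags <- mags[mags > zero_tol * scale]
  if (!length(mags)) stop("all eigenvalues are zero; no relaxation time")
  6 / min(mags)
}
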