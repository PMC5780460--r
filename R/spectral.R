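# Spectral primitives: fixed-convention eigendecomposition, polynomials of a
# matrix, the brute-force walk-weight oracle, and the upper-triangle
# matrix-correlation quality metric.

#' Eigendecomposition with fixed ordering and sign conventions
#'
#' Computes the eigendecomposition of a symmetric matrix with the conventions
#' used throughout the package: eigenvalues sorted in decreasing order, and
#' each eigenvector's sign flipped so that its largest-magnitude entry is
#' positive (ties broken by lowest index). Mapped matrices are invariant to
#' eigenvector signs, but the rotation and weight matrices are not, so a fixed
#' convention makes all outputs reproducible.
#'
#' @param X a symmetric numeric matrix.
#' @param warn_degenerate emit a warning when two consecutive eigenvalues are
#'   closer than \code{1e-10 * max(abs(values))} (near-degenerate spectrum;
#'   the pairing used downstream is then arbitrary within the cluster).
#' @return A list with components \code{values} (decreasing eigenvalues),
#'   \code{vectors} (orthonormal columns, column \code{i} paired with
#'   \code{values[i]}) and \code{n}.
#' @examples
#' es <- eigen_system(diag(3))
#' es$values
#' @export
eigen_system <- function(X, warn_degenerate = TRUE) {
  X <- check_square_symmetric(X, what = "X")
  e <- eigen(X, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  vals <- e$values
  if (warn_degenerate && length(vals) > 1L) {
    tol <- 1e-10 * max(abs(vals), .Machine$double.xmin)
    if (any(abs(diff(vals)) <= tol)) {
      warning("near-degenerate eigenvalues: pairing within the cluster is by sorted position")
    }
  }
  list(values = vals, vectors = V, n = nrow(X))
}

#' Evaluate a polynomial of a symmetric matrix
#'
#' Computes \eqn{\Omega = f(S) = a_0 S^0 + a_1 S + \dots + a_k S^k} by matrix
#' Horner recursion. For a symmetric \code{S} this equals
#' \eqn{V f(\Lambda) V^\top} where \eqn{S = V \Lambda V^\top}; both routes are
#' exercised in the test suite.
#'
#' @param S symmetric numeric matrix.
#' @param coefficients numeric vector \code{c(a0, a1, ..., ak)}.
#' @return The symmetric matrix \eqn{f(S)}.
#' @export
matrix_polynomial <- function(S, coefficients) {
  S <- check_square_symmetric(S, what = "S")
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1L,
            all(is.finite(coefficients)))
  n <- nrow(S)
  k <- length(coefficients) - 1L
  P <- diag(coefficients[k + 1L], n)
  if (k >= 1L) {
    for (i in k:1L) {
      P <- S %*% P
      diag(P) <- diag(P) + coefficients[i]
    }
  }
  (P + t(P)) / 2
}

#' Evaluate a scalar polynomial
#'
#' @param coefficients numeric vector \code{c(a0, ..., ak)}.
#' @param x numeric vector of evaluation points.
#' @return \code{a0 + a1*x + ... + ak*x^k}, vectorized over \code{x}.
#' @export
poly_eval <- function(coefficients, x) {
  k <- length(coefficients) - 1L
  drop(vandermonde(x, k) %*% coefficients)
}

# Vandermonde design: row i = (1, x_i, x_i^2, ..., x_i^k).
vandermonde <- function(x, k) {
  stopifnot(k >= 0L)
  outer(as.numeric(x), 0:k, `^`)
}

#' Sum of walk weights by explicit enumeration
#'
#' The weight of a walk is the product of its traversed edge weights; the sum
#' over all walks of length \code{l} from \code{from} to \code{to} equals
#' \eqn{[S^l]_{ij}}. This function computes the sum by brute-force enumeration
#' of node sequences and is intended as an independent oracle against the
#' matrix-power route; it is exponential in \code{l} and therefore restricted
#' to small graphs.
#'
#' @param S weighted adjacency matrix (symmetric, non-negative).
#' @param from,to 1-based node indices.
#' @param length walk length \code{l >= 0}.
#' @return The scalar sum of walk weights.
#' @export
walk_weight_sum <- function(S, from, to, length) {
  S <- check_square_symmetric(S, what = "S")
  n <- nrow(S)
  l <- as.integer(length)
  stopifnot(l >= 0L, from >= 1L, from <= n, to >= 1L, to <= n)
  if (l > 8L || n > 12L) {
    stop("walk enumeration oracle is limited to length <= 8 and n <= 12")
  }
  if (l == 0L) return(as.numeric(from == to))
  recurse <- function(node, remaining) {
    if (remaining == 0L) return(as.numeric(node == to))
    total <- 0
    for (nxt in seq_len(n)) {
      w <- S[node, nxt]
      if (w != 0) total <- total + w * recurse(nxt, remaining - 1L)
    }
    total
  }
  recurse(from, l)
}

#' Matrix correlation quality (upper-triangle Pearson correlation)
#'
#' The similarity between two square matrices used for all mapping-quality
#' reporting: the Pearson correlation between the two length
#' \eqn{n(n-1)/2} vectors of strict upper-triangular entries (diagonal
#' excluded).
#'
#' @param X,Y square numeric matrices of the same dimension, \code{n >= 3}.
#' @param na_if_constant if \code{TRUE}, return \code{NaN} (with a warning)
#'   when either vectorized triangle has zero variance instead of erroring;
#'   used by the stability sweeps so degenerate orders do not abort a sweep.
#' @return A correlation in \code{[-1, 1]} (or \code{NaN}, see above).
#' @examples
#' X <- matrix(rnorm(25), 5); X <- X + t(X)
#' ucorr(X, 2 * X + 1)  # affine invariance: exactly 1
#' @export
ucorr <- function(X, Y, na_if_constant = FALSE) {
  if (!is.matrix(X) || !is.matrix(Y) || !identical(dim(X), dim(Y)) ||
      nrow(X) != ncol(X)) {
    stop("ucorr requires two square matrices of identical dimension")
  }
  if (nrow(X) < 3L) stop("ucorr requires n >= 3 (at least 3 upper-triangular entries)")
  x <- X[upper.tri(X)]
  y <- Y[upper.tri(Y)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (na_if_constant) {
      warning("constant upper triangle: ucorr undefined, returning NaN")
      return(NaN)
    }
    stop("zero variance in a vectorized upper triangle; ucorr undefined")
  }
  stats::cor(x, y)
}

#' Pearson correlation matrix of a multichannel time series
#'
#' @param signals an \code{M x L} matrix, one row per region, one column per
#'   time sample.
#' @return The \code{M x M} symmetric correlation matrix with exact unit
#'   diagonal.
#' @export
correlation_matrix <- function(signals) {
  signals <- check_bold_series(signals)
  C <- stats::cor(t(signals))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dimnames(C) <- list(rownames(signals), rownames(signals))
  C
}

# ---- internal validation helpers ------------------------------------------

# Validates squareness/finiteness, checks relative asymmetry against `rtol`
# (spec'd boundary tolerance 1e-8) and returns the exactly symmetrized matrix.
check_square_symmetric <- function(X, what = "matrix", rtol = 1e-8) {
  if (!is.matrix(X) || !is.numeric(X)) stop(what, " must be a numeric matrix")
  if (nrow(X) != ncol(X)) stop(what, " must be square")
  if (any(!is.finite(X))) stop(what, " contains non-finite entries")
  scale <- max(abs(X), .Machine$double.xmin)
  asym <- max(abs(X - t(X)))
  if (asym > rtol * scale) {
    stop(what, sprintf(" is asymmetric beyond tolerance (max asymmetry %.3g relative)",
                       asym / scale))
  }
  (X + t(X)) / 2
}

check_bold_series <- function(signals) {
  if (!is.matrix(signals) || !is.numeric(signals)) {
    stop("time series must be a numeric regions x samples matrix")
  }
  if (nrow(signals) < 2L) stop("need at least 2 regions")
  if (ncol(signals) < 4L) stop("need at least 4 time samples")
  if (any(!is.finite(signals))) stop("time series contains non-finite values")
  v <- apply(signals, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance region(s): ", paste(which(v == 0), collapse = ", "))
  }
  signals
}
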