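# Per-subject spectral mapping: closed-form fit of polynomial coefficients
# (Vandermonde least squares on paired descending spectra) and eigenmode-
# aligning rotation (orthogonal Procrustes, R = U V').

#' Fit an individual spectral mapping from structure to function
#'
#' Fits the model \eqn{\hat F = R\,f(S)\,R^\top} with
#' \eqn{f(S) = \sum_{i=0}^{k} a_i S^i} and orthogonal \eqn{R}, minimizing the
#' Frobenius norm \eqn{\|\hat F - F\|_F}. The closed-form solution pairs the
#' descending eigenvalues \eqn{\lambda} of \eqn{S} with the descending
#' eigenvalues \eqn{\phi} of \eqn{F}: the coefficients solve the Vandermonde
#' least-squares problem \eqn{\min_a \|L a - \phi\|_2} (computed by QR
#' factorization, not the normal equations, on eigenvalues rescaled by
#' \code{max(abs(lambda))} for conditioning), and the rotation is
#' \eqn{R = U V^\top} where \eqn{V, U} hold the eigenvectors of \eqn{S} and
#' \eqn{F}. The orthogonality constraint admits reflections
#' (\eqn{\det R = \pm 1}); the determinant is not restricted.
#'
#' With \code{m < n}, only the leading \code{m} eigenmode pairs (by
#' descending eigenvalue) are freely aligned:
#' \eqn{R_m = U_m V_m^\top + \bar U \bar V^\top}, where \eqn{\bar U},
#' \eqn{\bar V} are deterministic orthonormal completions of the spans of the
#' first \code{m} columns. \code{m = n} reproduces the unconstrained solution
#' exactly.
#'
#' @param structural symmetric non-negative \code{n x n} structural matrix
#'   \eqn{S}.
#' @param functional symmetric \code{n x n} functional matrix \eqn{F}.
#' @param k maximum walk length / polynomial order (\code{n >= k + 1}).
#' @param m rank of the rotation: number of freely aligned eigenmode pairs,
#'   in \code{1..n}; defaults to \code{n} (unconstrained).
#' @return An object of class \code{"spectral_map"}: a list with the raw- and
#'   conditioned-scale coefficients, the rotation \code{R}, the two
#'   eigensystems, the fitted matrix \eqn{\hat F} and the Frobenius
#'   \code{fit_residual}.
#' @seealso \code{\link{predict.spectral_map}}, \code{\link{eigenmode_weights}},
#'   \code{\link{spectral_map_group}}
#' @examples
#' sim <- simulate_planted_pair(n = 12, k = 2, seed = 1)
#' fit <- spectral_map(sim$S, sim$F, k = 2)
#' ucorr(fitted(fit), sim$F)  # exact recovery: 1
#' @export
spectral_map <- function(structural, functional, k, m = NULL) {
  S <- check_square_symmetric(structural, what = "structural")
  F_ <- check_square_symmetric(functional, what = "functional")
  n <- nrow(S)
  if (nrow(F_) != n) stop("structural and functional matrices differ in dimension")
  k <- as.integer(k)
  if (k < 0L) stop("k must be >= 0")
  if (n < k + 1L) stop("underdetermined fit: need n >= k + 1")
  if (is.null(m)) m <- n
  m <- as.integer(m)
  if (m < 1L || m > n) stop("rotation rank m must be in 1..n")

  eig_s <- eigen_system(S)
  eig_f <- eigen_system(F_)
  if (any(!is.finite(eig_s$values)) || any(!is.finite(eig_f$values))) {
    stop("non-finite spectrum")
  }

  scale <- max(abs(eig_s$values))
  if (scale == 0) scale <- 1
  L <- vandermonde(eig_s$values / scale, k)
  a_scaled <- qr.coef(qr(L), eig_f$values)
  a_raw <- a_scaled / scale^(0:k)

  R <- if (m == n) {
    eig_f$vectors %*% t(eig_s$vectors)
  } else {
    Um <- eig_f$vectors[, seq_len(m), drop = FALSE]
    Vm <- eig_s$vectors[, seq_len(m), drop = FALSE]
    Um %*% t(Vm) +
      orthonormal_completion(Um) %*% t(orthonormal_completion(Vm))
  }

  fvals <- poly_eval(a_scaled, eig_s$values / scale)
  RV <- R %*% eig_s$vectors
  Fhat <- RV %*% (fvals * t(RV))
  Fhat <- (Fhat + t(Fhat)) / 2

  structure(list(
    coefficients = stats::setNames(a_raw, paste0("a", 0:k)),
    coefficients_scaled = a_scaled,
    eigenvalue_scale = scale,
    rotation = R,
    n = n, k = k, m = m,
    eig_structural = eig_s,
    eig_functional = eig_f,
    structural = S,
    functional = F_,
    fitted = Fhat,
    fit_residual = frobenius(Fhat - F_),
    call = match.call()
  ), class = "spectral_map")
}

#' Map a structural matrix through a fitted individual mapping
#'
#' Applies \eqn{\hat F = R^* f(S) (R^*)^\top} with the fitted parameters. On
#' the training matrix this equals \eqn{U f(\Lambda) U^\top} (the functional
#' eigenvectors with polynomial-transformed structural eigenvalues); on any
#' other structural matrix it is the swap prediction used by the null-model
#' analyses.
#'
#' @param object a fitted \code{spectral_map}.
#' @param newdata a symmetric structural matrix of the same dimension;
#'   defaults to the training matrix.
#' @param ... unused.
#' @return The symmetric mapped matrix \eqn{\hat F}.
#' @export
predict.spectral_map <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fitted)) stop("model carries no training data; supply newdata")
    return(object$fitted)
  }
  S <- check_square_symmetric(newdata, what = "newdata")
  if (nrow(S) != object$n) {
    stop(sprintf("dimension mismatch: model n = %d, newdata n = %d",
                 object$n, nrow(S)))
  }
  Om <- matrix_polynomial(S, as.numeric(object$coefficients))
  Fhat <- object$rotation %*% Om %*% t(object$rotation)
  (Fhat + t(Fhat)) / 2
}

#' @export
fitted.spectral_map <- function(object, ...) object$fitted

#' @export
residuals.spectral_map <- function(object, ...) {
  if (is.null(object$functional)) stop("model carries no training data")
  object$functional - object$fitted
}

#' @export
coef.spectral_map <- function(object, ...) object$coefficients

#' @export
print.spectral_map <- function(x, ...) {
  cat("Individual spectral mapping (F-hat = R f(S) R')\n")
  cat(sprintf("  n = %d regions, polynomial order k = %d, rotation rank m = %d\n",
              x$n, x$k, x$m))
  cat("  coefficients (raw eigenvalue scale):\n")
  print(signif(x$coefficients, 6))
  if (!is.null(x$fit_residual)) {
    cat(sprintf("  Frobenius fit residual: %.6g\n", x$fit_residual))
  }
  invisible(x)
}

#' @export
summary.spectral_map <- function(object, ...) {
  uc <- if (!is.null(object$functional)) {
    ucorr(object$fitted, object$functional, na_if_constant = TRUE)
  } else NA_real_
  structure(list(model = object, ucorr_in_sample = uc), class = "summary.spectral_map")
}

#' @export
print.summary.spectral_map <- function(x, ...) {
  print(x$model)
  cat(sprintf("  in-sample ucorr(F-hat, F): %.6f\n", x$ucorr_in_sample))
  invisible(x)
}

#' Scatter plot of mapped versus observed connectivity
#'
#' Plots the strict upper-triangular entries of \eqn{\hat F} against those of
#' the training \eqn{F}, with the identity line; the standard visual check of
#' mapping quality.
#'
#' @param x a fitted \code{spectral_map} (with training data).
#' @param ... passed to \code{plot}.
#' @export
plot.spectral_map <- function(x, ...) {
  if (is.null(x$functional)) stop("model carries no training data")
  obs <- x$functional[upper.tri(x$functional)]
  map <- x$fitted[upper.tri(x$fitted)]
  plot(obs, map, xlab = "observed [F]_ij", ylab = "mapped [F-hat]_ij",
       main = sprintf("ucorr = %.4f", ucorr(x$fitted, x$functional)), ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}

#' Eigenmode weight matrix W = V' R V
#'
#' Expresses each functional eigenmode as a linear combination of structural
#' eigenmodes: with \eqn{W = V^\top R V}, the columns satisfy
#' \eqn{u_i = V w_i = \sum_j w_{ji} v_j} (exact for the unconstrained
#' rotation, where \eqn{V W = R V = U}).
#'
#' @param object a fitted \code{spectral_map}.
#' @return The orthogonal \code{n x n} weight matrix \code{W}.
#' @export
eigenmode_weights <- function(object) {
  stopifnot(inherits(object, "spectral_map"))
  if (is.null(object$eig_structural)) stop("model carries no eigensystems")
  V <- object$eig_structural$vectors
  t(V) %*% object$rotation %*% V
}

# Deterministic orthonormal completion of the column span of A (n x m):
# the trailing n - m columns of the complete QR factor, sign-fixed.
orthonormal_completion <- function(A) {
  n <- nrow(A); m <- ncol(A)
  if (m >= n) return(matrix(numeric(0), n, 0))
  qrA <- qr(A)
  Q <- qr.Q(qrA, complete = TRUE)
  Q[, (m + 1L):n, drop = FALSE]
}

frobenius <- function(X) sqrt(sum(X * X))
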