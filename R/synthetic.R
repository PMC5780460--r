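# Seeded synthetic generators: weighted structural graphs, planted individual
# and group mappings, cohorts with tunable cross-subject heterogeneity, and
# autoregressive BOLD-like time series. Every generator is a pure function of
# its arguments plus the seed.

#' Draw a Haar-distributed random orthogonal matrix
#'
#' QR factorization of a standard-normal matrix with the sign of the
#' triangular factor's diagonal fixed, which makes the factor unique and the
#' resulting distribution uniform (Haar) on the orthogonal group.
#'
#' @param n dimension.
#' @param seed optional integer seed.
#' @return An \code{n x n} orthogonal matrix.
#' @export
random_orthogonal <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  qr_retract(matrix(stats::rnorm(n * n), n, n))
}

#' Generate a random weighted structural graph
#'
#' Erdos-Renyi-style topology: each of the \eqn{n(n-1)/2} undirected edges is
#' present independently with probability \code{density}, with weights drawn
#' from the chosen law. The matrix is symmetric, non-negative, has a zero
#' diagonal and is normalized so its maximum entry is exactly 1.
#'
#' @param n number of regions.
#' @param density edge probability in (0, 1].
#' @param weight_law \code{"uniform"} (weights on (0, 1]) or
#'   \code{"lognormal"} (heavy-tailed, as streamline counts tend to be).
#' @param seed optional integer seed.
#' @return A structural matrix.
#' @export
simulate_structural <- function(n, density = 0.3,
                                weight_law = c("uniform", "lognormal"),
                                seed = NULL) {
  weight_law <- match.arg(weight_law)
  if (n < 2L) stop("need n >= 2")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ne <- n * (n - 1L) / 2L
  present <- stats::runif(ne) < density
  w <- switch(weight_law,
              uniform = stats::runif(ne),
              lognormal = stats::rlnorm(ne, meanlog = 0, sdlog = 1))
  w[!present] <- 0
  S <- matrix(0, n, n)
  S[upper.tri(S)] <- w
  S <- S + t(S)
  if (max(S) == 0) stop("generated graph has no edges; increase density or n")
  normalize_structural(S)
}

#' Generate a planted structure-function pair with known ground truth
#'
#' Realizes the individual mapping model exactly: draws a structural matrix
#' \eqn{S}, a polynomial \eqn{f} strictly increasing on the spectrum of
#' \eqn{S} (so the descending eigenvalue pairings of truth and fit coincide),
#' and a Haar-random orthogonal \eqn{R_0}, then sets
#' \eqn{F = R_0 V f(\Lambda) V^\top R_0^\top} plus optional symmetric
#' Gaussian noise. The result is rescaled by its maximum absolute entry
#' (truth coefficients rescaled identically) so \eqn{F} lies in
#' \eqn{[-1, 1]}. At \code{noise_sigma = 0},
#' \code{\link{spectral_map}} recovers \eqn{F} and the coefficients exactly.
#'
#' @param n number of regions.
#' @param k planted polynomial order (>= 1).
#' @param density edge probability of the structural graph.
#' @param noise_sigma standard deviation of the additive symmetric noise on
#'   the functional matrix (0 for a noiseless, exactly recoverable pair).
#' @param seed optional integer seed.
#' @param rotation optional fixed orthogonal matrix to use as \eqn{R_0}
#'   (e.g. \code{diag(n)} for an aligned pair); default Haar-random.
#' @return A list with \code{S}, \code{F}, \code{coefficients} (the planted
#'   raw-scale coefficients after rescaling), \code{rotation}
#'   (\eqn{R_0}), \code{model} (a \code{spectral_map} object holding the
#'   planted parameters, usable with \code{predict}), and \code{scale} (the
#'   applied rescaling factor).
#' @export
simulate_planted_pair <- function(n = 50, k = 2, density = 0.3,
                                  noise_sigma = 0, seed = NULL,
                                  rotation = NULL) {
  k <- as.integer(k)
  if (k < 1L) stop("planted order k must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  S <- simulate_structural(n, density = density)
  eig <- eigen_system(S, warn_degenerate = FALSE)
  scale <- max(abs(eig$values))
  lam_s <- eig$values / scale
  a_scaled <- draw_monotone_coefficients(k, range(lam_s))
  a_raw <- a_scaled / scale^(0:k)
  R0 <- if (is.null(rotation)) random_orthogonal(n) else rotation
  check_orthogonal(R0, tol = 1e-8, what = "rotation")
  fvals <- poly_eval(a_scaled, lam_s)
  RV <- R0 %*% eig$vectors
  F0 <- RV %*% (fvals * t(RV))
  F0 <- (F0 + t(F0)) / 2
  F_ <- F0
  if (noise_sigma > 0) {
    E <- matrix(stats::rnorm(n * n, sd = noise_sigma), n, n)
    F_ <- F_ + (E + t(E)) / 2
  }
  t_ <- max(abs(F_))
  F_ <- F_ / t_
  a_true <- a_raw / t_
  model <- structure(list(
    coefficients = stats::setNames(a_true, paste0("a", 0:k)),
    coefficients_scaled = a_scaled / t_,
    eigenvalue_scale = scale,
    rotation = R0, n = n, k = k, m = n,
    structural = S,
    fitted = F0 / t_,
    fit_residual = frobenius(F_ - F0 / t_)
  ), class = "spectral_map")
  list(S = S, F = F_, coefficients = a_true, rotation = R0,
       model = model, scale = t_, noise_sigma = noise_sigma)
}

#' Generate a synthetic cohort with controllable heterogeneity
#'
#' At \code{heterogeneity = 0} all subjects share one planted orthogonal
#' eigenmode basis \eqn{Q_0} and one coefficient vector \eqn{c_0} while
#' keeping subject-specific structural spectra — the exact model class of the
#' group mapping, which \code{\link{spectral_map_group}} recovers to
#' numerical precision. At \code{heterogeneity = 1} each subject gets an
#' independent planted basis and jittered coefficients (purely individual
#' structure-function relationships). Intermediate values interpolate: each
#' subject's basis is the sign-fixed QR retraction of
#' \eqn{(1 - h) Q_0 + h\,G_j} with \eqn{G_j} standard normal, and
#' coefficients are multiplied by per-subject factors \eqn{1 + h \epsilon_j}.
#' All functional matrices are rescaled by the cohort-wide maximum absolute
#' entry so they lie in \eqn{[-1, 1]}.
#'
#' @param N number of subjects.
#' @param n number of regions.
#' @param k planted polynomial order.
#' @param heterogeneity in \code{[0, 1]}, see above.
#' @param density structural edge probability.
#' @param noise_sigma additive symmetric noise on each functional matrix.
#' @param seed optional integer seed.
#' @return A list with \code{cohort} (list of \code{list(S, F)}),
#'   \code{basis} (\eqn{Q_0}), \code{coefficients} (shared raw-scale planted
#'   coefficients after cohort rescaling), \code{subject_bases},
#'   \code{subject_coefficients} and \code{heterogeneity}.
#' @export
simulate_cohort <- function(N, n = 30, k = 2, heterogeneity = 0,
                            density = 0.3, noise_sigma = 0, seed = NULL) {
  if (N < 1L) stop("need N >= 1")
  if (heterogeneity < 0 || heterogeneity > 1) stop("heterogeneity must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  Q0 <- random_orthogonal(n)
  Ss <- lapply(seq_len(N), function(j) simulate_structural(n, density = density))
  lam <- vapply(Ss, function(S) eigen_system(S, warn_degenerate = FALSE)$values,
                numeric(n))
  lam <- matrix(lam, n, N)
  scale <- max(abs(lam))
  c_scaled <- draw_monotone_coefficients(k, range(lam / scale))
  h <- heterogeneity
  subject_bases <- vector("list", N)
  subject_coefs <- vector("list", N)
  Fs <- vector("list", N)
  for (j in seq_len(N)) {
    Qj <- if (h == 0) Q0 else {
      qr_retract((1 - h) * Q0 + h * matrix(stats::rnorm(n * n), n, n))
    }
    cj <- if (h == 0) c_scaled else {
      c_scaled * (1 + h * stats::runif(k + 1L, -0.3, 0.3))
    }
    g <- poly_eval(cj, lam[, j] / scale)
    Fj <- Qj %*% (g * t(Qj))
    Fj <- (Fj + t(Fj)) / 2
    if (noise_sigma > 0) {
      E <- matrix(stats::rnorm(n * n, sd = noise_sigma), n, n)
      Fj <- Fj + (E + t(E)) / 2
    }
    subject_bases[[j]] <- Qj
    subject_coefs[[j]] <- cj
    Fs[[j]] <- Fj
  }
  t_ <- max(vapply(Fs, function(Fj) max(abs(Fj)), numeric(1)))
  cohort <- lapply(seq_len(N), function(j) list(S = Ss[[j]], F = Fs[[j]] / t_))
  list(cohort = cohort,
       basis = Q0,
       coefficients = stats::setNames(c_scaled / t_ / scale^(0:k), paste0("c", 0:k)),
       subject_bases = subject_bases,
       subject_coefficients = lapply(subject_coefs, function(cc) cc / t_),
       eigenvalue_scale = scale,
       heterogeneity = h)
}

#' Generate a stationary BOLD-like multivariate time series
#'
#' First-order vector autoregression \eqn{x_t = A x_{t-1} + \varepsilon_t}
#' with coefficient matrix \eqn{A} proportional to the normalized structural
#' matrix, rescaled so its spectral radius equals \code{coupling} (< 1,
#' guaranteeing stationarity). The stationary covariance
#' \eqn{\sum_{m \ge 0} A^m (A^m)^\top} is a sum over walk-weighted structural
#' proximities, so population correlations increase with structural
#' proximity; \code{coupling = 0} gives independent white noise. Hemodynamics
#' and bandpass filtering are not emulated — only the correlation structure
#' the evaluation layer needs.
#'
#' @param S structural matrix.
#' @param L number of retained time samples (>= 8).
#' @param coupling spectral radius of the autoregression in [0, 1).
#' @param seed optional integer seed.
#' @param burn_in discarded initial samples.
#' @return An \code{n x L} matrix of signals (regions in rows).
#' @export
simulate_bold <- function(S, L = 1200, coupling = 0.5, seed = NULL,
                          burn_in = 100L) {
  S <- check_square_symmetric(S, what = "S")
  if (L < 8L) stop("need L >= 8 samples")
  if (coupling < 0 || coupling >= 1) stop("coupling must be in [0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(S)
  A <- if (coupling == 0 || max(abs(S)) == 0) {
    matrix(0, n, n)
  } else {
    rho <- max(abs(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
    S * (coupling / rho)
  }
  total <- L + burn_in
  X <- matrix(0, n, total)
  x <- stats::rnorm(n)
  for (t in seq_len(total)) {
    x <- drop(A %*% x) + stats::rnorm(n)
    X[, t] <- x
  }
  X[, (burn_in + 1L):total, drop = FALSE]
}

# Draw scaled-eigenvalue polynomial coefficients (a0..ak) whose derivative is
# strictly positive over the given range, so the polynomial is strictly
# increasing on the planted spectrum; regenerate up to 10 times.
draw_monotone_coefficients <- function(k, lam_range) {
  grid <- seq(lam_range[1], lam_range[2], length.out = 201L)
  for (attempt in seq_len(10L)) {
    a <- c(stats::runif(1, -0.3, 0.3),          # intercept
           stats::runif(1, 0.8, 1.5),           # dominant linear term
           if (k >= 2L) stats::runif(k - 1L, 0, 0.4 / (2:k)))
    deriv <- (1:k) * a[-1]
    dvals <- vandermonde(grid, k - 1L) %*% deriv
    if (all(dvals > 1e-3)) return(a)
  }
  stop("failed to draw a strictly increasing planted polynomial after 10 attempts")
}
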