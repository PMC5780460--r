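# Group spectral mapping: one shared orthogonal eigenmode basis Q and shared
# polynomial coefficients c fitted across a training cohort by alternating
# minimization (exact c-step; Riemannian gradient Q-step with QR retraction
# and backtracking line search).

#' Fit a group spectral mapping across a cohort
#'
#' Solves \deqn{\min_{c, Q} \sum_j \| Q\,g(\Lambda_j)\,Q^\top - F_j \|_F^2
#' \quad \mathrm{s.t.}\ Q Q^\top = Q^\top Q = I,} where
#' \eqn{g(\Lambda_j) = \sum_r c_r \Lambda_j^r} acts on subject \eqn{j}'s
#' descending structural eigenvalues. A subject's structural eigenvectors are
#' deliberately not used: the single orthogonal basis \eqn{Q} plays the role
#' of common functional eigenmodes for the whole cohort.
#'
#' The solver alternates two steps. The c-step is exact: the off-diagonal of
#' \eqn{Q^\top F_j Q} does not depend on \eqn{c}, so minimizing over \eqn{c}
#' reduces to a stacked \eqn{(Nn) \times (k+1)} Vandermonde least-squares
#' problem of \eqn{\mathrm{diag}(Q^\top F_j Q)} against each subject's
#' eigenvalues (on a cohort-wide conditioned scale). The Q-step performs
#' steepest descent on the orthogonal manifold: the ambient gradient
#' \eqn{\sum_j 4 (Q D_j Q^\top - F_j) Q D_j} is projected to the tangent
#' space, a step is taken, and the iterate is retracted back by a sign-fixed
#' QR factorization; backtracking guarantees a non-increasing objective.
#' Initialization is deterministic: \eqn{Q_0} is the eigenvector basis of the
#' cohort-mean functional matrix (descending order).
#'
#' @param cohort a list of subjects, each a list with elements \code{S}
#'   (structural matrix) and \code{F} (functional matrix), all the same
#'   dimension.
#' @param k polynomial order (\code{n >= k + 1}).
#' @param max_iter maximum number of alternating iterations.
#' @param tol relative objective-decrease threshold for convergence.
#' @param n_starts number of starts; starts beyond the first use seeded
#'   random orthogonal initial bases, and the best final objective wins.
#' @param seed integer seed for the extra random starts.
#' @return An object of class \code{"spectral_map_group"} with the basis
#'   \code{Q}, shared coefficients, the per-iteration \code{objective_trace}
#'   (non-increasing), and a \code{converged} flag. A warning is issued when
#'   \code{max_iter} is reached without meeting \code{tol}.
#' @seealso \code{\link{predict.spectral_map_group}}, \code{\link{split_cohort}}
#' @export
spectral_map_group <- function(cohort, k, max_iter = 500L, tol = 1e-8,
                               n_starts = 1L, seed = NULL) {
  cohort <- check_cohort(cohort)
  N <- length(cohort)
  n <- nrow(cohort[[1]]$S)
  k <- as.integer(k)
  if (k < 0L) stop("k must be >= 0")
  if (n < k + 1L) stop("underdetermined fit: need n >= k + 1")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be positive")

  lam <- vapply(cohort, function(subj) eigen_system(subj$S)$values, numeric(n))
  lam <- matrix(lam, n, N)
  scale <- max(abs(lam))
  if (scale == 0) scale <- 1
  lam_s <- lam / scale
  X <- do.call(rbind, lapply(seq_len(N), function(j) vandermonde(lam_s[, j], k)))
  qrX <- qr(X)
  Fs <- lapply(cohort, `[[`, "F")

  Fbar <- Reduce(`+`, Fs) / N
  starts <- list(eigen_system(Fbar, warn_degenerate = FALSE)$vectors)
  if (n_starts > 1L) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    for (s in seq_len(n_starts - 1L)) starts[[s + 1L]] <- random_orthogonal(n)
  }

  best <- NULL
  for (Q0 in starts) {
    run <- group_descent(Q0, Fs, lam_s, qrX, k, max_iter, tol)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  if (!best$converged) {
    warning(sprintf(
      "group fit did not converge: relative decrease %.3g > tol %.3g after %d iterations",
      best$last_decrease, tol, length(best$trace) - 1L))
  }

  c_scaled <- best$c_scaled
  structure(list(
    basis = best$Q,
    coefficients = stats::setNames(c_scaled / scale^(0:k), paste0("c", 0:k)),
    coefficients_scaled = c_scaled,
    eigenvalue_scale = scale,
    n = n, k = k,
    n_subjects_train = N,
    objective_trace = best$trace,
    objective = best$objective,
    converged = best$converged,
    iterations = length(best$trace) - 1L,
    call = match.call()
  ), class = "spectral_map_group")
}

# One descent run from initial basis Q0. Returns the final basis, scaled
# coefficients, the objective trace (entry 1 = objective after the initial
# c-step), and convergence bookkeeping.
group_descent <- function(Q0, Fs, lam_s, qrX, k, max_iter, tol) {
  n <- nrow(Q0)
  Q <- Q0
  c_step <- function(Q) {
    y <- unlist(lapply(Fs, function(Fj) diag(crossprod(Q, Fj %*% Q))),
                use.names = FALSE)
    qr.coef(qrX, y)
  }
  objective <- function(Q, c_scaled) {
    tot <- 0
    for (j in seq_along(Fs)) {
      g <- poly_eval(c_scaled, lam_s[, j])
      E <- Q %*% (g * t(Q)) - Fs[[j]]
      tot <- tot + sum(E * E)
    }
    tot
  }
  cs <- c_step(Q)
  obj <- objective(Q, cs)
  trace <- obj
  converged <- FALSE
  last_decrease <- Inf
  for (it in seq_len(max_iter)) {
    # Q-step: projected gradient with QR retraction and backtracking.
    G <- matrix(0, n, n)
    for (j in seq_along(Fs)) {
      g <- poly_eval(cs, lam_s[, j])
      QD <- Q * rep(g, each = n)            # Q %*% diag(g)
      E <- QD %*% t(Q) - Fs[[j]]
      G <- G + 4 * (E %*% QD)
    }
    QtG <- crossprod(Q, G)
    G <- G - Q %*% ((QtG + t(QtG)) / 2)     # tangent-space projection
    gnorm <- frobenius(G)
    if (gnorm > 0) {
      alpha <- 1 / gnorm
      for (bt in seq_len(50L)) {
        Qtry <- qr_retract(Q - alpha * G)
        otry <- objective(Qtry, cs)
        if (otry <= obj) break
        alpha <- alpha / 2
        Qtry <- NULL
      }
      if (!is.null(Qtry) && otry <= obj) {
        Q <- Qtry
      }
    }
    cs <- c_step(Q)
    new_obj <- objective(Q, cs)
    # The c-step is an exact minimizer, so new_obj <= objective(Q, old cs)
    # <= obj; guard against rounding drift all the same.
    new_obj <- min(new_obj, obj)
    trace <- c(trace, new_obj)
    last_decrease <- if (obj > 0) (obj - new_obj) / obj else 0
    obj <- new_obj
    if (last_decrease < tol) { converged <- TRUE; break }
  }
  list(Q = Q, c_scaled = cs, trace = trace, objective = obj,
       converged = converged, last_decrease = last_decrease)
}

#' Map a structural matrix through a fitted group mapping
#'
#' Computes \eqn{\hat F = Q\,g(\Lambda(S))\,Q^\top}: only the eigenvalues of
#' the supplied structural matrix are used, combined with the cohort-shared
#' eigenmode basis.
#'
#' @param object a fitted \code{spectral_map_group}.
#' @param newdata a symmetric structural matrix of matching dimension.
#' @param ... unused.
#' @return The symmetric mapped matrix.
#' @export
predict.spectral_map_group <- function(object, newdata, ...) {
  S <- check_square_symmetric(newdata, what = "newdata")
  if (nrow(S) != object$n) {
    stop(sprintf("dimension mismatch: model n = %d, newdata n = %d",
                 object$n, nrow(S)))
  }
  lam <- eigen_system(S, warn_degenerate = FALSE)$values
  g <- poly_eval(object$coefficients_scaled, lam / object$eigenvalue_scale)
  Q <- object$basis
  Fhat <- Q %*% (g * t(Q))
  (Fhat + t(Fhat)) / 2
}

#' @export
coef.spectral_map_group <- function(object, ...) object$coefficients

#' @export
print.spectral_map_group <- function(x, ...) {
  cat("Group spectral mapping (F-hat_j = Q g(Lambda_j) Q')\n")
  cat(sprintf("  n = %d regions, order k = %d, trained on N = %d subjects\n",
              x$n, x$k, x$n_subjects_train))
  cat("  shared coefficients (raw eigenvalue scale):\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("  objective: %.6g after %d iterations (%s)\n",
              x$objective, x$iterations,
              if (isTRUE(x$converged)) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
summary.spectral_map_group <- function(object, ...) {
  structure(list(model = object), class = "summary.spectral_map_group")
}

#' @export
print.summary.spectral_map_group <- function(x, ...) {
  print(x$model)
  tr <- x$model$objective_trace
  cat(sprintf("  objective trace: start %.6g, end %.6g, monotone: %s\n",
              tr[1], tr[length(tr)], all(diff(tr) <= 1e-12)))
  invisible(x)
}

#' Split a cohort into training and validation subgroups
#'
#' Draws a deterministic (seeded) subject-level partition: the training set
#' holds \code{ceiling(fraction * N)} subjects chosen uniformly at random
#' without replacement, the validation set holds the rest.
#'
#' @param cohort list of subjects as for \code{\link{spectral_map_group}}.
#' @param fraction training fraction in (0, 1); default 0.5.
#' @param seed integer seed.
#' @return A list with elements \code{train}, \code{validate} (cohorts) and
#'   \code{train_indices}, \code{validate_indices}.
#' @export
split_cohort <- function(cohort, fraction = 0.5, seed = NULL) {
  cohort <- check_cohort(cohort)
  N <- length(cohort)
  if (N < 2L) stop("need at least 2 subjects to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_train <- ceiling(fraction * N)
  idx <- sort(sample.int(N, n_train))
  rest <- setdiff(seq_len(N), idx)
  list(train = cohort[idx], validate = cohort[rest],
       train_indices = idx, validate_indices = rest)
}

check_cohort <- function(cohort) {
  if (!is.list(cohort) || length(cohort) == 0L) {
    stop("cohort must be a non-empty list of subjects")
  }
  n <- NULL
  for (j in seq_along(cohort)) {
    subj <- cohort[[j]]
    if (!is.list(subj) || is.null(subj$S) || is.null(subj$F)) {
      stop("each subject must be a list with elements S and F")
    }
    cohort[[j]]$S <- check_square_symmetric(subj$S, what = sprintf("S[[%d]]", j))
    cohort[[j]]$F <- check_square_symmetric(subj$F, what = sprintf("F[[%d]]", j))
    nj <- nrow(cohort[[j]]$S)
    if (nrow(cohort[[j]]$F) != nj) {
      stop(sprintf("subject %d: S and F differ in dimension", j))
    }
    if (is.null(n)) n <- nj
    else if (nj != n) stop("subjects differ in dimension across the cohort")
  }
  cohort
}

# Sign-fixed QR retraction onto the orthogonal group.
qr_retract <- function(M) {
  qrM <- qr(M)
  Q <- qr.Q(qrM)
  d <- sign(diag(qr.R(qrM)))
  d[d == 0] <- 1
  Q * rep(d, each = nrow(Q))
}
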