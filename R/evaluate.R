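# Evaluation apparatus: time-sample splitting into in/out-of-sample
# functional matrices, order/rank stability sweeps, multiplicative
# perturbation robustness, null-model swap analyses and cross-subject
# spectral-similarity diagnostics.

#' Split a time series into in-sample and out-of-sample functional matrices
#'
#' Draws \code{floor(L/2)} time-sample indices uniformly at random without
#' replacement; the complement forms the second half. One index set is shared
#' across all regions (the only construction under which inter-regional
#' Pearson correlation of the sub-series is well defined). Correlation
#' matrices of the two sub-series give the in-sample matrix \eqn{F^{(1)}}
#' used for fitting and the out-of-sample matrix \eqn{F^{(2)}} used for
#' validation.
#'
#' @param signals \code{M x L} matrix of region signals, \code{L >= 8}.
#' @param seed optional integer seed.
#' @return A list with \code{in_sample}, \code{out_sample} (functional
#'   matrices), \code{in_indices}, \code{out_indices}.
#' @export
split_time_series <- function(signals, seed = NULL) {
  signals <- check_bold_series(signals)
  L <- ncol(signals)
  if (L < 8L) stop("need at least 8 time samples to split")
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx1 <- sort(sample.int(L, L %/% 2L))
  idx2 <- setdiff(seq_len(L), idx1)
  list(in_sample = correlation_matrix(signals[, idx1, drop = FALSE]),
       out_sample = correlation_matrix(signals[, idx2, drop = FALSE]),
       in_indices = idx1, out_indices = idx2)
}

#' Sweep the polynomial order of the individual mapping
#'
#' For each order \code{k}, fits the mapping on the in-sample functional
#' matrix and reports the in-sample and out-of-sample mapping qualities
#' \eqn{ucorr(\hat F, F^{(1)})} and \eqn{ucorr(\hat F, F^{(2)})}. Degenerate
#' fits with a constant upper triangle (possible at \code{k = 0}) report
#' \code{NaN} rather than aborting the sweep.
#'
#' @param structural structural matrix.
#' @param split a list with \code{in_sample} and \code{out_sample} functional
#'   matrices, as returned by \code{\link{split_time_series}}.
#' @param k_values integer vector of orders (all \code{<= n - 1}).
#' @param m optional rotation rank applied at every order.
#' @return A data frame with columns \code{k}, \code{ucorr_in},
#'   \code{ucorr_out}, \code{fit_residual}.
#' @export
sweep_order <- function(structural, split, k_values, m = NULL) {
  stopifnot(is.list(split), !is.null(split$in_sample), !is.null(split$out_sample))
  n <- nrow(structural)
  if (max(k_values) > n - 1L) stop("max(k_values) must be <= n - 1")
  rows <- lapply(as.integer(k_values), function(k) {
    fit <- spectral_map(structural, split$in_sample, k = k, m = m)
    data.frame(
      k = k,
      ucorr_in = ucorr(fitted(fit), split$in_sample, na_if_constant = TRUE),
      ucorr_out = ucorr(fitted(fit), split$out_sample, na_if_constant = TRUE),
      fit_residual = fit$fit_residual
    )
  })
  do.call(rbind, rows)
}

#' Sweep the rank of the rotation at fixed polynomial order
#'
#' @param structural structural matrix.
#' @param split as in \code{\link{sweep_order}}.
#' @param m_values integer vector of rotation ranks in \code{1..n}.
#' @param k polynomial order held fixed across the sweep.
#' @return A data frame with columns \code{m}, \code{ucorr_in},
#'   \code{ucorr_out}, \code{fit_residual}.
#' @export
sweep_rank <- function(structural, split, m_values, k) {
  stopifnot(is.list(split), !is.null(split$in_sample), !is.null(split$out_sample))
  rows <- lapply(as.integer(m_values), function(m) {
    fit <- spectral_map(structural, split$in_sample, k = k, m = m)
    data.frame(
      m = m,
      ucorr_in = ucorr(fitted(fit), split$in_sample, na_if_constant = TRUE),
      ucorr_out = ucorr(fitted(fit), split$out_sample, na_if_constant = TRUE),
      fit_residual = fit$fit_residual
    )
  })
  do.call(rbind, rows)
}

#' Multiplicative perturbation of a structural matrix
#'
#' Draws a symmetric perturbation field with entries uniform on
#' \eqn{(-\rho, \rho)} (upper triangle plus diagonal drawn, then mirrored)
#' and applies \eqn{[\check S]_{ij} = (1 + [\Delta]_{ij})[S]_{ij}}. The
#' multiplicative form preserves the sparsity pattern exactly, and the
#' expected perturbation magnitude is proportional to each entry's value.
#'
#' @param S structural matrix.
#' @param rho uniform half-width, \code{>= 0}.
#' @param seed optional integer seed.
#' @return A list with \code{perturbed} (\eqn{\check S}), \code{delta} and
#'   \code{rho}.
#' @export
perturb_structural <- function(S, rho, seed = NULL) {
  S <- check_square_symmetric(S, what = "S")
  if (rho < 0) stop("rho must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(S)
  D <- matrix(0, n, n)
  up <- upper.tri(D, diag = TRUE)
  D[up] <- stats::runif(sum(up), -rho, rho)
  D <- D + t(D) - diag(diag(D))
  list(perturbed = (1 + D) * S, delta = D, rho = rho)
}

#' Mapping quality under structural perturbation
#'
#' With the parameters \eqn{(a^*, R^*)} fitted on the unperturbed matrix,
#' computes the perturbed mapped matrix
#' \eqn{\check F = R^* (\sum_i a_i^* \check S^i) (R^*)^\top} and returns
#' \eqn{ucorr(\hat F, \check F)} — the sensitivity of the mapping to bounded
#' multiplicative noise in the structural input. Exactly 1 at
#' \code{rho = 0}.
#'
#' @param model a fitted \code{\link{spectral_map}}.
#' @param rho perturbation half-width.
#' @param S structural matrix the model was fitted on; defaults to the one
#'   stored in the model.
#' @param seed optional integer seed.
#' @return A correlation in \code{[-1, 1]}.
#' @export
perturbation_quality <- function(model, rho, S = NULL, seed = NULL) {
  stopifnot(inherits(model, "spectral_map"))
  if (is.null(S)) S <- model$structural
  if (is.null(S)) stop("model carries no training structural matrix; supply S")
  if (rho == 0) return(1)
  Scheck <- perturb_structural(S, rho, seed = seed)$perturbed
  Fhat <- predict(model, newdata = S)
  Fcheck <- predict(model, newdata = Scheck)
  ucorr(Fhat, Fcheck)
}

#' Null-model swap analysis over a cohort
#'
#' Quantifies how much of the mapping quality is attributable to
#' subject-specific structure rather than similarities inherent in the data,
#' by computing the upper-triangle correlation for every family of
#' matched and swapped pairs: \code{fs_self} \eqn{(F_i, S_i)},
#' \code{fs_cross} \eqn{(F_i, S_j)}, \code{ff_cross} \eqn{(F_i, F_j)},
#' \code{ss_cross} \eqn{(S_i, S_j)}, the swap predictions
#' \code{fhat_cross_fi} \eqn{(\hat F_i^j, F_i)} and \code{fhat_cross_fj}
#' \eqn{(\hat F_i^j, F_j)} where \eqn{\hat F_i^j} maps subject \eqn{j}'s
#' structure through subject \eqn{i}'s fitted parameters, and the matched
#' reference \code{fhat_self} \eqn{(\hat F_i^i, F_i)}.
#'
#' @param cohort list of subjects (\code{list(S, F)}).
#' @param models list of \code{\link{spectral_map}} objects, \code{models[[i]]}
#'   fitted on subject \code{i}.
#' @return An object of class \code{"null_model_report"}: a list of the raw
#'   per-pair correlation vectors plus a \code{summary} data frame of
#'   mean/sd/median/count per family. Symmetric families have
#'   \eqn{N(N-1)/2} entries; ordered (swap) families have \eqn{N(N-1)}.
#' @export
null_model_report <- function(cohort, models) {
  cohort <- check_cohort(cohort)
  N <- length(cohort)
  if (length(models) != N) stop("need one fitted model per cohort subject")
  if (!all(vapply(models, inherits, logical(1), "spectral_map"))) {
    stop("models must be spectral_map objects")
  }
  Ss <- lapply(cohort, `[[`, "S")
  Fs <- lapply(cohort, `[[`, "F")
  fs_self <- vapply(seq_len(N), function(i) ucorr(Fs[[i]], Ss[[i]]), numeric(1))
  fhat_self <- vapply(seq_len(N), function(i) {
    ucorr(predict(models[[i]], newdata = Ss[[i]]), Fs[[i]])
  }, numeric(1))
  fs_cross <- numeric(0); fhat_cross_fi <- numeric(0); fhat_cross_fj <- numeric(0)
  ff_cross <- numeric(0); ss_cross <- numeric(0)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      fs_cross <- c(fs_cross, ucorr(Fs[[i]], Ss[[j]]))
      Fij <- predict(models[[i]], newdata = Ss[[j]])
      fhat_cross_fi <- c(fhat_cross_fi, ucorr(Fij, Fs[[i]]))
      fhat_cross_fj <- c(fhat_cross_fj, ucorr(Fij, Fs[[j]]))
      if (i < j) {
        ff_cross <- c(ff_cross, ucorr(Fs[[i]], Fs[[j]]))
        ss_cross <- c(ss_cross, ucorr(Ss[[i]], Ss[[j]]))
      }
    }
  }
  fam <- list(fs_self = fs_self, fs_cross = fs_cross, ff_cross = ff_cross,
              ss_cross = ss_cross, fhat_cross_fi = fhat_cross_fi,
              fhat_cross_fj = fhat_cross_fj, fhat_self = fhat_self)
  summary <- data.frame(
    family = names(fam),
    mean = vapply(fam, mean, numeric(1)),
    sd = vapply(fam, stats::sd, numeric(1)),
    median = vapply(fam, stats::median, numeric(1)),
    n_pairs = vapply(fam, length, integer(1)),
    row.names = NULL
  )
  structure(c(fam, list(summary = summary, n_subjects = N)),
            class = "null_model_report")
}

#' @export
print.null_model_report <- function(x, ...) {
  cat(sprintf("Null-model swap analysis over %d subjects\n", x$n_subjects))
  print(transform(x$summary,
                  mean = signif(mean, 4), sd = signif(sd, 4),
                  median = signif(median, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Cross-subject spectral similarity diagnostics
#'
#' Summarizes how similar the spectra of a cohort's connectivity matrices
#' are: per-rank quartiles of the descending eigenvalues across subjects
#' (structural and functional), and for the leading two eigenvectors of each
#' modality the absolute Pearson correlation over every subject pair
#' (\eqn{l(l-1)/2} pairs; absolute value because eigenvector sign is
#' arbitrary even after the fixed sign convention).
#'
#' @param cohort list of subjects (\code{list(S, F)}), at least 2.
#' @return An object of class \code{"spectral_similarity"}: per-modality
#'   eigenvalue-quartile data frames (\code{rank}, \code{q1}, \code{median},
#'   \code{q3}, \code{mean}) and pairwise eigenvector-correlation vectors
#'   \code{evec_cor[[modality]][[rank]]}.
#' @export
spectral_similarity <- function(cohort) {
  cohort <- check_cohort(cohort)
  l <- length(cohort)
  if (l < 2L) stop("need at least 2 subjects")
  eig_of <- function(key) lapply(cohort, function(subj) {
    eigen_system(subj[[key]], warn_degenerate = FALSE)
  })
  per_modality <- function(eigs) {
    vals <- vapply(eigs, `[[`, numeric(eigs[[1]]$n), "values")
    qt <- t(apply(vals, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75)))
    evq <- data.frame(rank = seq_len(nrow(vals)), q1 = qt[, 1],
                      median = qt[, 2], q3 = qt[, 3],
                      mean = rowMeans(vals), row.names = NULL)
    evc <- lapply(1:2, function(r) {
      cors <- numeric(0)
      for (i in seq_len(l - 1L)) {
        for (j in (i + 1L):l) {
          cors <- c(cors, abs(stats::cor(eigs[[i]]$vectors[, r],
                                         eigs[[j]]$vectors[, r])))
        }
      }
      cors
    })
    names(evc) <- c("first", "second")
    list(eigenvalue_quartiles = evq, evec_cor = evc)
  }
  out <- list(structural = per_modality(eig_of("S")),
              functional = per_modality(eig_of("F")),
              n_subjects = l,
              n_pairs = (l * (l - 1L)) %/% 2L)
  structure(out, class = "spectral_similarity")
}

#' @export
print.spectral_similarity <- function(x, ...) {
  cat(sprintf("Spectral similarity across %d subjects (%d pairs)\n",
              x$n_subjects, x$n_pairs))
  for (mod in c("structural", "functional")) {
    cat(sprintf("  %s: mean |cor| of first eigenvectors %.3f, second %.3f\n",
                mod,
                mean(x[[mod]]$evec_cor$first),
                mean(x[[mod]]$evec_cor$second)))
  }
  invisible(x)
}
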