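# Evaluation apparatus: time-series splits, order/rank sweeps, perturbation
# robustness, null-model swap report, and spectral-similarity diagnostics.

test_that("split_time_series is a shared disjoint half-split, seeded", {
  S <- simulate_structural(10, seed = 91)
  ts <- simulate_bold(S, L = 400, coupling = 0.6, seed = 92)
  sp <- split_time_series(ts, seed = 7)
  expect_length(sp$in_indices, 200)
  expect_length(sp$out_indices, 200)
  expect_identical(sort(c(sp$in_indices, sp$out_indices)), 1:400)
  sp2 <- split_time_series(ts, seed = 7)
  expect_identical(sp$in_indices, sp2$in_indices)
  expect_identical(sp$in_sample, sp2$in_sample)

  # odd length: floor(L/2) vs the rest
  ts_odd <- simulate_bold(S, L = 401, coupling = 0.6, seed = 93)
  sp3 <- split_time_series(ts_odd, seed = 1)
  expect_length(sp3$in_indices, 200)
  expect_length(sp3$out_indices, 201)

  # pooled sanity: merging the two halves reproduces the full-series matrix
  merged <- ts[, c(sp$in_indices, sp$out_indices)]
  expect_equal(correlation_matrix(merged), correlation_matrix(ts),
               tolerance = 1e-12)
})

test_that("sweep_order reports nested in-sample quality and handles k = 0", {
  sim <- suppressWarnings(
    simulate_planted_pair(n = 15, k = 3, noise_sigma = 0.02, seed = 93))
  split <- list(in_sample = sim$F,
                out_sample = sim$F + 0.01 * random_symmetric(15, seed = 94))
  tab <- suppressWarnings(sweep_order(sim$S, split, k_values = 1:6))
  expect_identical(tab$k, 1:6)
  expect_true(all(diff(tab$ucorr_in) >= -1e-12))
  expect_true(all(diff(tab$fit_residual) <= 1e-12))
  # true order 3, tiny noise: near-exact from k = 3 on
  expect_gt(tab$ucorr_in[3], 0.999)

  # exact-recovery data: ucorr hits 1 for all k >= true order
  sim0 <- suppressWarnings(simulate_planted_pair(n = 15, k = 3, seed = 95))
  split0 <- list(in_sample = sim0$F, out_sample = sim0$F)
  tab0 <- suppressWarnings(sweep_order(sim0$S, split0, k_values = 1:5))
  expect_true(all(abs(tab0$ucorr_in[3:5] - 1) <= 1e-8))

  expect_error(sweep_order(sim$S, split, k_values = 1:20), "n - 1")

  # k = 0 on a diagonal-free structure: constant mapped triangle -> NaN flag
  D <- diag(c(2, 1.5, 1, 0.5))
  splitD <- list(in_sample = diag(4) * 0.5 + 0.5, out_sample = diag(4) * 0.5 + 0.5)
  tabD <- suppressWarnings(sweep_order(D, splitD, k_values = 0))
  expect_true(is.nan(tabD$ucorr_in))
})

test_that("sweep_rank covers the rank hierarchy at fixed order", {
  sim <- suppressWarnings(simulate_planted_pair(n = 12, k = 2, seed = 96))
  split <- list(in_sample = sim$F, out_sample = sim$F)
  tab <- suppressWarnings(sweep_rank(sim$S, split, m_values = c(1, 6, 12), k = 2))
  expect_identical(tab$m, c(1L, 6L, 12L))
  expect_equal(tab$ucorr_in[3], 1, tolerance = 1e-8)
  expect_true(all(diff(tab$ucorr_in) >= -1e-10))
})

test_that("perturb_structural implements the bounded multiplicative model", {
  S <- simulate_structural(12, density = 0.5, seed = 97)
  p0 <- perturb_structural(S, rho = 0)
  expect_identical(p0$perturbed, S)

  p <- perturb_structural(S, rho = 0.1, seed = 1)
  expect_equal(p$perturbed, t(p$perturbed))
  expect_identical(p$perturbed == 0, S == 0)          # support preserved
  rel <- abs(p$perturbed - S)[S > 0] / S[S > 0]
  expect_lt(max(rel), 0.1)                            # bounded support
  expect_equal(p$delta, t(p$delta))
  expect_lt(max(abs(p$delta)), 0.1)
  p2 <- perturb_structural(S, rho = 0.1, seed = 1)
  expect_identical(p$perturbed, p2$perturbed)
  expect_error(perturb_structural(S, rho = -0.1), "rho")
})

test_that("perturbation quality is exactly 1 at rho = 0 and degrades with rho", {
  sim <- suppressWarnings(simulate_planted_pair(n = 20, k = 2, seed = 98))
  fit <- suppressWarnings(spectral_map(sim$S, sim$F, k = 2))
  expect_identical(perturbation_quality(fit, rho = 0), 1)
  med <- vapply(c(0.05, 0.2), function(rho) {
    stats::median(vapply(1:50, function(s) {
      perturbation_quality(fit, rho = rho, seed = s)
    }, numeric(1)))
  }, numeric(1))
  expect_gte(med[1], med[2])
  expect_gt(med[1], 0.9)
})

test_that("null_model_report computes all swap families with correct bookkeeping", {
  sim <- suppressWarnings(
    simulate_cohort(N = 4, n = 12, k = 2, heterogeneity = 1, seed = 99))
  models <- lapply(sim$cohort, function(subj) {
    suppressWarnings(spectral_map(subj$S, subj$F, k = 2))
  })
  nmr <- null_model_report(sim$cohort, models)
  expect_length(nmr$fs_self, 4)
  expect_length(nmr$fhat_self, 4)
  expect_length(nmr$fs_cross, 12)        # N(N-1) ordered pairs
  expect_length(nmr$fhat_cross_fi, 12)
  expect_length(nmr$fhat_cross_fj, 12)
  expect_length(nmr$ff_cross, 6)         # N(N-1)/2 unordered pairs
  expect_length(nmr$ss_cross, 6)
  expect_true(all(abs(unlist(nmr[1:7])) <= 1 + 1e-12))
  expect_identical(nmr$summary$n_pairs, c(4L, 12L, 6L, 6L, 12L, 12L, 4L))
  # noiseless planted self-mappings are perfect; swaps are not
  expect_equal(min(nmr$fhat_self), 1, tolerance = 1e-8)
  expect_gt(stats::median(nmr$fhat_self), stats::median(nmr$fhat_cross_fj))

  # identical cohort: exchangeability collapses cross and self families
  twin <- rep(list(sim$cohort[[1]]), 3)
  twin_models <- rep(list(models[[1]]), 3)
  tnmr <- null_model_report(twin, twin_models)
  expect_equal(tnmr$ss_cross, rep(1, 3))
  expect_equal(unname(tnmr$fhat_cross_fj), rep(tnmr$fhat_self[1], 6))

  expect_error(null_model_report(sim$cohort, models[1:2]), "one fitted model")
})

test_that("spectral_similarity summarizes eigenvalue spread and eigenvector alignment", {
  sim <- suppressWarnings(simulate_cohort(N = 5, n = 10, k = 1, seed = 101))
  ss <- spectral_similarity(sim$cohort)
  expect_identical(ss$n_pairs, 10L)           # 5*4/2
  expect_length(ss$structural$evec_cor$first, 10)
  expect_length(ss$functional$evec_cor$second, 10)
  expect_true(all(ss$structural$evec_cor$first >= 0))  # absolute correlations
  evq <- ss$structural$eigenvalue_quartiles
  expect_identical(evq$rank, 1:10)
  expect_true(all(evq$q1 <= evq$median & evq$median <= evq$q3))

  # identical cohort: all pairwise eigenvector correlations are 1
  twin <- rep(list(sim$cohort[[1]]), 3)
  st <- spectral_similarity(twin)
  expect_equal(st$functional$evec_cor$first, rep(1, 3))

  # shared leading eigenvector with shrinking noise aligns in the limit
  mean_cor <- vapply(c(0.2, 0.01), function(noise) {
    set.seed(5)
    base <- simulate_structural(10, density = 0.9)
    cohort <- lapply(1:4, function(j) {
      E <- matrix(rnorm(100, sd = noise), 10, 10)
      Sj <- abs(base + (E + t(E)) / 2)
      list(S = normalize_structural(Sj), F = diag(10) * 0 + diag(10))
    })
    mean(spectral_similarity(cohort)$structural$evec_cor$first)
  }, numeric(1))
  expect_gt(mean_cor[2], mean_cor[1] - 1e-12)
  expect_gt(mean_cor[2], 0.99)
})
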