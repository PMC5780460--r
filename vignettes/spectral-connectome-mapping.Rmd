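---
title: "Spectral structure-to-function connectome mapping: model, numerics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral structure-to-function connectome mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`specmap` treats the functional connectome as a spectral transform of the
structural one. Two facts motivate the parameterization. First, for a
weighted adjacency matrix $S$, the entry $[S^l]_{ij}$ equals the sum over
all walks of length $l$ from region $i$ to $j$ of the product of traversed
edge weights, so a polynomial $f(S)=\sum_{i=0}^k a_i S^i$ is precisely a
weighted aggregation of walk evidence up to length $k$. Second, functional
correlation matrices share eigen-structure with the anatomy only up to a
change of basis: co-activation patterns (functional eigenmodes) are linear
combinations of propagation patterns (structural eigenmodes). The model
composes the two stages:

$$\hat F \;=\; R\, f(S)\, R^\top, \qquad
  \min_{a,R}\ \lVert \hat F - F\rVert_F^2
  \ \ \text{s.t.}\ \ RR^\top = R^\top R = I_n .$$

Writing $S = V \Lambda V^\top$ and $F = U \Phi U^\top$ with both spectra in
decreasing order, the solution decouples: $a^\*$ solves the Vandermonde
least-squares problem $\min_a \lVert L a - \phi \rVert_2$ with
$L_{i\cdot} = (1, \lambda_i, \dots, \lambda_i^k)$, and $R^\* = U V^\top$
(orthogonal Procrustes). On the training matrix the mapped matrix is then
$\hat F = U f(\Lambda) U^\top$: the subject's functional eigenvectors
carrying polynomially transformed structural eigenvalues. The weight matrix
$W = V^\top R V$ satisfies $U = VW$, so column $i$ of $W$ gives the
decomposition of functional eigenmode $u_i$ over the structural eigenmodes.

Assumptions worth making explicit:

* **Descending pairing.** Spectra are paired by sorted position. This is the
  only pairing consistent with the Vandermonde construction when $f$ is
  increasing on the spectrum; for non-monotone relationships it is a
  modelling choice, not an optimum over permutations.
* **Reflections allowed.** The constraint set $RR^\top=R^\top R=I$ contains
  $\det R = -1$; we do not restrict the determinant, since $UV^\top$ may
  carry either sign.
* **Degenerate spectra.** Repeated eigenvalues make the within-cluster
  pairing arbitrary. `eigen_system()` warns when
  $|\lambda_i - \lambda_{i+1}| \le 10^{-10}\max|\lambda|$ and keeps the
  sorted order; no re-pairing search is attempted. Mapped matrices are
  unaffected (they depend only on eigenspaces), but $R$ and $W$ are
  basis-dependent in a degenerate cluster.

## Tunable parameters

* `k` — maximum walk length (polynomial order), dimensionless. The fit
  requires $n \ge k+1$; no regularization is applied. Empirically most of
  the attainable quality arrives by $k \approx 3$ and saturates around 8,
  which is why the examples and script sweep `1:8`.
* `m` — rotation rank, in `1..n`, default `n`. Only the leading `m`
  eigenmode pairs are freely aligned; the orthogonal complements are joined
  by deterministic orthonormal completions (trailing columns of the
  complete QR factor of $U_m$ and $V_m$). `m = n` reproduces the
  unconstrained closed form exactly. A "rank-constrained rotation" admits
  several constructions; "number of freely aligned eigenmode pairs" is this
  package's documented choice, made because it nests the full solution and
  gives a deterministic, orthogonality-preserving family to sweep.
* Group solver: `max_iter` (default 500), `tol` (relative objective
  decrease, default `1e-8`), `n_starts` (default 1, deterministic start).
* Generators: `density` (edge probability, default 0.3 — sparse but
  connected at the sizes used), `weight_law` (uniform or lognormal),
  `noise_sigma` (additive symmetric noise on planted functional matrices,
  default 0 — the exactly realizable world), `coupling` (spectral radius of
  the autoregression, default 0.5; time-series demos that need a strong
  functional signal use 0.9–0.95).

## Numerical choices

* **Least squares by QR, not normal equations.** The textbook solution
  $(L^\top L)^{-1} L^\top \phi$ squares the condition number; the package
  solves the same optimum through a QR factorization.
* **Eigenvalue conditioning.** Raw eigenvalue powers up to $k = 10$
  overflow the double mantissa's useful range. Before forming any
  Vandermonde system the eigenvalues are divided by
  `eigenvalue_scale = max(abs(lambda))` (cohort-wide maximum in the group
  fit) and coefficients are mapped back analytically
  ($a_i = \tilde a_i / s^i$) — an exact reparameterization. Coefficients are
  reported on the raw scale.
* **Sign convention.** Each eigenvector is flipped so its largest-magnitude
  entry is positive (ties: lowest index). $\hat F$ is sign-invariant, but
  $R$, $W$ and reported eigenmodes are not, so the convention makes outputs
  reproducible; cross-subject eigenvector correlations are additionally
  reported in absolute value because the convention cannot remove the
  intrinsic sign ambiguity between different matrices.
* **Boundary symmetrization.** Loaders accept relative asymmetry up to
  `1e-8`, symmetrize by averaging, and refuse anything larger: connectivity
  matrices are symmetrized upstream, and a large silent correction would
  mask data errors.
* **Degenerate sweeps.** `ucorr` is undefined for a constant upper triangle
  (possible at `k = 0`); sweeps report a flagged `NaN` instead of aborting.

## The group solver

The group problem
$\min_{c,Q} \sum_j \lVert Q\,g(\Lambda_j)\,Q^\top - F_j \rVert_F^2$ over
orthogonal $Q$ has no closed form, so the package implements a standard
alternating scheme with a provably monotone objective:

1. **c-step (exact).** The off-diagonal of $Q^\top F_j Q$ does not involve
   $c$, so the minimization reduces to stacked Vandermonde least squares of
   $\mathrm{diag}(Q^\top F_j Q)$ on each subject's eigenvalues. The design
   matrix is fixed across iterations and factorized once.
2. **Q-step (monotone descent).** The ambient gradient of the objective is
   $\sum_j 4\,(Q D_j Q^\top - F_j)\,Q D_j$; it is projected onto the tangent
   space of the orthogonal group, a step is taken, and the iterate is
   retracted by a sign-fixed QR factorization. Backtracking halves the step
   until the objective does not increase.

Initialization is deterministic: $Q_0$ = eigenvectors of the cohort-mean
functional matrix. For planted common-basis cohorts this start is already
essentially exact (the mean functional matrix shares the planted basis), so
convergence there certifies the solver's fixed point rather than its path.
The objective trace is recorded and asserted non-increasing; `n_starts > 1`
adds seeded Haar-random restarts and keeps the best optimum. The solver can
stop in a local minimum on heterogeneous cohorts — the trace and the
non-convergence warning are the honest surface of that limitation; other
iterative schemes for the same objective may reach different local optima.

## The synthetic world

The generators exist so that every operation has a ground truth:

* `simulate_structural` — Erdős–Rényi-weighted symmetric graphs, zero
  diagonal, max-normalized: the *shape* of a streamline-count matrix, not
  its empirical degree or weight distribution.
* `simulate_planted_pair` — draws $F = R_0 f(S) R_0^\top (+\text{noise})$
  with $f$ strictly increasing on the spectrum (non-negative dominant linear
  term; derivative checked on a grid; regeneration up to 10 attempts).
  Monotonicity forces the descending pairings of truth and fit to coincide,
  which is the identifiability condition behind the exact-recovery tests.
  The functional matrix is rescaled by its maximum absolute entry (truth
  coefficients rescaled identically) so it satisfies the $[-1,1]$ loader
  invariant; every tested property is invariant to that scale.
* `simulate_cohort` — heterogeneity 0 gives the exact group model class
  (shared basis and coefficients, subject-specific spectra); heterogeneity 1
  gives independent per-subject mappings; intermediate values retract
  $(1-h)Q_0 + hG_j$ back to the orthogonal group and jitter coefficients.
* `simulate_bold` — a first-order vector autoregression with coefficient
  matrix proportional to $S$, spectral radius = `coupling`. Its stationary
  covariance $\sum_m A^m (A^m)^\top$ is a walk-weighted function of the
  anatomy, which is all the evaluation layer needs. It does **not** emulate
  hemodynamics, bandpass filtering, physiological confounds, or empirical
  BOLD spectra.

Consequently a green test establishes the estimator's mathematical
contracts — exact recovery in its model class, optimality against probes,
monotone hierarchies, robustness trends — and *not* any empirical claim
about human connectome data, whose headline correlation levels depend on an
imaging pipeline outside this package's scope.

One measured caveat: with additive spectral noise the in-sample *Frobenius
residual* is guaranteed non-increasing in `k` (nested least squares), but
the in-sample `ucorr` can fluctuate at the noise floor (observed up to
$\sim 2\times 10^{-6}$ at `noise_sigma = 0.05`). The strict
machine-precision monotonicity of both quantities holds in the noiseless,
exactly realizable regime, and that is where the package asserts it.

## Evaluation conventions

* **Time-sample splitting.** One random index set of size
  $\lfloor L/2 \rfloor$ is drawn and *shared across regions*; a per-region
  independent split would destroy the temporal alignment that inter-regional
  Pearson correlation requires. The split is seeded and deterministic.
* **Perturbation analysis.** $[\check S]_{ij} = (1+[\Delta]_{ij})[S]_{ij}$
  with $\Delta$ symmetric, uniform on $(-\rho,\rho)$: sparsity-preserving,
  with expected magnitude proportional to the entry. Quality is
  $\mathrm{ucorr}(\hat F, \check F)$ with the *original* fitted parameters;
  it is exactly 1 at $\rho = 0$ and its seeded medians decrease with
  $\rho$.
* **Null models.** Six swap families quantify how subject-specific the
  fitted mapping is; ordered families ($\hat F_i^j$ against $F_i$ or
  $F_j$) have $N(N-1)$ entries, symmetric families $N(N-1)/2$. The matched
  family $\mathrm{ucorr}(\hat F_i^i, F_i)$ is reported alongside as the
  reference.

## Known limitations

* The group objective is non-convex; single-start results are deterministic
  but only locally optimal. Use `n_starts` for reassurance on real cohorts.
* Dense $O(n^3)$ eigendecompositions throughout: designed for parcellations
  up to a few hundred regions, not voxel-level graphs.
* The rank-`m` rotation family is this package's interpretation (see above);
  other constructions of a "rank-constrained rotation" exist.
* `fit_residual` includes the diagonal (it is the literal Frobenius
  objective); `ucorr` excludes it. The two quantities answer different
  questions and are deliberately not interchangeable.
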