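---
title: "Directed partial correlation: model, design choices, and benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed partial correlation: model, design choices, and benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inference problem

A gene-expression time series gives `p` genes at `m` ordered time points
with, typically, `p` in the hundreds and `m` in the tens. A directed
regulatory edge `j -> i` is taken in the Granger sense: the past of gene
`j` carries information about the present of gene `i` beyond what the past
of all other genes carries. Fitting a full VAR(1) model makes this
operational but requires `m - 1 > p + 1` observations, which short
microarray series never satisfy. `dpcnet`'s directed partial correlation
(DPC) method keeps the Granger logic but replaces model fitting with
partial-correlation estimation, which remains feasible when variables far
outnumber samples.

## Model and procedure

**Assumptions.** The series is treated as (weakly) stationary with
approximately linear, lag-`q` dependencies and Gaussian-like marginals.
Each gene is standardized to mean 0, variance 1 before estimation;
zero-variance genes are dropped with a warning and reported as `NA` in all
score matrices.

**Joint state matrix.** For lag order `q`, `build_joint_matrix()` stacks
`X(t)` over `X(t-1), ..., X(t-q)`, so a lagged dependency becomes an
ordinary partial correlation between a "past" row and a "present" row of
the joint matrix.

**Shrinkage covariance.** `shrinkage_covariance()` shrinks the sample
correlation matrix toward the identity with the analytic intensity
`lambda* = sum Var-hat(r_ij) / sum r_ij^2` (off-diagonal sums) and rescales
by the sample standard deviations; the sample covariance uses the unbiased
`n - 1` denominator. Two numerical choices matter here:

* *The intensity is capped at `1 - 1e-3`, not 1.* On data with little or
  no true correlation the analytic estimate frequently exceeds 1; clamping
  to exactly 1 returns the identity on the correlation scale, every
  partial correlation becomes exactly 0, and every downstream paired
  comparison degenerates to p = 1. The cap keeps the estimator's
  *direction* information intact; because the paired t statistic is
  scale-free, results are insensitive to the cap's exact value. A
  user-supplied `lambda = 1` still yields the exact target, which is the
  documented limiting case.
* *The target on the correlation scale is the identity* (equivalently a
  diagonal-variance target on the covariance scale after the rescaling).
  Since genes are standardized first, the two classical target choices
  coincide here; the identity-correlation form is the default and only
  implemented target.

**Leave-one-out partial correlations.** Deleting variable set `J` from the
conditioning structure is done by the Schur complement of the full
precision matrix, `P' = P_AA - P_AJ P_JJ^{-1} P_JA`, then standardizing.
Because the shrinkage intensity is *not* re-estimated on the reduced data,
the downdate is algebraically exact (it equals re-inverting the reduced
covariance, which the test suite verifies to 1e-10 on random
positive-definite matrices) and reduces the per-regulator cost from a
fresh `O(d^3)` inversion to `O(d^2)`.

**The DPC score.** For each ordered pair `j -> i`, two groups of
coefficients are compared with a paired t-test:

* *before*: target `i`'s partial correlations with every past variable
  except past-of-`j` (for DPC(0): with every other gene except `j`);
* *after*: the same coefficients after past-of-`j` is deleted.

The p-value is the directed score (small = strong evidence). The paired
t statistic uses the sample standard deviation of the differences with
`k - 1` degrees of freedom; two degenerate cases are mapped by convention,
and checked by exact zero rather than a tolerance, so that genuinely tiny
differences (which occur under heavy shrinkage) are still tested:
identical groups give p = 1 and an exactly uniform nonzero shift gives
p = 0.

## Design choices that were genuinely open

* **Magnitudes, not signed coefficients (default `use_abs = TRUE`).**
  Deleting a true regulator of gene `i` lowers the `i`-th diagonal entry
  of the precision matrix, which *rescales upward* the magnitude of every
  remaining partial correlation in row `i`; the induced signed changes
  alternate in sign across the row. Empirically (sparse stable VAR(1)
  networks, p = 50, density 0.04, m = 100) the signed comparison recovers
  no structure (mean AUC ≈ 0.51, chance level) while the magnitude
  comparison reaches mean AUC ≈ 0.82. The signed variant remains available
  via `use_abs = FALSE`.
* **Only the past copy of the regulator is deleted (default
  `delete = "past"`).** The hypothesis concerns the *past* of `j`
  predicting the *present* of `i`, mirroring how Granger arguments remove
  "the past of" a predictor; the present copy of `j` stays in the
  conditioning set. `delete = "both"` removes both copies.
* **The autoregressive term is kept** (`keep_autoregressive = TRUE`):
  past-of-`i` is itself a conditional predictor of present-of-`i` and is
  subject to the same rescaling signal, so excluding it only shrinks the
  paired groups.
* **Two-sided test by default.** The null is "deletion does not change the
  profile"; a one-sided option (`sided = "one"`) is provided for users who
  want to test the increase direction specifically.
* **Diagonal (autoregulation) excluded** from testing and from the FDR
  family by default, with a flag (`include_diagonal`) because the
  simulator's ground truth may keep autoregulatory edges.
* **SVAR significance** uses the Fisher z-transform of the cross-block
  partial correlations with effective sample size `m - 1`, feeding the
  same BH-FDR routine as DPC, so all methods share one multiple-testing
  path. (The historical implementation used an empirical-null local fdr;
  this is a deliberate simplification.)
* **GC-VAR** adopts the standard log variance-ratio
  `ln(sigma^2_without-j / sigma^2_full)`, clamped at 0, with the nested
  OLS F-test (1 and `n - p - 1` df) as companion p-value. Intercepts are
  fitted even though standardization makes them near zero: one degree of
  freedom buys robustness on non-centered input.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `q` | 1 | lag order; 1 suits short series where each transition must carry signal |
| `fdr` | 0.05 | Benjamini–Hochberg level for edge selection |
| `lambda` | analytic | shrinkage intensity; override for experiments |
| `additive_sd` | 0.3 | additive measurement-noise sd in the simulator |
| `log_sd` | 0.2 | lognormal (multiplicative) noise log-sd |
| `mix_weight` | 0.5 | weight of the multiplicative component |
| `avg_degree` | 2 | scaffold edges contributed per gene |
| `k_top` | 20 | pool size of the hub-biased subnetwork sampler |
| `spectral_radius` | 0.9 | stationarity rescaling of simulated dynamics |

Noise defaults were fixed once as microarray-plausible values; they are
deliberately *not* tuned to any benchmark outcome.

## What the synthetic benchmark emulates — and what it does not

`make_benchmark_suite()` reproduces the statistical shape of an
ODE-kinetics benchmark without its unpublished kinetics: scale-free
directed topologies (preferential attachment, hubs as regulators),
subnetworks sampled by a hub-biased random walk, **linear stochastic
dynamics** `x(t) = b + W x(t-1) + noise` with edge weights rescaled to
spectral radius 0.9, the four perturbation kinds (multifactorial baseline
jitter, knockout clamping, production-halving knockdown, dual knockout)
applied at the series start, equispaced subsampling of a 100-step grid to
21 or 100 observed points, mixed lognormal + additive measurement noise,
and per-gene standardization *after* the noise.

Because the latent dynamics are linear, the suite is kinder to
VAR-family assumptions than true nonlinear kinetics would be — though
process noise, perturbation transients, and multiplicative measurement
noise still break the exact VAR(1) likelihood. Passing benchmarks here
therefore demonstrates correct mechanics and sensible relative ordering of
methods, not performance on saturating, Hill-kinetics regulation.
Knockout/knockdown datasets can carry very little signal when the
perturbed gene has few downstream targets; this mirrors real single-
perturbation designs and is intentional. The default factorial grid
(4 sizes x 4 perturbations x 2 lengths x 5 replicates = 160 datasets) has
an optional median-latent-variance screen (`variance_quantile`), off by
default, since no principled cut is established.

## Numerical and determinism notes

* Edge lists are ordered by adjusted p, then raw p, then (regulator,
  target) lexical order — byte-identical across reruns.
* AUC is computed by the midrank (Mann–Whitney) formula; the threshold
  sweep over unique score values yields the identical trapezoidal area
  (verified to 1e-10), with midrank tie handling and linear interpolation
  for TPR at FPR 0.2.
* Score orientation (small p strong vs. large ratio strong) travels with
  the method tag so the evaluator never guesses.
* Every stochastic routine takes an explicit seed; a benchmark suite is a
  pure function of its configuration, with per-dataset seeds recorded in
  metadata.
* Test and benchmark problem sizes (p up to 500 for generation, p = 50 for
  inference benchmarks, 5–50 replicates) were chosen to exercise the
  estimators well past the `p >> m` regime while keeping the default suite
  comfortably fast on a laptop.

## Known limitations

* The paired t-test has modest power when the groups are short: with only
  a handful of genes (group length `q(p-1)` for DPC(q)) true edges
  separate from false ones only in aggregate. In a minimal two-gene toy
  (one lagged edge, four white-noise decoys, m = 100) DPC(1) orients the
  edge correctly in roughly 55–65% of replicates — better than chance but
  far from certain; with realistic autocorrelated regulators the present
  state of the regulator proxies its past and the rate improves.
* DPC p-values are calibrated under independence (verified by KS distance
  < 0.1 from uniform) but are *not* exact under strong dependence; the
  FDR-selected edge count on dense simulated systems should be read as a
  ranking cut, not a literal false-discovery guarantee.
* GC-VAR is only defined for `m - 1 > p + 1` and is refused otherwise, by
  design.
* No missing-value imputation and no detrending are provided; input series
  are assumed complete and stationary.
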