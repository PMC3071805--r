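# dpcnet

Directed gene regulatory network inference from short, high-dimensional
expression time series.

## The problem

Time-course microarray (or RNA-seq) experiments routinely measure hundreds
of genes at a few dozen time points. Classical multivariate time-series
tools — vector autoregression, Granger causality — need many more samples
than variables and cannot be fit at all in this regime, while plain
partial-correlation methods scale well but only recover *undirected*
association networks. `dpcnet` implements **directed partial correlation
(DPC)**, which combines the two ideas: small-sample shrinkage partial
correlation supplies a well-conditioned estimate of the conditional
dependence structure, and a Granger-style deletion argument orients the
edges.

## The method

For genes `X_1, ..., X_p` observed at `m` time points, stack the present
state with `q` lagged copies into the joint matrix
`Z = [X(t); X(t-1); ...; X(t-q)]`. The covariance of `Z` is estimated by
the Schäfer–Strimmer shrinkage estimator

    C = (1 - λ) S + λ T,    λ* = Σ_{i≠j} Var̂(r_ij) / Σ_{i≠j} r_ij²

(sample covariance `S`, diagonal target `T` on the correlation scale,
analytic intensity `λ*`), which is positive definite even when
`(q+1)·p ≫ m`. Inverting `C` and standardizing the negated precision
matrix gives the partial-correlation matrix `Ω` of all present and past
variables.

To score a candidate edge `j → i`, DPC deletes gene `j`'s **past** state
from the conditioning set (a Schur-complement downdate of the precision
matrix, exact and cheap) and asks whether target `i`'s profile of lagged
partial correlations changes: the coefficients linking present-`i` to
every remaining past variable are compared before vs. after deletion with
a **paired t-test** (by default on absolute magnitudes — removing a true
regulator systematically inflates the target's remaining conditional
dependencies). The p-value is the edge score; Benjamini–Hochberg FDR
selects the network at a chosen level.

The package also provides the two standard baselines for this setting —
**SVAR** (shrinkage-VAR: Fisher-z tests on the past→present cross-block of
`Ω`) and **GC-VAR** (log residual-variance ratio of nested OLS VAR(1)
fits, applicable only when `m - 1 > p + 1`) — plus ROC/AUC/max-F/TPR@FPR
evaluation against known networks, a transcription-factor hub enrichment
test (Welch–Satterthwaite on score row sums), and a reproducible synthetic
benchmark generator (scale-free topologies, knockout / knockdown /
dual-knockout / multifactorial perturbations, mixed lognormal + additive
measurement noise).

## Worked example

Simulate a 50-gene network with the built-in generator, infer it with
DPC(1), and evaluate against the ground truth:

```r
library(dpcnet)

net <- sample_subnetwork(generate_scaffold(500, avg_degree = 2, seed = 7),
                         50, seed = 7)
latent <- simulate_dynamics(net, list(kind = "multifactorial",
                                      targets = integer(0)), seed = 7)
expr <- add_noise_and_normalize(latent, length = 100, additive_sd = 0.1,
                                seed = 7)

fit <- dpcnet(expr, method = "dpc", q = 1, fdr = 0.05)
fit
#> Directed network inference fit
#>   method: DPCq (q = 1)
#>   genes: 50  time points used: 99
#>   shrinkage intensity lambda: 0.8362
#>   edges at FDR 0.05 : 558

head(summary(fit)$edges, 3)
#>   regulator target            p   adjusted_p
#> 1       g11    g45 5.787521e-10 9.398741e-07
#> 2       g11    g66 7.672441e-10 9.398741e-07
#> 3       g49    g80 3.184050e-09 2.149734e-06

roc_evaluate(fit$scores, net)
#> ROC evaluation: 90 true edges, 2360 non-edges
#>   AUC = 0.6184  max F = 0.1571  TPR@FPR0.2 = 0.3333
```

The fit prints the estimated shrinkage intensity (`λ = 0.84`: with 100
joint variables and 99 usable columns the covariance is shrunk hard toward
its target) and the number of directed edges passing the FDR cut. The
evaluation ranks all 2450 candidate edges by score and reports the area
under the ROC curve (0.62 here — this simulated series carries process
noise, measurement noise, and non-VAR perturbation structure, so it is
deliberately harder than data matching the model; on sparse stable VAR(1)
data at the same size DPC(1) reaches AUC ≈ 0.82, see below), the best
achievable F-score, and sensitivity at a 20% false-positive rate.
`coef(fit)` returns the p-value matrix (regulator rows × target columns),
`plot(fit)` the p-value histogram, and `plot(fit, truth = net)` the ROC
curve.

A thin command-line front end with `simulate` / `infer` / `evaluate` /
`benchmark` subcommands is installed at `inst/cli/dpcnet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dpcnet.R", package="dpcnet"))')" \
  infer --input expr.tsv --out run1 --method dpc --lag 1 --fdr 0.05 --seed 1
```

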