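---
title: "Kinetic models, Fisher information and the design of RNA labeling experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models, Fisher information and the design of RNA labeling experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsedesign)
```

## The model

`pulsedesign` treats a metabolic labeling experiment as a set of count
observations whose means follow first-order RNA turnover. For a gene with
degradation rate $\delta$ (per hour) and steady-state level $\mu$ (expected
reads in the total-RNA reference sample), a pulse of length $t$ gives

$$m_T = \mu, \qquad
  m_L(t) = x_L\,\mu\,(1 - e^{-\delta t}), \qquad
  m_U(t) = x_U\,\mu\,e^{-\delta t},$$

where $x_L, x_U$ are fraction normalization coefficients relative to the
total sample (fixed at 1 for the total fraction to keep the system
identifiable). A chase experiment swaps the roles of the labeled and
unlabeled expressions. When labeling is incomplete — some transcripts never
carry label even after a long pulse — the chase model gains a never-labeled
background $\mu_1$ and a labelable pool $\mu_2$ (with $\mu = \mu_1 +
\mu_2$):

$$m_U(t) = \mu_1 + \mu_2(1 - e^{-\delta t}), \qquad
  m_L(t) = \mu_2\,e^{-\delta t}.$$

Counts are Poisson or negative binomial (NB) with mean $m$ and shared size
parameter $k$, so $\mathrm{var}(X) = m + m^2/k$; small $k$ means strong
overdispersion and $k \to \infty$ recovers the Poisson. The model assumes
steady state, no cell-division dilution, no RNA maturation compartments,
and (by default) no cross-contamination between fractions; $k$ and the
normalization coefficients are treated as known constants when single-gene
uncertainty is computed, so their own estimation uncertainty is not
propagated into rate intervals.

## Information and optimal times

For independent counts the Fisher information about the kinetic parameters
is assembled from a scalar kernel — the per-observation information with
respect to the mean, $u(m) = 1/m$ (Poisson) or $k/(m(m+k))$ (NB) — and the
mean gradients:

$$I_{ab} = n \sum_{\text{samples } p}
  \frac{\partial m_p}{\partial \theta_a}
  \frac{\partial m_p}{\partial \theta_b}\, u(m_p).$$

The asymptotic variance of the maximum-likelihood rate estimator is
$(I^{-1})_{\delta\delta}$, and $1/I_{\delta\delta}$ bounds it from below,
with equality when $\delta$ is information-orthogonal to the other
parameters — which happens exactly in the Poisson ratio-preserving
(SLAMseq) case, where

$$(I^{-1})_{\delta\delta} = \frac{e^{\delta t} - 1}{\mu t^2}.$$

In the dimensionless time $\alpha = t/\tau = \delta t$ the information
terms become $\alpha^2\mu/(e^{2\alpha}-e^{\alpha})$ (labeled),
$\alpha^2 e^{-\alpha}\mu$ (unlabeled) and $\alpha^2\mu/(e^{\alpha}-1)$
(combined), and bounded scalar maximization gives the optima the package
reports:

```{r}
c(combined = optimal_alpha("slam_combined"),
  unlabeled = optimal_alpha("unlabeled_only"),
  labeled = optimal_alpha("labeled_only"))
```

Under the NB the inverse term gains a depth-independent penalty
$2(1-e^{-\delta t})^2/(kt^2)$, so sequencing deeper saturates while adding
replicates always scales the variance as $1/n$; the package exposes the
floors and ceilings (`asymptotic_limits()`) and the tradeoff surface
(`depth_vs_replicates()`). For the incomplete-labeling chase model the
dimensionless objective $I_{\delta\delta}(\alpha)\,\delta^2$ depends on
$(\mu_1, \mu_2, k)$; at $k = 10.4$, $\mu_1 = 251$, $\mu_2 = 89$ it peaks
near $\alpha = 2.9$.

A genuinely open choice here was whether the chase objective should be the
diagonal information term or the delta entry of the inverse matrix. The
diagonal term is the natural single-sample screening quantity — it bounds
the relative variance via
$\mathrm{var}(\hat\delta)/\delta^2 \ge 1/(I_{\delta\delta}\delta^2)$ — and
is the package default; `optimal_chase_time_incomplete(use_inverse = TRUE)`
computes the alternative, which accounts for uncertainty leaking from
$\mu_1, \mu_2$ and peaks at a slightly different time.

## Tunable parameters

* `delta` (1/h) and `mu` (reads): per-gene kinetics; `mu1`/`mu2` (reads)
  for incomplete labeling. All strictly positive.
* `k` (dimensionless, > 0): NB size. Defaults are never assumed — it is
  either supplied or estimated by profiling; `k = 20` is a typical bulk
  RNA-seq value and is used in the coverage studies.
* `norm_coeff` / `norm_coeffs` (dimensionless, > 0): per-(time, fraction)
  depth factors, total fixed at 1. Known (default 1), supplied, or
  estimated from the data.
* Times are hours and rates per hour throughout; nothing auto-converts
  units.
* Optimization brackets: $\alpha \in [10^{-3}, 20]$ covers every optimum
  of these objectives (they rise from 0 and decay exponentially);
  `optimize()`'s golden-section search with tolerance $10^{-8}$ gives
  $\alpha$ to well below $10^{-6}$, and each reported optimum is verified
  to be an interior stationary point.

## Fitting

`fit_kinetics()` alternates (a) per-gene maximization of the Poisson/NB
likelihood in $\log\theta$ (Nelder–Mead, box $\log\delta \in [-12, 6]$,
three starts: a method-of-moments initialization from the conditional
labeled/unlabeled split — binomial with unlabeled rate $e^{-\delta t}$ —
plus the same with $\delta$ scaled by 0.1 and 10), (b) closed-form
(Poisson) or 1-D (NB) updates of the shared normalization coefficients, and
(c) a profile update of the shared $k$ on a log grid refined by
golden-section search, until the total log-likelihood changes by less than
$10^{-6}$ (at most 200 outer iterations). Genes with all-zero rows, and
designs carrying no rate information (only $t = 0$ or total samples), are
flagged unidentifiable rather than fitted.

Wald intervals are $\hat\delta \pm z\sqrt{(I^{-1})_{\delta\delta}}$ at the
estimate. Profile intervals solve
$2[\ell(\hat\delta) - \ell_{\text{prof}}(\delta)] = \chi^2_1(0.95) = 3.84$
by stepping geometrically outward from $\hat\delta$ and root-finding on the
log scale, re-optimizing the nuisance levels at each fixed $\delta$ (a
closed form exists for Poisson pulse/chase fits, since all means are then
proportional to $\mu$). If the deviance never crosses the threshold within
$\delta \in [e^{-12}, e^{6}]$ the endpoint is reported open (`0`/`Inf`
with an `"open"` attribute) — typical for nearly fully labeled genes whose
unlabeled counts are all zero.

## Numerical choices

* $1 - e^{-\delta t}$ is always computed as `-expm1(-delta * t)`; naive
  subtraction loses precision exactly in the short-time regime the theory
  cares about.
* Samples whose mean is numerically zero (below $10^{-12}$, e.g. labeled
  at $t = 0$) contribute zero information, the continuity limit; this
  keeps $t = 0$ samples usable for estimating $\mu_1, \mu_2$.
* FIM conditioning and inversion operate on the correlation-scaled matrix
  $D^{-1/2} I D^{-1/2}$ ($D = \mathrm{diag}(I)$): with $\mu \sim 10^{10}$
  and $\delta \sim 1$ in one matrix, raw-scale condition numbers are an
  artifact of units. A scaled reciprocal condition number below $10^{-12}$
  flags the result singular, and singular fits return only the
  $1/I_{\delta\delta}$ bound.
* In the likelihood, means are floored at $10^{-10}$ so that a structural
  zero with an observed zero count contributes no spurious infinity.

## The simulator

`simulate_counts()` draws Poisson/NB counts around the kinetic means with
per-(time, fraction) coefficients, optional symmetric fraction
cross-contamination ($m_L' = (1-c)m_L + c\,m_U$ and vice versa), and
optional incomplete labeling. One global seed drives a deterministic
substream per (gene, sample) cell, so growing a panel never perturbs
existing draws — simulation output is bit-reproducible.

Generator defaults, chosen once as typical of bulk labeling experiments:
rates log-uniform on $[0.05, 2]$ h$^{-1}$ (half-lives of roughly 20 min to
14 h), levels log-normal with median 500 reads and log-sd 1, two
replicates, and — for the width study — the classic layout of total
samples at $t = 0$ plus labeled/unlabeled fractions at $\{2, 4, 8\}$ h
with depth $\mu = 10^4$ and unit coefficients under Poisson noise.

What the simulator emulates: the count-level statistical structure the
theory assumes (NB dispersion shared across genes, fraction coefficients,
contamination as mean-mixing). What it does not: read-level phenomena
(T-to-C conversion calling, alignment artifacts, 3'-end biases,
uridine-content-dependent capture), rate distributions with correlated
$\delta$–$\mu$ structure, or non-steady-state biology. Passing recovery
and coverage tests therefore validate the estimator under the model's own
assumptions, not robustness to protocol-specific artifacts.

Study sizes used by the test suite, chosen to make Monte-Carlo conclusions
stable while keeping the suite quick: 100-draw parameter grids for the
closed-form equivalences ($10^{-8}$ relative), $10^5$ NB draws per
curvature check (3 Monte-Carlo SEs), a 30-point rate grid with 10
simulation runs for the CI-width curves, 300 NB genes ($k = 20$) for the
coverage study, and 20 genes per rate for the contamination bias
directions.

## Known limitations

* All conclusions are asymptotic: the FIM describes the quadratic
  approximation of the log-likelihood, which degrades at low counts and
  extreme $\delta t$ (the profile intervals are then the honest ones).
* Uncertainty in $\hat k$ and in estimated normalization coefficients is
  not propagated into per-gene intervals.
* Cross-contamination can be simulated but is never estimated; fitting
  contaminated data with the clean model biases slow genes fast and fast
  genes slow (`contamination_bias_study()` quantifies this).
* The kinetic model is the simplest synthesis–degradation scheme; genes
  dominated by maturation delays or dilution through cell division need a
  richer model than this package provides.
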