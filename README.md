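# pulsedesign

Planning and analysis of metabolic RNA labeling experiments (4sU
pulse/chase, SLAMseq-style nucleotide conversion, biochemically separated
fractions) with asymptotic optimal-design theory.

## The problem

In a metabolic labeling experiment, nascent RNA incorporates a nucleoside
analog during a pulse of length *t*, splitting each gene's transcripts into
labeled and unlabeled pools. Under first-order kinetics with synthesis rate
*s* and degradation rate *δ*, the steady-state expression level is
*μ* = *s*/*δ* and the expected read counts are

    m_T = μ
    m_L(t) = x_L · μ (1 − e^{−δt})     (labeled)
    m_U(t) = x_U · μ e^{−δt}           (unlabeled)

with fraction normalization coefficients *x_L*, *x_U* relative to the total
sample (ratio-preserving protocols such as SLAMseq have *x_L* = *x_U*,
conveniently 1). Read counts are modelled as Poisson or negative binomial
with shared overdispersion *k* (variance *m* + *m*²/*k*).

Choosing the labeling time is a design problem: too short and the labeled
signal drowns in noise, too long and the unlabeled pool is gone. The
package computes the Fisher information matrix (FIM) *I(θ)* of any design
for *θ* = (*δ*, *μ*) — or (*δ*, *μ₁*, *μ₂*) for chase experiments with
incomplete labeling — and uses the asymptotic variance
var(*δ̂*) ≈ (*I*⁻¹)<sub>δδ</sub> to find optimal times, compare designs
across gene panels, and quantify the depth-versus-replicates tradeoff. Key
closed forms implemented and tested:

* Poisson SLAMseq: (*I*⁻¹)<sub>δδ</sub> = (e^{δt} − 1)/(μt²), minimized at
  **t\* = 1.59 τ** where τ = 1/δ; unlabeled-only and labeled-only designs
  peak at 2 τ and 0.64 τ.
* NB SLAMseq: (*I*⁻¹)<sub>δδ</sub> = (e^{δt} − 1)/(μt²) +
  2(1 − e^{−δt})²/(kt²) — an overdispersion term that no sequencing depth
  removes (floor 2δ²/k as t → 0).
* Separated fractions at infinite depth: information ceilings
  (*I_L*)<sub>δδ</sub> ≤ k/δ² and (*I_U*)<sub>δδ</sub> = t²k.
* Incomplete-labeling chase (background μ₁, labelable pool μ₂):
  m_U = μ₁ + μ₂(1 − e^{−δt}), m_L = μ₂ e^{−δt}, with a numerically found
  optimum near **2.9 τ** at the shared parameters k = 10.4, μ₁ = 251,
  μ₂ = 89.

On the estimation side, `fit_kinetics()` is a pulseR-style alternating
maximum-likelihood fitter for genes × samples count matrices: per-gene
kinetic parameters, a shared NB overdispersion *k* profiled over all genes,
and shared per-(time, fraction) normalization coefficients, with Wald and
profile-likelihood confidence intervals. A reproducible simulator generates
NB/Poisson count matrices (optionally with fraction cross-contamination)
for power, coverage and bias studies.

## Worked example

```r
library(pulsedesign)

# When should I sequence a transcript with a 1 h half-life?
half_life_to_tau(1)            # 1.442695  (characteristic time, hours)
optimal_time(half_life = 1)    # 2.299155  (SLAMseq pulse length, hours)

# Simulate a SLAMseq experiment and refit it
panel <- list(gene_kinetics(delta = 0.5, mu = 5000),
              gene_kinetics(delta = 2,   mu = 3000))
des <- slam_pulse_design(c(2, 4), n_reps = 2, t0_total = TRUE)
sim <- simulate_counts(panel, des, seed = 1)
fit <- fit_kinetics(sim$counts, sim$samples)
coef(fit)
#>          delta       mu
#> [1,] 0.4969715 4970.833
#> [2,] 1.9307052 2966.667
profile_ci(fit, "gene1")
#>     lower     upper
#> 0.4881634 0.5059063
```

The fitted rates (0.497, 1.93 per hour) recover the simulated truth (0.5,
2), and the 95% profile-likelihood interval for gene 1 covers it; at these
depths it agrees with the Wald interval to three decimals, as the quadratic
log-likelihood approximation predicts.

A thin command-line launcher drives the same functionality from YAML
configs (subcommands `optimal-time`, `evaluate`, `simulate`, `fit`, `ci`,
`bias-study`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pulsedesign.R", package = "pulsedesign"))')" config.yaml
```

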