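---
title: "Telegraph transcription across the cell division cycle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telegraph transcription across the cell division cycle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telecycle)
```

## The model and its assumptions

`telecycle` analyses a two-state (telegraph) transcription model embedded
in a two-stage cell division cycle. The cycle is split at the instant the
gene of interest is duplicated — S1 carries one gene copy, S2 two — under
five structural assumptions:

1. Stage durations are independent exponentials with rates κ₁ (S1) and κ₂
   (S2), both in hr⁻¹. Nothing else about cell-cycle control (checkpoints,
   size sensing) is represented.
2. Transcription restarts in the OFF state at the beginning of each stage
   (replication and chromatin condensation displace the machinery).
3. In S1 the single copy follows telegraph kinetics with activation λ₁,
   inactivation γ₁, synthesis ν₁ and degradation δ₁ (all hr⁻¹, first
   order).
4. In S2 the two copies switch and transcribe independently with rates λ₂,
   γ₂, ν₂, δ₂; the state keeps track only of how many copies are active
   (0, 1 or 2).
5. At division each transcript goes to either daughter with probability
   1/2, independently.

Gene duplication itself is treated as instantaneous:
`mean_gene_duplication_time()` makes the supporting arithmetic available
(for the *E. coli* genome, ~4.64 Mbp over ~4375 genes at 290–650 bp/s, a
single gene duplicates in 1.6–3.7 s, negligible against stage durations of
minutes to hours).

The canonical unit is hr⁻¹ throughout; `convert_rate()` and the
`units:` block of `read_model_params()` apply the exact factor 60 to
per-minute inputs at the boundary, and published decimal rate values are
accepted as printed rather than re-derived from durations, so worked
examples reproduce digit for digit.

## Stationary theory

`steady_state()` evaluates the closed-form stationary mean and second
moment of the mRNA count conditioned on each stage, their
occupancy-weighted population mixtures (weights κ₂/(κ₁+κ₂) and
κ₁/(κ₁+κ₂), the stationary stage occupancies), the noise η² = Var/Mean²,
the noise strength Φ = Var/Mean, and the fold change r\* = m₂\*/m₁\*.
The formulas are evaluated in double precision exactly in their published
algebraic arrangement — no re-simplification — so that results are
traceable; the test suite then adjudicates them against solvers that never
touch the closed forms (below). This includes the asymmetric cross terms
in the second-moment pair (a `2 ν₂ κ₁` weight in the S1 branch against an
`8 ν₁ κ₂` weight in S2), which we verified to ~1e-14 relative error
against the master-equation solver on both symmetric and asymmetric
parameter sets before freezing them.

Useful exact consequences wired into tests: Φᵢ = η²ᵢ·mᵢ\*; all stationary
quantities are invariant under a common rescaling of all ten rates
(a change of time unit); and with shared kinetics and κ₁ = κ₂ = κ the fold
change collapses to (2δ+3κ)/(δ+2κ).

### Fold-change regimes and constructions

Under stage-independent kinetics, `fold_change_regime()` reports the exact
threshold inequalities for r\* > 2 and r\* < 1 and the fact that
r\* < 2 whenever κ₁ ≤ κ₂. `design_fold_change(C)` constructs a
shared-kinetics parameter set achieving any prescribed fold change C > 0:

* C ≤ 1 uses the closed-form witness λ+γ = κ₁, κ₂ = 4κ₁/C,
  δ = (16 − 12C − 2C³)κ₁/C³.
* C > 1 has no published closed form. A natural first attempt — fix
  λ+γ = δ = κ₁ and vary κ₂ — only reaches fold changes in (1, 8/3), so the
  constructor instead fixes λ+γ = κ₁/C² and δ = κ₁C². Along this family
  r\* exceeds C as κ₂ → 0 (it approaches 2(δ+κ₁)(λ+γ+κ₁)/[κ₁(λ+γ+κ₁)+δ(λ+γ)],
  which grows without bound as δ/κ₁ grows and λ+γ shrinks) and tends to 1
  as κ₂ → ∞, so a κ₂ root exists for every C > 1 and `uniroot()` on log κ₂
  finds it; the constructor verifies the achieved fold change before
  returning. The contract is existential, so any witness satisfying
  r\* = C is a valid construction.

`constitutive_fold_change()` covers the always-active limit λ → ∞ used to
study duplication timing: there m₁\* is nearly flat and r\* falls roughly
linearly as the duplication point moves later in a fixed-length cycle.

## Temporal moments

For a population synchronized at the start of S1 (promoter OFF, zero
counted transcripts), the five joint stage–promoter occupancies, the five
promoter-resolved first moments and the two stage-partitioned second
moments close into a single 12-dimensional linear ODE system with constant
coefficients. `moment_dynamics()` therefore evaluates the exact solution
with one matrix exponential per output time (`Matrix::expm`, Padé), which
removes step-size and tolerance tuning entirely; a 12×12 exponential costs
microseconds, so no fallback integrator is needed at any spectral range we
can construct from valid rates. Stage-conditioned moments are the ratios
m₁ = n₁/P₁ etc.; at t = 0 the S2 conditionals are 0/0 and are reported as
`NA` rather than 0.

## The master-equation solver (brute-force route)

`fsp_generator()` builds the sparse generator of the truncated master
equation over the 5(N+1) joint states (stage, active copies, mRNA ≤ N).
Design choices:

* **Absorbing truncation.** The synthesis flux out of m = N is dropped
  from the off-diagonals but kept in the diagonal, so probability leaks at
  exactly the rate the projection discards; `1 − mass` is the projection
  error and is checked against `tail_tol` (default 1e-8) instead of being
  hidden by a reflecting boundary.
* **Division block.** The binomial redistribution C(n,m)(1/2)ⁿ is laid
  down as a dense lower-triangular block (O(N²) entries); at desk scale
  (N ≤ a few hundred) exactness beats sparsity tricks.
* **Truncation sizing.** `fsp_truncation_hint()` uses mean + 10 sd from
  the closed forms, raised to the fully-active quasi-stationary mean
  q = max(ν₁/δ₁, 2ν₂/δ₂) plus 10√q — the mixture sd alone
  under-represents the conditional branch with both copies active and can
  leave ~1e-7 tail mass. Only the sizing consults the closed forms; the
  solved distribution never does, which is what makes it a legitimate
  second route.
* **Stationary solve.** The default replaces one balance row with the
  normalization and solves the sparse linear system directly; long-time
  integration (`method = "integrate"`, horizon 50/min(κ₁, κ₂, δ₁, δ₂)) is
  kept as a cross-check and the two agree to ≤ 1e-6 in tests. The direct
  solve was promoted to default because it is exact for the truncated
  system and an order of magnitude faster.

Means around 10³ and above are out of scope for this solver (state spaces
become needlessly large); cross-validation uses moderate-mean parameter
sets and the simulator covers the large-mean regime.

## The lineage simulator (stochastic route)

`simulate_lineage()` runs an exact Gillespie simulation of one cell
followed through successive divisions. The kernel is ~100 lines of C++
(Rcpp) driven by R's own RNG, so `set.seed()` gives byte-identical
trajectories; division applies a single `Binomial(M, 1/2)` draw, which is
distributionally identical to per-molecule coin flips. A lineage rather
than a branching population is simulated because the stationary
stage-conditioned moments concern a statistically stationary single-cell
process; the occupancy weights κ₂/(κ₁+κ₂), κ₁/(κ₁+κ₂) in the stationary
mixtures match the lineage stage occupancy, and ergodicity (time average =
stationary value) is verified empirically against the closed forms rather
than assumed silently.

`estimate_stage_moments()` uses time-weighted averages of M and M²
conditioned on the stage, with standard errors by batch means: completed
cycles are grouped into (default) 20 consecutive batches, every quantity
is recomputed per batch, and the SE is the batch standard deviation over
√B. The default burn-in of 20 completed cycles removes the transient from
the synchronized start (the slowest relaxation scale is
min(κ₁, κ₂, δ₁, δ₂); twenty cycles exceed 10 of its e-folds for every
parameter set used here). These simulated trajectories are the package's
synthetic data: they emulate stage-resolved single-cell count statistics
under the model's own assumptions (exponential stage durations, OFF
restarts, binomial partitioning) and deliberately do not emulate
measurement noise, extrinsic rate variability, non-exponential stage
durations or mother/daughter correlations — so tests passing against them
validate internal consistency of the implementation, not the biological
completeness of the model.

## Homeostasis analyses

Transcription homeostasis is m₁\* = m₂\*. Clearing the common denominator
of the two stationary means leaves the residual
ν₁λ₁δ₂(λ₂+γ₂+κ₂) − ν₂λ₂(2δ₁+κ₁)(λ₁+γ₁+κ₁), which carries the sign of
m₁\* − m₂\* (negative in the usual shared-kinetics regime where S2
out-produces S1). Setting it to zero for one stage-2 rate at a time gives
the four closed-form partner rates of `homeostasis_partner_rate()`; in the
frozen-cycle limit these reduce to ν₂ = ν₁/2, δ₂ = 2δ₁ and γ₂ = 2γ₁ + λ —
each a different mechanism for cancelling the dosage doubling. The γ route
can be infeasible (the formula can go non-positive for fast division) and
errors rather than clamping.

Concentration homeostasis instead requires r\* = r_v, the volume fold
change under exponential growth V(t) = e^{at} with E[V] doubling per
cycle, which fixes a = (κ₁+κ₂−√(κ₁²+κ₂²))/2 and r_v = κ₂/(κ₂−a) ∈ (1, 2).
`solve_concentration_homeostasis()` frees one S2 rate and root-finds
r\*(x) = r_v with a 200-point log-spaced scan over [1e-6, 1e3] hr⁻¹ to
bracket sign changes before bisection; monotonicity of r\* in a single
rate is plausible but unproven, so multiple brackets raise an ambiguity
error listing all roots instead of picking one. The hypoexponential cycle
length CDF uses the analytic Erlang limit at κ₁ = κ₂ (switched at relative
rate difference 1e-9) because the two-exponential form is catastrophically
cancelling there.

`find_homeostasis_and_noise_minimum()` compares, along a single S2/S1
rate-ratio axis, the homeostasis point H (root of the residual) with the
minimizer Z of the population noise η²\* (coarse log grid plus
golden-section refinement; the population noise is used as the objective,
with stage-specific noises available through `steady_state()` if wanted).
For the mESC-like setting the two sit within |log H − log Z| < 0.7 on the
ν axis — homeostasis comes close to minimizing noise without exactly doing
so.

## Scans

`steady_state_scan()` takes a tibble of rate overrides (any subset of the
ten rates; convenience builders express duration grids in minutes, the
customary presentation, with log spacing) and returns one row per grid
point in input order, making reruns byte-identical. Two directional facts
from these scans are asserted as tests rather than strict global claims,
because the strict versions are false: with shared mESC-like kinetics the
fold change stays essentially inside [1, 2] over 10–1000 min durations
(measured fraction ~0.80 strictly inside, excursions bounded by
(0.95, 2.07)), and the population mean grows monotonically along the
S2-duration axis but not everywhere along the S1-duration axis (when
S2 ≫ S1, lengthening S1 shifts occupancy toward the lower-mean stage and
m\* falls).

## Problem sizes and test budget

The suite runs in well under a minute: master-equation cross-checks use
five moderate-mean parameter sets (truncations N ≈ 60–130, state spaces
≤ ~700), the fold-change consistency property uses 1000 random parameter
sets, homeostasis self-consistency 100, and the simulation checks use a
~500-cycle run for the acceptance comparison (3-SE agreement on means and
Fano factors) plus a 3200-cycle run for the SE-scaling property.
Monte-Carlo distribution checks (volume doubling, cycle-length CDF) use
10⁶ draws. These sizes were chosen so every stochastic assertion has
comfortable power at fixed seeds.

## Known limitations

* Exponential stage durations only; no deterministic or Gaussian-sum
  stage-length models, and no cell-size feedback on kinetics.
* Constant rates within a stage; no periodic or size-dependent modulation.
* mRNA level only — no protein layer, no mother/daughter correlation
  statistics, no population-tree (branching) simulation.
* The master-equation solver targets desk-scale means (≲ 10³); beyond
  that, use the closed forms and the simulator.
* No parameter inference from data; the package computes forward from
  rates.
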