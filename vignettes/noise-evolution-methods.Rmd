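---
title: "Modelling the evolution of gene-specific expression noise in regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of gene-specific expression noise in regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

grnoise simulates a discrete-time (Wagner-type) gene regulatory network of
`n` genes in which *both* the regulatory interactions and a per-gene
intrinsic-noise level are heritable. An individual's genotype is the pair
`(W, eta)`: `W` is the `n x n` regulatory matrix, with `w_ij` the signed
strength with which gene `j` activates (`w_ij > 0`) or represses
(`w_ij < 0`) gene `i`, and `eta_i >= 0` is the **variance** of gene `i`'s
per-step expression draw, in squared expression units.

A genotype is *realized* into a phenotype by iterating, from the basal state
`s(0) = (s_basal, ..., s_basal)`,

```
a_i(t)   = sum_j w_ij s_j(t)                       (additive regulation)
s_i(t+1) ~ Normal(s_basal + a_i(t), eta_i)          (stochastic update)
```

for `T_r` steps, with every draw hard-clamped to `[s_min, s_max]`. All genes
update synchronously from the same previous state; the steady state is
invariant to synchronous versus asynchronous updating, which the test suite
checks against an asynchronous oracle. With `eta = 0` the map is
deterministic and seed-independent. The phenotype is the state at `t = T_r`.

Additivity means no cooperative or competitive transcription-factor binding
is modelled; clamping is a hard projection onto the expression bounds, not
truncated-normal resampling, so draws that land outside the bounds pile up
mass exactly on the bound. The fraction of clamped draws is recorded on
every realization (`clampedFraction`) because it controls a bias discussed
below.

A trajectory counts as *stable* (non-oscillating) when

```
Phi(S(t)) = (1/tau) * sum_{theta = t - tau .. t} D(S(theta), S(t)) < epsilon
```

with `D` the mean absolute per-gene difference between two state vectors.
The sum runs over `tau + 1` terms including the zero `theta = t` term,
exactly as the criterion is conventionally printed; `Phi` is evaluated once,
at `t = T_r`.

Fitness under stabilizing selection is the exponential of the (negative)
mean absolute deviation from a per-gene optimum, weighted by the fitness
contribution `rho_i`:

```
F(s) = exp( - sum_i |s_opt_i - s_i| / (n * rho_i) )
```

`rho_i` divides the per-gene deviation, as the formula is literally written;
with the study default `rho = 1` the alternative reading (multiplication)
coincides, so the literal form is implemented and `rho` stays a parameter.

## The two evolutionary stages

**Stage 1 — network establishment.** Random networks realize mostly to the
expression bounds, where variance is censored, so a preliminary stage
evolves `W` toward intermediate expression. A population of `N` copies of
the founding topology undergoes, per generation: deterministic realization
(`eta = 0`), fitness toward the uniform target `s_max / 2`, fitness-
proportional (Wright–Fisher) reproduction, and regulatory mutation at rate
`mu_w` per nonzero weight (topology is never changed; no recombination).
Oscillating individuals get fitness 0 and cannot reproduce; if the entire
population oscillates the run aborts and the topology is discarded —
because the founding population is clonal, this amounts to discarding
founding topologies whose deterministic dynamics oscillate, and
`runExperiment()` logs and replaces them. The stage returns the
highest-fitness stable individual of the final generation (ties broken by
lowest index), its deterministic steady state, and the mask of genes whose
steady state is strictly inside `(s_min, s_max)`. Boundary genes stay in
the dynamics and the fitness sum (their optimum equals their boundary
steady state, so they contribute zero deviation) but are excluded from
analysis tables.

**Stage 2 — noise evolution.** The established `W` is frozen; only `eta`
evolves. The starting population is `N` copies of the founder with each
`eta_i` drawn from the mutation distribution (clamped at zero), so
generation-1 population variance is well defined. Per generation: stochastic
realization, fitness toward `s_opt` = the founder's deterministic steady
state (computed once and frozen; under the `"neutral"` mode fitness is a
constant), reproduction, eta mutation, recombination. Eta mutations
*replace* the current value with a `Normal(100, 40^2)` draw clamped at zero
— replacement is the only reading under which selection can drive `eta`
toward zero while neutrality equilibrates near the mutant mean, which is
the observed behaviour of both regimes. Recombination picks each offspring
with probability `r`, draws a uniform partner and a uniform breakpoint
`b in 1..n-1`, and swaps the eta tail beyond `b`; it conserves the per-locus
multiset of eta values, which the tests assert exhaustively. Events run in
a single pass in individual order and partners may recombine repeatedly in
one generation.

### Additive versus replacement regulatory mutations

Regulatory mutations default to **additive** `Normal(0, 2^2)` perturbations
of the current weight (`wMutKind = "additive"`). Under this reading weights
random-walk over evolutionary time and can grow large, which amplifies
propagated noise and, through clamping, biases generation-1 population
means away from the deterministic steady state; as noise is selected away
the bias fades, so per-gene mean expression in generation 1 and in the
final generation decorrelate noticeably at desk scale (the acceptance
script measures this correlation; we observe roughly 0.91–0.96 across
seeds). Under the alternative `wMutKind = "replacement"` reading the draw
replaces the weight, weights stay on the scale of the founding
`Uniform(-3, 3)` draw, clamp bias is small, and the same correlation rises
to about 0.98 — at the cost of a higher fraction of genes reaching
intermediate expression during establishment (~81% rather than ~71% at
desk scale). Both readings are one switch apart; the additive default
matches this package's documented operator contract, and the consequences
of each are stated here so users can choose deliberately.

## Parameters and defaults

| Parameter | Default | Units / meaning |
|---|---|---|
| `nGenes` | 40 | genes per network |
| `sBasal` | 20 | basal expression (expression units) |
| `sMin`, `sMax` | 0, 100 | hard expression bounds |
| `Tr` | 50 | realization steps per generation |
| `popSize` | 1000 | individuals per population |
| `generations` | 10000 | generations per stage |
| `muEta` | 0.01 | eta mutation rate, per gene per replication |
| `noiseMutMean`, `noiseMutSpread` | 100, 40 | mean, SD of the eta replacement draw |
| `muW` | 0.1 | regulatory mutation rate per nonzero weight |
| `wMutMean`, `wMutSpread` | 0, 2 | mean, SD of the regulatory mutation draw |
| `wMutKind` | `"additive"` | additive vs replacement (see above) |
| `recombRate` | 0.05 | recombination rate per offspring |
| `tau`, `epsilon` | 10, 1e-6 | oscillation window and threshold |
| `rho` | 1 | per-gene fitness contribution |
| `pressureThreshold` | 0.5 | responsiveness cut on selective pressure |
| `etaRecordStride` | 2 | record eta trajectories every 2nd generation |

`Normal(100, 40)` and `Normal(0, 2)` are read as (mean, standard
deviation); both spreads are configurable. Topologies default to 40 nodes
at directed density `d = 0.05` (`edges = round(d n (n-1))`, so 78 edges),
weights `Uniform(-3, 3)` with exact zeros redrawn, no autoregulation, and
only weakly connected skeletons are accepted (rejection sampling).
Barabási–Albert and Watts–Strogatz skeletons are built undirected with the
classic constructions tuned to the same edge-count target, adjusted to the
exact target by connectivity-preserving edge edits, then each edge is
oriented uniformly at random; the Watts–Strogatz rewiring probability
defaults to 0.1. All three models therefore match edge counts exactly, so
comparisons across topology models are density-matched.

## Outcome statistics

* **Expression variance**: per-gene sample variance (denominator `N - 1`)
  of the population's terminal expression states.
* **Relative variance change**: `(var_gen1 - var_final) / (var_gen1 +
  var_final)` in `[-1, 1]`; positive means noise was reduced. Computed per
  replicate, then averaged.
* **Selective pressure**: with `e(g)` the population mean eta of one gene
  sampled every `etaRecordStride` generations, the pressure is the mean of
  `(e(1) - e(g)) / e(1)` over sampled generations `g > 1`. The zero
  `g = 1` term is excluded (including it would rescale pressures by
  `(G-1)/G`). Pressure is averaged across replicates *first*, then a gene
  is called responsive iff the average exceeds 0.5 (strict).
* **Mutual information**: plug-in estimate in nats after equal-frequency
  binning into `ceiling(length^(1/3))` bins, ties broken by stable rank
  order; significance by Monte Carlo permutation (optionally within-network
  when group labels are given). Because the estimate depends on the binning
  rule, printed MI magnitudes are comparable only within one rule; the
  package treats MI as a directional, assumption-free complement to rank
  correlations.
* **Node strengths**: `instrength(i) = sum_j |w_ij|`,
  `outstrength(j) = sum_i |w_ij|`.
* **Graph metrics**: twelve descriptors of the unweighted directed edge
  set. Nine are standard: diameter, mean path distance (unreachable ordered
  pairs excluded, the igraph convention), Freeman centralization of
  indegree, outdegree and betweenness, a closeness centralization built
  from normalized harmonic out-closeness (harmonic scores remain finite
  under unreachability; centralization is `sum(max - x)/(n-1)`, which is 1
  on an out-star), and average total/in/out degree. The remaining three are
  configurable extras — reciprocity, global clustering of the skeleton,
  mean betweenness by default — chosen as common, non-redundant graph
  summaries; they are an explicit guess at a 12-metric panel and are kept
  out of acceptance checks.
* **Synthetic axes**: PCA on the standardized metric table (correlation
  matrix, since the metrics have incommensurate scales); zero-variance
  columns are dropped with a warning. Signs are oriented so diameter loads
  positively on PC1 and average degree positively on PC2, making PC1 a
  "synthetic diameter and centralization" axis and PC2 a "synthetic average
  degree" axis.

## Randomness and reproducibility

Every stochastic entry point takes an integer seed. Sub-streams (per
topology, stage, replicate, generation, individual) derive their seeds by a
31-bit counter-based hash (`deriveSeed`), so adding replicates or
topologies never perturbs existing streams and results are independent of
any parallel scheduling. R-level code uses R's RNG under scoped seeding
(the caller's RNG state is always restored). The batch stochastic
realization kernel consumes on the order of 10^8 Gaussian draws per run and
uses a self-contained xoshiro256++ generator with a 128-layer ziggurat
normal sampler, seeded explicitly per generation from the same derivation
chain; the sampler's moments and distribution are checked in the test suite
against R's normal quantiles. The R-level `realize()` /
`realizePopulation()` path uses R's own `rnorm` and per-individual
sub-streams, and the population wrapper is bitwise-reproducible against
single realizations under the matching sub-seed.

## What the generator does and does not emulate

The topology generator plus the two-stage engine constitute the study's
synthetic-data machinery: there is no external data. The generated networks
are density-matched random graphs with independent uniform weights — they
emulate the *statistical* setting of regulatory networks (sparse, signed,
directed, heavy-tailed under preferential attachment) but not biological
motif structure, autoregulation (deliberately absent, as it directly tunes
gene-specific noise), condition-dependent regulation, or mRNA/protein
two-stage kinetics. Passing tests therefore demonstrate properties of the
model class, not of any measured biological network.

## Numerical choices and degenerate inputs

* Clamping happens after every draw; realizations report the clamp
  fraction. Deterministic establishment also clamps, so establishment
  steady states can sit exactly on a bound — that is what the
  intermediate-expression mask records.
* Stability is judged once, at `t = T_r`; trajectories are retained only on
  request.
* Establishment tie-breaks ("highest fitness") resolve to the lowest
  individual index.
* A weight mutated exactly onto zero is nudged by machine epsilon so the
  edge set (and hence topology invariants) never changes; the event has
  probability zero but the guarantee is kept exact.
* `relativeVarianceChange(0, 0)` is undefined and returns `NA` with a
  warning; a constant vector has zero mutual information, with a warning;
  `selectivePressure` refuses a zero starting level.
* Degenerate metric tables (fewer than 3 networks, or fewer than 2 varying
  metrics) are errors; zero-variance columns are dropped with a warning.

## Problem sizes used by the tests and the acceptance script

Full-scale runs (thousands of topologies, `N = 1000`, `T = 10000`, 10 + 10
replicates) are the `"paper"` preset and are intended for long batch
execution. The test suite and the acceptance script use the `"desk"` scale,
chosen as the smallest configuration at which the qualitative contrasts are
statistically resolvable: 20 established topologies (establishment
`N = 100`, 1000 generations) and, on 10 founders, 3 selection + 3 neutral
replicates at `N = 200`, `T = 500`. At this scale the establishment stage
yields ~71% intermediate-expression genes, selection reduces per-gene
expression variance and median eta for the overwhelming majority of genes
while neutral runs show no pressure, and the rank-correlation directions
between strengths and outcomes match the full-scale study. The
generation-1-to-final mean-expression correlation is the one quantity that
is materially scale- and reading-sensitive (see the additive-versus-
replacement section above).

## Known limitations

* Intrinsic noise is a single abstract variance parameter per gene; no
  mechanistic noise decomposition (transcription/translation bursting,
  extrinsic noise) is modelled.
* The mixed-effects / logistic modelling layer of downstream analyses is
  deliberately out of scope: `buildGeneTable()` exports a model-ready tidy
  table (response, fixed effects, grouping id) for standard tools such as
  `lme4` or `nlme`.
* Under the additive mutation default, regulatory weights are unbounded and
  grow diffusively over long establishment runs; see the discussion above
  for the observable consequences and the replacement alternative.
* Haploid, unstructured, constant-size populations only; no co-evolution of
  `W` and `eta` within one stage.
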