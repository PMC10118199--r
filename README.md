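# grnoise

Forward-in-time evolutionary simulation of gene regulatory networks with
heritable, gene-specific expression noise.

Gene expression is intrinsically noisy, the noise level of a gene is
genetically encoded and therefore evolvable, and genes do not evolve in
isolation: their expression — and their noise — propagates through the
regulatory network. **grnoise** asks how stabilizing selection acting on
the *expression levels* of a whole network translates into differential
selective pressure on the *intrinsic noise* of individual genes, depending
on where they sit in the network. It is aimed at systems- and
evolutionary-biology researchers who want a tractable, fully reproducible
in-silico evolution testbed for noise-propagation questions.

## The model

A genotype is a pair `(W, η)`: a signed regulatory matrix `W = (w_ij)`
(`w_ij` = effect of gene *j* on gene *i*; positive activation, negative
repression, no autoregulation) and an intrinsic-noise vector `η`, where
`η_i` is the variance of gene *i*'s per-step expression draw. Phenotypes
arise by iterating, from a basal state, the stochastic Wagner-type map

    a_i(t)   = Σ_j w_ij s_j(t)
    s_i(t+1) ~ N( s_basal + a_i(t), η_i ),   clamped to [s_min, s_max]

for `T_r` steps; the phenotype is the final state. Fitness under
stabilizing selection is

    F(s) = exp( − Σ_i |s_i^opt − s_i| / (n ρ_i) )

Evolution proceeds in two stages: (1) **network establishment** — `W`
mutates under deterministic dynamics until genes reach intermediate
(non-boundary) steady-state expression, oscillating configurations being
discarded by the criterion Φ < ε over the last τ steps; (2) **noise
evolution** — `W` is frozen and `η` evolves under selection toward the
founder's steady state (or neutrally), with Wright–Fisher reproduction,
replacement mutations `η ← max(0, N(100, 40²))` at rate 0.01, and
tail-swap recombination at rate 0.05. Outcome statistics include per-gene
expression variance, relative variance change, a gene-level *selective
pressure* (mean normalized reduction of `η`, "responsive" if > 0.5), node
in/outstrength `Σ|w|`, twelve graph-level metrics reduced by PCA to
synthetic axes, and permutation-tested mutual information.

## Worked example

```r
library(grnoise)

graph <- generateTopology("ER", nGenes = 40, density = 0.05, seed = 7)
graph
#> WeightedDigraph: 40 genes, 78 directed edges (ER model)
#>   weights in [-2.95, 2.95]

est <- establishNetwork(graph, simulationParams(popSize = 100, generations = 500),
                        seed = 1)
est
#> EstablishmentResult: 40 genes, fitness 2.455e-12
#>   27/40 genes at intermediate expression

rec <- evolveNoise(est, simulationParams(popSize = 200, generations = 300),
                   mode = "selection", seed = 2)
rec
#> EvolutionRecord (selection): 40 genes, generations 1..300 (151 recorded)
#>   mean fitness 4.261e-05 -> 0.002695

tab <- buildGeneTable(list(net1 = rec),
                      list(net1 = nodeStrengths(est@genotype@graph)))
head(tab[order(-tab$selective_pressure),
         c("gene", "instrength", "outstrength", "variance_gen1",
           "variance_final", "selective_pressure", "responsive")], 5)
#>  gene instrength outstrength variance_gen1 variance_final selective_pressure responsive
#>    10      0.000       25.49         100.7           2.23              0.937       TRUE
#>    33     22.880        8.74         107.8           7.70              0.862       TRUE
#>    16      2.450       31.38          93.3          16.82              0.815       TRUE
#>    17      0.000       24.59         112.9          12.75              0.815       TRUE
#>     9      0.538       0.00          151.9          45.24              0.726       TRUE
```

Reading the output: of 40 genes, 27 ended strictly inside the expression
bounds after establishment and enter the analysis. After 300 generations of
stabilizing selection the population's mean fitness rose by two orders of
magnitude, per-gene expression variance collapsed (e.g. 100.7 → 2.2), and
the genes under the strongest selective pressure on their noise are
predominantly strong *regulators* (high outstrength, e.g. 25.5, 31.4,
24.6) — noise in regulators propagates downstream, so selection on the
network penalizes it most. A topology whose deterministic dynamics
oscillate makes `establishNetwork()` stop with an error;
`runExperiment()` discards and replaces such draws automatically.

End-to-end orchestration, including neutral control replicates, graph
metrics and the tidy per-gene table, is one call:

```r
bundle <- runExperiment(experimentPreset("desk", seed = 1))
```

or from the shell, `Rscript inst/scripts/grnoise-run.R --preset desk
--seed 1 --out results/`.

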