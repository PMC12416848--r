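# ecoassembly

Simulation and analysis of **eco-evolutionary community assembly** in
generalized Lotka–Volterra networks with three interaction types —
competition, consumer–resource and mutualism — under Type II saturating
functional responses.  The package is for theoretical ecologists studying
how network complexity, interaction-type composition and dynamical
stability emerge when communities are grown species by species, either by
**speciation with inheritance of interactions** or by **invasion with
random interactions**, with establishment decided by the population
dynamics themselves.

## The model

Abundances follow

$$
\dot x_i = x_i\Big(r_i - \delta n^+_i - s_i x_i - \sum_j c_{ij} x_j
 - \sum_j \frac{p^-_{ij} x_j}{1 + h_p \sum_k p^+_{jk} x_k}\Big)
 + x_i\Big(\frac{\sum_j p^+_{ij} x_j}{1 + h_p \sum_k p^+_{ik} x_k}
 + \frac{\sum_j m_{ij} x_j}{1 + h_m \sum_k m_{ik} x_k}\Big),
$$

with non-negative interaction coefficients, a cost $\delta$ per beneficial
link ($n^+_i$ = links where $i$ is consumer or mutualist), and consumer
gains capped by resource losses (conversion efficiency ≤ 1).  Species
below the extinction threshold $x_\mathrm{ext} = 10^{-6}$ are removed.
Whenever the system is at equilibrium (all relative abundance changes
< 0.01% across a check window), a candidate species is proposed and
accepted iff its per-capita growth rate at $x_\mathrm{ext}$ is positive —
one *assembly event*.  Scenario families contrast pure evolution, pure
invasion, mixtures, mutualism-free and mutualism-enforced variants, and
mid-run switches of the mutualism regime.

Analysis tools include the analytic community matrix (Jacobian) and its
eigenspectrum for linear stability, and network diagnostics: connectance,
complexity $S\cdot C$, interaction-type proportions, degree entropy,
Louvain modularity, and effective increases over Erdős–Rényi baselines of
matched size and connectance.

## Worked example

```r
library(ecoassembly)

cfg <- assembly_config("evolution", n_events = 100, seed = 42,
                       params = glv_params(t_max = 5000))
run <- run_assembly(cfg)
run
#> <assembly_run> evolution scenario, 100 events, seed 42
#> <glv_community> S = 80, event_index = 100
#>   connectance 0.242 | pairs: comp 0.08, cons 0.21, mut 0.71
#>   mean abundance 3.537

glance(run)[, c("S", "C", "SC", "prop_mut")]
#> # A tibble: 1 × 4
#>       S     C    SC prop_mut
#>   <int> <dbl> <dbl>    <dbl>
#> 1    80 0.242  19.4    0.714

spec <- eigenspectrum(jacobian_at(run$community, cfg$params))
spec
#> <eigenspectrum> S = 80, max Re(lambda) = -0.124
is_linearly_stable(spec)
#> [1] TRUE
```

After 100 speciation events the 5 founders have grown into an 80-species
community in which mutualistic pairs dominate (71% of links): ecological
selection on inherited interactions favours mutualism, which sustains both
richness and connectance, and the assembled equilibrium is linearly stable
(all eigenvalues of the community matrix in the left half-plane).

Scenario-level runs aggregate replicates with standard errors:

```r
pre <- scenario_preset("Evo", n_events = 300, n_replicates = 5, seed = 7,
                       params = glv_params(t_max = 5000))
res <- run_scenario(pre)
autoplot(res)              # mean ± SE of S, C, S·C, prop_mut vs event
final_state_scatter(res)   # per-replicate final (S, C)
```

A thin CLI over the same functions lives at `inst/cli/assemble.R`:

```sh
Rscript inst/cli/assemble.R --preset Inv-High-M --replicates 5 \
    --events 300 --seed 7 --out results/inv-high-m
```

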