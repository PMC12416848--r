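---
title: "Eco-evolutionary assembly of multi-interaction communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary assembly of multi-interaction communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ecoassembly` simulates how ecological communities are built up species by
species when population dynamics, rather than the modeller, decide which
newcomers persist.  Abundances $x_i$ of the $S$ resident species follow a
generalized Lotka–Volterra system with three interaction types:

$$
\frac{dx_i}{dt} = x_i\Big(r_i - \delta\, n^+_i - s_i x_i
 - \sum_j c_{ij} x_j
 - \sum_j \frac{p^-_{ij} x_j}{1 + h_p \sum_k p^+_{jk} x_k}\Big)
 + x_i\Big(\frac{\sum_j p^+_{ij} x_j}{1 + h_p \sum_k p^+_{ik} x_k}
 + \frac{\sum_j m_{ij} x_j}{1 + h_m \sum_k m_{ik} x_k}\Big),
$$

where $c_{ij}$, $p^{\pm}_{ij}$ and $m_{ij}$ are non-negative competition,
consumer–resource and mutualism coefficients (effect of $j$ on $i$), $r_i$
is the intrinsic growth rate and $s_i$ the intraspecific competition
strength.  Positive interactions (consumer gains and mutualistic gains)
saturate through Type II functional responses with handling/satiation times
$h_p$ and $h_m$; crucially, a resource's loss to consumer $j$ is divided by
*that consumer's* total saturated intake, so a satiated consumer exerts less
pressure.  Each beneficial link (being a consumer or a mutualist, not being
eaten) costs $\delta$ off the growth rate, creating a trade-off between
accumulating positive interactions and depending on them: $n^+_i$ counts
those links.  Species dropping below the extinction threshold
$x_\mathrm{ext}$ are removed, as are species left with no interactions
(after a burn-in of 20 assembly events).

Assembly proceeds at ecological equilibrium.  A candidate species is
proposed, placed at abundance $x_\mathrm{ext}$, and accepted only if its
instantaneous per-capita growth rate there is strictly positive; rejected
candidates are redrawn until one establishes.  Each successful
establishment is one *assembly event*, after which the system is integrated
to its next equilibrium (with any cascade of extinctions processed).

Two proposal mechanisms are contrasted:

* **Speciation (evolution).** A parent is sampled from the residents
  (uniformly, or weighted by abundance); its offspring inherits the
  parent's links, differing by $d \sim \mathrm{Uniform}\{1,\dots,\Delta\}$
  interactions split randomly between removals and creations, with
  inherited weights jittered by $\mathcal{N}(0, (0.05 w)^2)$ noise.
  Traits $r$ and $s$ are never inherited.
* **Invasion.** The newcomer links to each resident independently with
  probability $\rho \sim \mathrm{Uniform}(\rho_1, \rho_2)$, with
  interaction-type proportions drawn uniformly on the simplex (optionally
  forced mutualism-free, mutualism-heavy, or switched between regimes
  mid-run) and half-normal $|\mathcal{N}(0, \sigma^2)|$ weights.

In both mechanisms a consumer's gain on any link is capped at the
resource's loss, so biomass conversion efficiency never exceeds one.
Mixed scenarios flip a coin with probability `p_invasion` once per event.

## Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `sigma` | 0.2 | half-normal scale of new link weights (strong-interaction regime) |
| `delta` | 0.01 | growth-rate cost per beneficial link (1/time) |
| `delta_mut` | 5 | maximum link differences between parent and offspring |
| `h_m`, `h_p` | 0.1 | Type II saturation times |
| `x_ext` | 1e-6 | extinction threshold and introduction abundance |
| `rho1`, `rho2` | 0.05, 0.5 | invader connection-probability range |
| `mu_r` | 0.1 | mean intrinsic growth; sd is `0.1 * mu_r` |
| `s` | `1/LogNormal(0.1, 0.5)` | intraspecific competition (lognormal on the log scale; its inverse keeps carrying capacities order-1) |
| `n_init` | 5 | non-interacting founders, abundances uniform on [0, 0.02] |
| `eq_rel_tol` | 1e-4 | equilibrium: all relative abundance changes below 0.01% |

These defaults put the model in a high strength-to-cost regime
($\sigma/\delta = 20$) where communities are free to select the composition
of interaction types; the simulations then show mutualism being favoured,
and more strongly under speciation than invasion.

## Numerical choices

* **Integrator.** The stiff-capable `lsoda` (via `deSolve`) drives a
  compiled right-hand side with an analytic Jacobian (derived in closed
  form from the Type II terms; `jacobian_at()` exposes the same
  linearization in R, cross-checked against central finite differences
  with per-coordinate steps $\max(10^{-7}, 10^{-4} x_i)$).
* **Equilibrium and extinction.** "Successive timesteps" is made
  integrator-independent by comparing abundance vectors across windows of
  `t_check = 10` time units; extinctions are processed between windows.  A
  window in which a species was removed never counts as converged.
* **Cap on equilibration.** `glv_params()` defaults to `t_max = 1e5`; the
  scenario presets used for the reduced-scale analyses set `t_max = 5000`
  because communities that have not converged by then are in practice
  cycling, and the contract in that case is to take the current state as
  the assembly baseline rather than integrate indefinitely.  Unconverged
  events are flagged in the trajectory (`converged` column); they are rare
  (typically ~1% of events).
* **Mutation feasibility.** If the drawn difference $d$ exceeds what the
  parent's links and the unoccupied partners allow, $d$ is drawn from the
  feasible subrange instead; a community offering no feasible mutation
  yields a skip signal.  Created links go to non-parent residents, so a
  lone linkless parent admits none.
* **Louvain modularity.** `igraph`'s Louvain optimization at resolution 1,
  best of 5 restarts, seeded by the caller for determinism; on every
  fixture with at most 8 nodes it matches exhaustive partition search.
* **Degenerate draws.** $r_i$ is left untruncated (a negative draw simply
  fails to establish or grow); half-normal weights are strictly positive;
  inheritance noise is clamped at zero.

## What the simulator does and does not emulate

The generator produces the full study conditions itself — there is no
external data.  What passing tests show is therefore internal: the
dynamics match their defining equations, the assembly rules match their
contracts, and the qualitative orderings among scenario families (mutualism
selected more strongly under speciation; complexity collapsing without
mutualism; a mid-run switch-on of mutualism disrupting richness while
raising connectance; evolution relaxing the negative richness–connectance
relationship of invasion) are reproduced at reduced scale.  The model has
no space, no dispersal, no demographic noise, no trait evolution beyond
interaction rewiring, and one interaction type per species pair; none of
the conclusions should be read as claims about data from real communities.

## Scale of the shipped analyses

The reference scale is 15 replicates of 1000 assembly events per scenario,
aggregated every 50 events — an overnight computation documented here as
the optional full run (`scenario_preset()` defaults).  The package's own
analyses and tests use a reduced scale chosen once: 5 seeds × 300 events
for the trend checks (with stability assessed on those same 10 evolution
and invasion finals), and 3 seeds × 220 events in
`scripts/acceptance.R`.  Trends at this scale are qualitative orderings of
means across families, not curve values.

```{r example}
library(ecoassembly)
pre <- scenario_preset("Evo", n_events = 300, n_replicates = 5, seed = 7,
                       params = glv_params(t_max = 5000))
res <- run_scenario(pre)
autoplot(res)                     # mean ± SE trajectories
final_state_scatter(res)          # per-replicate final (S, C)

run <- res$runs[[1]]
spec <- eigenspectrum(jacobian_at(run$community, pre$config$params))
is_linearly_stable(spec)
autoplot(spec)                    # eigenvalues on the complex plane
```

## Known limitations

* Fixed-interval (pre-equilibrium) assembly integrates a fixed number of
  `t_check` windows per event; very fast schedules make the establishment
  test act on transient states, which is the point of that variant; the
  trajectory's `converged` flag is then reported `FALSE` since no
  convergence test is performed.
* Louvain is a heuristic: modularity values on large graphs are lower
  bounds, stabilized (not eliminated) by restarts.
* The effective-increase baseline skips edgeless Erdős–Rényi draws for
  modularity; at very low connectance the baseline mean is then computed
  over fewer than `n_random` graphs.
* Communities whose every founder draws a negative growth rate go extinct
  before the first event; assembly into an empty community is an error by
  design.
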