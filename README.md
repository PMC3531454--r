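# caspike

Hierarchic semi-Markov modelling of intracellular Ca²⁺ spikes.

Cellular Ca²⁺ signals are stochastic sequences of concentration spikes
built from a hierarchy of release events: single IP₃ receptor channels
open ("blips"), channel clusters open ("puffs"), and Ca²⁺-induced Ca²⁺
release escalates puffs into cell-wide spikes. Exact Markov modelling of
every binding step is intractable (the microscopic state space explodes),
and diffusion-approximation shortcuts are hard to justify when single
molecules matter. caspike instead models only the *observable* state —
the number of open clusters, `0..N` — as a semi-Markov chain whose
transitions carry non-exponential waiting-time densities, and solves the
resulting non-Markovian master equation in the Laplace domain. It is
written for modellers of cell signalling who need interspike-interval
(ISI) statistics as analytical functions of cellular parameters rather
than as expensive simulation output.

## The method in brief

Waiting times are generalized exponential (GE) densities
`f(t) = aλ e^{−λt}(1−e^{−λt})^{a−1}` with closed Laplace transform
`ψ̂(s) = a·B(1+s/λ, a)`. Conditioned waiting times for the cluster chain
are competing-risks products, e.g.

    Ψ_{i,i+1}(t) = (N−i)·ψ_op(t)·S_op(t)^{N−i−1}·S_cl(t)^i,

normalised by the condition `Σ_j ∫Ψ_ij dt = 1`. From the moment table
`m_n(i,j) = ∫ tⁿ Ψ_ij dt` the package computes, without any inverse
transform:

- **stationary occupancies** `π_i ∝ v_i τ_i` (final-value theorem; `v` the
  embedded-chain stationary vector, `τ_i` the mean sojourn),
- **first-passage / ISI moments** `⟨Tⁿ⟩ = (−1)ⁿ n! f_n` from an
  order-by-order Taylor solve of the absorbing-target flux system about
  `s = 0` (mean `T_av`, σ, CV, skewness, excess kurtosis),
- **splitting probabilities** ξ (puff → spike escalation) via the
  gambler's-ruin formula on the embedded weights.

Opening densities and their parameter maps (Hill curves in [IP₃], linear
forms in channels-per-cluster `N_ch`) are derived from the De Young–Keizer
single-channel model, lumped by subunit-count symmetry to a 330-state
channel chain. A delayed Gillespie-type simulator and a generic
inhomogeneous-Poisson spike model with refractory recovery
(`Λ(t) = Λ∞(1−e^{−ρt})`, ISI density `Λ(t)e^{−∫Λ}`) complete the toolkit.

## Worked example

```r
library(caspike)

# cluster chain at standard parameters, densities from the bundled
# De Young-Keizer parameter map
chain <- spike_chain_from_map(cell_params(), default_param_map())
fpt_moments(chain, "0", "4")
#> First-passage / ISI statistics:
#>   T_av = 3.40463 s, sd = 3.27317 s, CV = 0.9614
#>   skewness = 1.9972, excess kurtosis = 5.9885
```

The mean interspike interval at [IP₃] = 1 µM is 3.4 s with CV ≈ 1,
skewness ≈ 2 and excess kurtosis ≈ 6: under the strong time-scale
separation between rare puffs and fast excursions, the ISI distribution is
(nearly) exponential — the system waits in the ground state and each puff
either spikes quickly or collapses quickly. The splitting probability and
the generic-model approximation:

```r
xi <- coupling_from_mechanistic(chain)   # 0.793: puff -> spike probability
lam <- chain$trans[[1]][[1]]$dist$rate   # 0.388 s^-1 total puff rate
1 / (lam * xi)                           # 3.25 s: generic-model T_av
# vs the exact 3.40 s: 4.5% error from neglected failed-puff excursions
```

A stochastic cross-check and the σ–T_av moment relation:

```r
traj <- simulate_trajectory(chain, t_max = 1e4, seed = 1)
isi_statistics(extract_spikes(traj, "4"), seed = 1)   # mean 3.48 s ± 0.08

moment_relation(seq(0.005, 0.05, length.out = 8), rho = Inf)
#> sigma-T_av moment relation (rho = Inf s^-1): slope 1.000000, intercept 0 s
```

With recovery (`rho` finite) the slope drops below 1 — the global negative
feedback regularises the spike train, which is how measured moment
relations with slopes between 0.2 and 1 arise.

The end-to-end pipeline (config → chain → analytics → simulation → generic
comparison) is available as `run_pipeline(load_config("my.yaml"))` or from
the shell via `exec/caspike analyze --config my.yaml`.

## Package layout

- `R/ge-dist.R`, `R/fit-waiting-time.R` — GE/gamma/exponential densities,
  transforms, moments, fitting.
- `R/dyk-channel.R`, `R/dyk-maps.R` — De Young–Keizer channel chain,
  first-opening sampling, Hill parameter maps (`inst/extdata/` holds the
  versioned rate constants and the fitted default map).
- `R/semimarkov.R`, `R/chain.R` — conditioned waiting times, Laplace-domain
  engine, fixture chains.
- `R/simulate.R` — delayed Gillespie simulation, spike trains, ISI
  statistics.
- `R/generic.R` — the generic spike model.
- `R/config.R`, `R/pipeline.R`, `exec/caspike` — configuration, pipeline,
  CLI.

See `vignettes/hierarchic-calcium-spikes.Rmd` for the full account of the
model, its assumptions, numerical choices and limitations.
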