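---
title: "Hierarchic semi-Markov modelling of calcium spikes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchic semi-Markov modelling of calcium spikes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caspike)
```

## The model

Cellular Ca²⁺ spikes arise from a hierarchy of stochastic release events.
IP₃ receptor channels sit in clusters of a few channels on the ER membrane;
a cluster is observably *open* when at least one of its channels is open.
Opening of one cluster raises the local Ca²⁺ concentration at its
neighbours, raising their opening probability (Ca²⁺-induced Ca²⁺ release),
so a single-cluster *puff* can escalate into a cell-wide *spike* in which
all clusters open.

caspike models only the observable state — the number of open clusters,
`0..N` — as a semi-Markov chain. Microscopic gating (binding and unbinding
of IP₃ and Ca²⁺ on receptor subunits) is folded into non-exponential
waiting-time densities for the observable transitions. We use the
generalized exponential (GE) family

$$f(t) = a\lambda e^{-\lambda t}(1-e^{-\lambda t})^{a-1},$$

which for integer `a` is the law of the maximum of `a` iid exponentials,
and whose Laplace transform is the closed Beta form
$\hat\psi(s) = a\,B(1+s/\lambda,\,a)$. That closed transform is the reason
the whole analysis can stay in Laplace space.

From the per-cluster opening density `psi_open` (level-dependent: an
exponential *puff* density out of the ground state, a CICR-accelerated GE
density once a cluster is open) and the closing density `psi_close`
(GE with shape `n_ch`: the last of `n_ch` channels closing), the
*conditioned waiting times* are competing-risks products,

$$\Psi_{i,i+1}(t) = (N-i)\,\psi_{\mathrm{op}}(t)\,S_{\mathrm{op}}(t)^{N-i-1}S_{\mathrm{cl}}(t)^{i},\qquad
\Psi_{i,i-1}(t) = i\,\psi_{\mathrm{cl}}(t)\,S_{\mathrm{cl}}(t)^{i-1}S_{\mathrm{op}}(t)^{N-i},$$

with `S` the survival functions. Rows integrate to one over the possible
destinations — the `Psi_ij` are sub-densities, normalised *by the
condition*, not individually.

All outputs derive from the raw moments
$m_n(i,j) = \int t^n \Psi_{ij}(t)\,dt$:

* **Stationary occupancy** (final-value theorem of the Laplace-transformed
  flux system): $\pi_i \propto v_i \tau_i$ with `v` the stationary vector of
  the embedded jump chain `P = m_0` and $\tau_i = \sum_j m_1(i,j)$ the mean
  sojourn.
* **First-passage (ISI) moments**: with the target state absorbing, the
  Laplace transforms of the first-passage densities satisfy
  $F_i(s) = \hat\Psi_{i,T}(s) + \sum_{j\ne T}\hat\Psi_{ij}(s)F_j(s)$. We
  expand every $\hat\Psi_{ij}$ as a truncated Taylor series about `s = 0`
  (coefficients $(-1)^n m_n/n!$) and solve the linear system order by order:
  one LU factorisation of $I - P_{\neg T,\neg T}$, one triangular solve per
  order. $\langle T^n\rangle = (-1)^n n! f_n$. No inverse transform, no
  symbolic algebra; the series arithmetic is exact to truncation order, and
  only the `s = 0` derivatives are ever needed.
* **Splitting probability**: the probability that one open cluster
  escalates to all `N` open before everything closes, from the one-step
  embedded weights via the gambler's-ruin product formula. This is the
  coupling strength ξ of the generic model.

The interspike interval is the first passage from 0 to `N` with renewal at
0 (after a spike the chain relaxes and the clock restarts on the next entry
into the ground state).

## Waiting times from the De Young–Keizer model

The package derives the opening densities from the De Young–Keizer
single-channel model: each of 4 subunits occupies one of 8 states (IP₃
site, activating Ca²⁺ site, inhibitory Ca²⁺ site), a subunit is *active*
with IP₃ and activating Ca²⁺ bound and no inhibitory Ca²⁺, and a channel is
open when at least 3 of 4 subunits are active. Exploiting subunit-count
symmetry, a channel is a 330-state Markov chain; a cluster is `n_ch`
independent channels seeing the same local Ca²⁺ (a two-level step map:
`ca_base` with all clusters closed, `ca_open` otherwise). The first-opening
time of a cluster is then the minimum of `n_ch` iid phase-type channel
times, which we sample exactly by inverting the spectral survival function
$S(t) = \alpha' e^{Q_{CC}t}\mathbf 1$ (the mean is cross-checked against
the $(-Q_{CC})^{-1}$ linear solve).

Two initial-condition conventions matter:

* **Puff context** (basal Ca²⁺): the channel starts from the stationary
  distribution conditioned on being closed — interpuff semantics.
* **Successive openings** (elevated Ca²⁺): the still-closed cluster was
  equilibrated at *basal* Ca²⁺ before its neighbour opened, so the initial
  distribution is the basal conditioned-closed stationary law evolved under
  the elevated-Ca²⁺ rates. This is what produces the CICR acceleration (at
  the defaults, mean cluster opening drops from ~10 s to ~0.03 s) and the
  sharper GE shape (`a` ≈ 2.2 vs ≈ 0.9 at base). Starting instead from the
  prevailing-Ca²⁺ conditioned stationary (available via `ca_init`) would
  condition the channel into its inhibited states and suppress CICR.

`fit_parameter_maps()` sweeps IP₃ and `n_ch`, fits the per-point
first-opening samples (exponential rate at base, GE at elevated Ca²⁺), and
condenses the dependencies into Hill curves (offset 1 for the GE shape,
whose floor is the exponential case `a = 1`) and linear forms in `n_ch`.
The 1-D panels are combined multiplicatively after normalisation at the
reference point, because each panel varies one parameter with the others
held at the standard values; `n_ch` panels are only meaningful at integer
arguments.

## Parameters, units and defaults

Times are in seconds, rates in s⁻¹, concentrations in µM.

| parameter | default | meaning |
|---|---|---|
| `ip3` | 1 µM | stimulus strength |
| `ca_base` | 0.01 µM | basal local Ca²⁺ (see below) |
| `ca_open` | 0.6 µM | local Ca²⁺ with ≥ 1 cluster open |
| `n_ch` | 5 | channels per cluster |
| `lambda_cl` | 50 s⁻¹ | channel closing rate (20 ms mean open time) |
| `n_clusters` | 4 | tetrahedron arrangement; spike = all 4 open |
| `rho` | ∞ | generic-model recovery rate (∞ = no feedback) |

The basal Ca²⁺ level is experimentally undetermined and acts as the
calibration knob of any single-channel rate set: we chose `ca_base` once so
that the bundled (canonical) De Young–Keizer rates yield a cluster puff
rate of about 0.1 s⁻¹ — an interpuff interval of ~10 s, the figure measured
in SH-SY5Y cells — which lands the model in the rare-puff, strong
time-scale separation regime that the hierarchy is about. At 0.01 µM the
basal first-opening density is approximately exponential (fitted GE shape
≈ 0.9). Larger values (e.g. 0.1 µM) push the canonical rate set into a
high-open-probability regime with near-continuous puffing; `ca_base`
remains fully configurable. The closing rate of 50 s⁻¹ is a standard IP₃
receptor figure and was fixed before any downstream statistics were
inspected.

The chain's 0→1 transition uses the fitted cluster puff rate as a
per-cluster rate by default, so the total ground-state exit rate is
`n_clusters` times the map value (`puff_scope = "cell"` treats the map
value as cell-total instead — the measured interpuff interval of a cell
counts all clusters).

## The generic spike model

Under strong time-scale separation the chain spends almost all its time in
the ground state and the ISI is nearly exponential (skewness 2, excess
kurtosis 6, CV 1 — the headline analytical result, reproduced by
`scripts/acceptance.R`). The generic model exploits this: puffs form an
inhomogeneous Poisson process whose intensity recovers after each spike,
$\Lambda(t) = \big(\sum_i \xi_i\lambda_i\big)(1-e^{-\rho t})$, and each
puff is *thinned* into a spike with probability ξ — the splitting
probability computed from the mechanistic chain. The ISI density
$p(t)=\Lambda(t)e^{-\int_0^t\Lambda}$ has a closed cumulative hazard, so
moments come from quadrature of the survival function and sampling from
bisection of the hazard (a thinning sampler is kept as a cross-check).
The recovery kernel is pluggable in principle; the single-exponential
relaxation is the implemented default.

Neglecting the excursion durations of failed puffs costs, per spike, an
expected time proportional to the failed-puff count `(1−ξ)/ξ`; the
absolute error of `T_av ≈ 1/(λξ)` grows linearly in that count and the
relative error stays below 10% across the stimulation sweep at the default
closing rate (the acceptance suite recomputes this from a fresh
De Young–Keizer map fit).

## Numerical choices

* GE pdf/survival are evaluated in the log domain (`log1p`/`expm1`), so Ψ
  products of many survivals cannot underflow prematurely.
* Moment quadrature: `stats::integrate` with relative tolerance 1e-10 on
  `[0, t*]`, `t*` fixed by joint sojourn survival < 1e-16; all-exponential
  states use the closed form `m_n = r n!/R^{n+1}` instead.
* The GE mean uses the digamma identity `(ψ(a+1) − ψ(1))/λ`; transforms of
  integer shapes are validated against the finite exponential-sum
  expansion to 1e-10.
* Phase-type sampling inverts the spectral survival on a 3000-point
  geometric time grid (log-linear interpolation; inversion error ~1e-5
  relative). This draws from the same law as jump-by-jump channel
  simulation at a small fraction of the cost.
* GE maximum likelihood seeds a shape grid `{0.5, 1, 2, 4, 8, 16}` before
  BFGS on log-parameters; Hill fits multi-start over half-saturation
  candidates (the half-saturation may lie below the sampled grid when the
  curve is already saturated).
* Hazard inversion for generic-model sampling bisects to 1e-10.
* Ties in the competing-risks simulation draw are measure-zero and
  resolved by first minimum.

## What the synthetic fixtures do and do not show

Test fixtures are all-exponential chains (two-state, Erlang, random
birth-death, exponential tetrahedron) whose stationary occupancies and
first-passage moments have closed CTMC forms — they validate the engine in
the Markov limit to 1e-6 and the simulator against chi-square/KS checks.
The De Young–Keizer generator supplies the non-Markovian inputs. None of
this emulates spatial heterogeneity (cluster-specific distances and sizes),
Ca²⁺ concentration time courses, store depletion, or measured TIRF puff
data; passing tests show the mathematics of the observable-state reduction
is implemented correctly under the stated study conditions, not that those
conditions describe any particular cell type. Sweep sizes used by the
tests and the acceptance analysis: 10⁴ first-opening samples per grid
point (6 IP₃ × 5 `n_ch` grid), trajectories of 1.2×10⁴ s (~3000 spikes),
2×10⁵-walk ruin simulations.

## Known limitations

* The cluster chain assumes identical, exchangeable clusters (the
  tetrahedron); heterogeneous per-cluster rates enter only through the
  generic model's ξᵢ, λᵢ.
* Memory resets on every observable transition (semi-Markov renewal); no
  per-cluster age tracking across transitions.
* The two-level Ca²⁺ step map ignores the dependence of coupling strength
  on *how many* clusters are open beyond the first.
* With the bundled canonical rate set the calibrated coupling at standard
  parameters (ξ ≈ 0.8) is stronger than the small experimental couplings
  (ξ ~ 0.01–0.05); consequently stationary occupancy is not strictly
  decreasing in the number of open clusters, though the ground state
  dominates and the spike state stays rare. Rate sets fitted to a specific
  cell type can be swapped in through the versioned rates file.
* No inverse Laplace transform: full ISI densities are only available for
  the generic model (closed form) or by simulation.

## A worked example

```{r example, eval = FALSE}
library(caspike)

# analytic ISI statistics of the tetrahedron at standard parameters
chain <- spike_chain_from_map(cell_params(), default_param_map())
fpt_moments(chain, "0", "4")
#> First-passage / ISI statistics:
#>   T_av = 3.40463 s, sd = 3.27317 s, CV = 0.9614
#>   skewness = 1.9972, excess kurtosis = 5.9885

# simulate and compare
traj <- simulate_trajectory(chain, t_max = 1e4, seed = 1)
isi_statistics(extract_spikes(traj, "4"), seed = 1)

# generic model with feedback
moment_relation(seq(0.005, 0.05, length.out = 8), rho = 0.01)
```
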