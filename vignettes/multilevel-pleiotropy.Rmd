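---
title: "Multilevel selection, cooperation and pleiotropy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel selection, cooperation and pleiotropy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiosim)
```

# The model

`pleiosim` simulates the evolution of cooperation in populations of
cellular groups — microbial patches, biofilms, or proto-multicellular
organisms — and asks when a *pleiotropic* genetic architecture, which
couples the loss of a cooperative trait to the loss of a privately
beneficial trait, is itself favoured by selection between groups.

The model has two coupled levels:

1. **Within groups**, a finite population of cells grows logistically to a
   carrying capacity $K$ and then turns over, with birth, death and
   mutation simulated exactly as a continuous-time Markov process
   (Gillespie's Direct method).
2. **Between groups**, an infinite age-structured population of groups is
   described by a transport PDE
   $\partial_t n_k(t,y) + \partial_y n_k(t,y) = \text{births} -
   \text{deaths}$ per group type $k$, where the ageing speed is
   normalised to 1 and all newborn groups enter at age $y = 0$.

The stochastic level feeds the deterministic level: each group type's
expected development (genotype composition, group function, offspring
genotype distribution, all as functions of group age) is estimated by
averaging many replicate simulations, and those replicate-averaged
profiles parameterise the PDE's birth, death and type-transition terms.
This captures what a deterministic within-group model cannot: in a finite
group, cheater lineages arise by *rare* mutation and invade at very
different times in different replicates, so the expected invasion is
gradual rather than instantaneous.

## Cells and genotypes

Cells carry three binary traits: a cooperative trait $z_u$ (costly to the
cell, essential for group function), a private trait $z_v$ (protects the
carrying cell from death, also essential for group function), and a
pleiotropy trait $z_p$ (no direct rate effect; reshapes mutation). The
$2^3 = 8$ genotypes are labelled `g1`..`g8` in binary order with $z_u$ the
most significant bit, so `g1` = (0,0,0), `g4` = (0,1,1) (the canonical
"cheater": private trait but no cooperation), and `g8` = (1,1,1) (the
pleiotropic cooperator). Internally indices are plain integers 1..8; all
output tables carry the `g` labels.

## Within-group rates

In a group with mean trait expression $\bar z_u, \bar z_v$ and size $N$,

$$ b_i = \frac{1 - s^c z_{u,i}}{1 - s^c \bar z_u}, \qquad
   d_i = \frac{1 - s^c z_{v,i}}{1 - s^c \bar z_v}\cdot\frac{N-1}{K}. $$

Both rates are *relative to the group*: the denominators make the
population-mean birth rate 1 per cell per unit time (one expected division
per cell lifetime) and couple every cell's fate to the group composition.
Two consequences matter and are tested:

* a clonal group equilibrates where $b = d$, i.e. at $N \approx K + 1$,
  matching the reading of $K$ as the size at maturity;
* the fitness effect of a mutation, measured as
  $\ln(b_{\text{mut}}/b_{\text{wt}}) - \ln(d_{\text{mut}}/d_{\text{wt}})$,
  is exactly zero for a pleiotropic double loss (`g8` to `g1`): the birth
  advantage of dropping cooperation is cancelled by the survival penalty
  of dropping the private trait. Loss of cooperation alone is worth
  $+\ln\!\big(1/(1-s^c)\big) \approx 3$ at $s^c = 0.95$ — this asymmetry
  is the whole mechanism.

The flattened rate formulas admit other readings (e.g. products instead of
ratios); the ratio form is adopted because only it makes $K$ an
equilibrium size, keeps the mean cell life span at one time unit, and
produces the exact double-loss cancellation above. The $(N-1)$ factor
means the death rate vanishes for the last cell, so groups cannot go
extinct from within — group death is a group-level event only.

In the *control model* (`control_private = TRUE`) the cooperative trait is
replaced by a second private trait $z_w$ occupying the same slot, with
$b_i = (1 - s^c + s^c z_{w,i})/(1 - s^c + s^c \bar z_w)$: now both traits
benefit their carrier, and pleiotropy has nothing to protect. This control
separates "pleiotropy evolves because it stabilises cooperation" from
"pleiotropy evolves whenever traits are linked".

## Mutation

Per cell division, each trait independently flips active→inactive with
probability $\mu$ ($10^{-4}$ by default) and inactive→active with
probability $\nu\mu$ ($\nu = 0.01$: restoring function is much harder than
breaking it). This defines the null $8\times 8$ matrix $Q$. The
pleiotropic matrix $P$ differs only in the `g8` row: a loss-of-function
hit on either of $z_u, z_v$ takes both away together (probability
$2\mu - \mu^2$, descendant `g1`), loss of the pleiotropy trait alone has
probability $(1-\mu)^2\mu$ (descendant `g7`), and the remainder stays
`g8`. The effective kernel is the convex blend
$H = \phi P + (1-\phi) Q$, with $\phi \in [0,1]$ the strength of
pleiotropy.

Two remarks on the `g8` row of $P$, implemented exactly as specified with
no "corrected" variant: it contains no gain-of-function terms, and the
pleiotropic double loss maps to `g1` (the pleiotropy trait is lost along
with the other two) rather than to `g2`. The matrices are state- and
age-independent, so they are built once per parameter set and cached.

## Group-level dynamics

Group function is $z_f = \bar z_u \bar z_v (1 - \zeta \bar z_p)$:
multiplicative in the two functional traits (a group of half cheaters has
half function — a deliberately conservative, linear damage model) and
optionally discounted by a pleiotropy cost $\zeta$. Maturity is a step
function: groups can reproduce only from age $\alpha\lambda$ onward.
Group birth and death rates mirror the cell-level ratio form with
$\rho = 1/\lambda$:

$$ b^g_k(y) = \rho\,\frac{1 - s^g + s^g z_{r,k}(y)}{1 - s^g + s^g \bar z_r(t)},
\qquad
   d^g_k(y) = \rho\,\frac{1 - s^g z_{f,k}(y)}{1 - s^g \bar z_f(t)}, $$

with $\bar z_r, \bar z_f$ group-density-weighted population means. The
weighting is a modelling choice ("fraction of groups mature" suggests
group rather than cell weighting); with it, the population-average birth
and death rates both equal $\rho$ *identically*, so total group density is
conserved — which turns mass conservation into a sharp solver test rather
than a tuning target.

A reproducing group seeds a descendant founded by a cell drawn from it:
with probability $\gamma$ (germ-line strength) a copy of the founder
genotype passed through one round of mutation, and with probability
$1-\gamma$ a uniformly random resident cell, again mutated. For
two-founder groups the two cells are drawn independently from the same
per-cell distribution and the descendant type is their unordered pair;
the germ-line row for a mixed founder pair is defined as the average of
the two founders' mutation rows (the case is not otherwise pinned down;
it only matters for $\gamma > 0$ with two founders).

## Numerics

**Gillespie core.** 16 event channels (birth and death of each genotype),
propensities recomputed after every event because the rates are
frequency-dependent; no tau-leaping. Offspring genotypes are drawn by
inverse CDF on the cached row of $H$. The core is compiled (Rcpp), which
keeps the default acceptance workload — thousands of replicates of a
$K = 200$ group over 50 time units — in seconds.

**Random numbers.** All stochastic code uses a counter-based splitmix64
stream, never R's global RNG. Replicate $r$ of a run with master seed $s$
uses the initial state `fmix64(fmix64(s + c1) ^ fmix64(r + c2))`: both
inputs pass through the full avalanche finalizer. A cautionary note from
development: deriving replicate states by offsetting with multiples of
the generator's own additive constant makes replicate streams shifted
copies of one another wherever the offset's XOR degenerates to addition,
which showed up as replicate-averaged curves that failed to converge with
increasing replicate count. A test pins the empirical offspring
frequencies to the matrix row within binomial error, and the
replicate-averaging tests would catch a correlated-stream regression.

**Replicate averaging** interpolates each trajectory onto a shared age
grid by last-value-carried-forward between events (Gillespie event times
are irregular; the default grid spacing is 0.25 time units for
within-group analyses and the PDE cell width when profiles feed the PDE).
Whether to bin or interpolate is a free choice; LVCF is exact for a
piecewise-constant jump process.

**PDE solver.** Uniform cell-centred age grid, $\Delta y = 0.1$ by
default, truncated at $y_{\max} = 10\lambda$ with free outflow (the
neutral steady state leaves $e^{-10} \approx 5\times10^{-5}$ of mass
beyond that). Operator splitting per step: (i) conservative finite-volume
advection with a superbee flux limiter (TVD; at CFL $= 1$ it reduces to
exact translation, which the tests exploit as an oracle), then (ii)
explicit-Euler births and deaths evaluated from the same post-advection
state. Deaths are applied multiplicatively ($n \leftarrow n(1 - d\,dt)$,
so densities cannot go negative) and all births are injected into the
age-0 cell. Because both totals equal $\rho \times \text{mass} \times dt$
for the same state, the step conserves mass to round-off; the
renormalisation applied afterwards is verifiably a no-op (tested at
$10^{-6}$ per $\lambda$). The splitting is first order in $dt$: the
default CFL safety is 0.9, and the closed-form accuracy test (neutral
single-type steady state $n(y) \propto e^{-\rho y}$, $L^2$ error
$< 10^{-3}$ at $\Delta y = 0.05$) runs at CFL 0.5 where the splitting
error is comfortably below the bound. A development note: injecting
births as a boundary *flux* during advection (lagged one step) was tried
and abandoned — it broke exact conservation ($\mathcal{O}(\rho\,dt)^2$
leak per unit time) without improving the steady-state error, which is
dominated by the splitting, not by injection placement.

**Steady state** is declared when the sup-norm change of the global trait
means $(\bar z_u, \bar z_v, \bar z_p)$ over a sliding window of $5\lambda$
falls below $10^{-4}$ (default), with $t_{\max} = 10^4$; non-convergence
is reported and the final state still returned. The paper-scale
experiments start from all mass in trait-less (`g1`) groups at age 0, so
cooperation must *evolve* through rare gain-of-function mutations before
it can be stabilised.

# What the generator emulates — and what a green test establishes

The within-group simulator *is* the data-generating model: there is no
external data, and every "fixture" is generated by code at test time.
The defaults are the standard parameter set ($s^c = s^g = 0.95$,
$\lambda = 20$, $K = 200$, $\mu = 10^{-4}$, $\nu = 0.01$, all variant
switches off). What the model deliberately does not represent: spatial
structure within groups, explicit public-good concentrations, resource
dynamics, finite group numbers (the PDE is the infinite-population
limit — there is no between-group drift), and any within-lifetime trait
plasticity. A green steady-state test therefore establishes directional
claims about this idealised world — e.g. that steady-state cooperation
under $\phi = 1$ strictly exceeds that under $\phi = 0$ for long-lived
groups — not quantitative predictions for any real system.

Monte-Carlo accuracy enters only through the replicate count. Acceptance
runs use 1,000 replicates for invasion timings (the paper-scale default
is 10,000) and 200 replicates per group type at $\Delta y = 0.2$ for the
steady-state sweeps; the directional gaps being tested (e.g. 0.79 vs 0.98
in global cooperation at $\lambda = 20$) are an order of magnitude larger
than the profile noise at those settings.

# Oracles and validation choices worth recording

* **Mutation kernel**: checked entrywise against an independently coded
  per-trait channel enumeration at $10^{-15}$, and the `g8` row of $P$
  against direct substitution into its printed closed form.
* **Clonal growth**: the replicate-mean size under $\mu = 0$ is *not*
  within Monte-Carlo error of the deterministic logistic — starting from
  one cell, the mean lags the ODE systematically (by several cells in the
  steep phase). The honest oracle averages the logistic over the
  stochastic takeoff factor $W \sim \mathrm{Exp}(1)$ of the near-Yule
  early phase ($N e^{-y} \to W$), which matches the simulation to a few
  percent; the stationary mean is additionally required to sit in
  $K \pm 3\sqrt K$.
* **Neutral mutation flow**: with $s^c = 0$, mean genotype frequencies
  obey $\dot x = x(H - I)$; the test integrates this ODE independently
  and compares at elevated $\mu$ so the signal beats sampling noise.
* **Invasion timing**: the headline within-group result — the mean
  cheater frequency ($z_u = 0$ genotypes) crossing 25% near age 25
  without pleiotropy, near age 40 at $\phi = 0.5$, and not within 50 time
  units at $\phi = 1$ — is reproduced at 1,000 replicates with a
  $\pm 20\%$ band. The crossing age is linearly interpolated between grid
  ages.

# Known limitations

* The PDE solver is first-order accurate in time through the source
  splitting; halve the CFL safety (or $\Delta y$) for accuracy-critical
  work.
* Two-founder sweeps are supported but expensive (36 types, and a
  $36^2$ offspring kernel per age cell in the PDE inner loop).
* Profiles are cached by exact parameter match (content-addressed key),
  so a sweep over continuous parameter values never shares profiles
  between grid points.
* The fraction-of-groups-mature and mean-function normalisers are
  group-density weighted; cell-weighted alternatives would change the
  rates only when group sizes differ strongly between types, but this
  sensitivity has not been mapped.

# A worked within-group run

```{r example, eval = FALSE}
library(pleiosim)
p <- model_params(phi = 0)          # no pleiotropy
prof <- group_profile(8, p, n_replicates = 1000, horizon = 50, seed = 1)
cheater_crossing_age(prof)          # ~22 time units
p1 <- model_params(phi = 1)         # full pleiotropy
prof1 <- group_profile(8, p1, n_replicates = 1000, horizon = 50, seed = 1)
cheater_crossing_age(prof1)         # Inf: no invasion within the horizon
```
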