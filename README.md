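# pleiosim

Multilevel selection dynamics of cooperation and pleiotropy in cellular
groups.

## The problem

Cooperation in cellular groups — microbial colonies, biofilms, simple
multicellular organisms — is threatened from within: even a group founded
by a single cooperative cell accumulates mutant "cheater" lineages that
enjoy the group's benefits without paying cooperation's cost, and these
lineages outgrow their neighbours. One candidate defence is a
**pleiotropic genetic architecture** that couples the cooperative trait to
a privately beneficial trait, so that a mutation knocking out cooperation
also knocks out something the cell needs itself. `pleiosim` implements an
age-structured multilevel-selection model to ask when such pleiotropy
evolves, and how much cooperation it rescues. It is aimed at theoreticians
in social evolution and anyone who wants a worked example of embedding
stochastic within-group simulations inside a deterministic between-group
population model.

## The model in brief

Cells carry three binary traits `(z_u, z_v, z_p)` — cooperative, private,
pleiotropy — giving 8 genotypes `g1..g8`. Within a group of size `N` with
mean trait expression `z̄_u, z̄_v`, cell birth and death rates are

    b_i = (1 - s_c z_u,i) / (1 - s_c z̄_u)
    d_i = (1 - s_c z_v,i) / (1 - s_c z̄_v) * (N - 1) / K

so groups grow logistically to the carrying capacity `K` and then turn
over. Mutation per division flips traits independently (loss rate `mu`,
gain rate `nu*mu`), except that in a fully active `g8` cell a
loss-of-function hit is pleiotropic with probability `phi`, removing the
cooperative and private traits together. Within-group dynamics are exact
Gillespie simulations averaged over replicates.

Between groups, the relative density `n_k(t, y)` of type-`k` groups aged
`y` obeys a transport PDE with group-level births and deaths:

    b_k = rho (1 - s_g + s_g z_r,k) / (1 - s_g + s_g z̄_r)
    d_k = rho (1 - s_g z_f,k) / (1 - s_g z̄_f),       rho = 1/lambda

where group function `z_f = z̄_u z̄_v (1 - zeta z̄_p)` and maturity
`z_r = 1{y >= alpha*lambda}`. Newborn groups enter at age 0 with a founder
cell sampled from the parent (optionally through a germ line of strength
`gamma`). The PDE is advanced by a conservative finite-volume scheme with
a superbee flux limiter. See `vignettes/multilevel-pleiotropy.Rmd` for the
full account of the model, numerics and validation oracles.

## Worked example

How fast do cheater lineages (genotypes with `z_u = 0`) take over a group
founded by a single fully active cell, as a function of the strength of
pleiotropy?

```r
library(pleiosim)
for (phi in c(0, 0.5, 1)) {
  prof <- group_profile(8, model_params(phi = phi),
                        n_replicates = 1000, horizon = 50, seed = 1)
  cat(sprintf("phi = %3.1f  crossing age = %s\n", phi,
              format(cheater_crossing_age(prof))))
}
```

```
phi = 0.0  crossing age = 22.34576
phi = 0.5  crossing age = 35.29442
phi = 1.0  crossing age = Inf
```

Without pleiotropy the mean cheater frequency reaches 25% of the group by
age ~22; intermediate pleiotropy delays that to ~35; full pleiotropy
prevents it within the 50-unit horizon entirely (`Inf`), because every
loss of cooperation in a `g8` cell drags the private trait down with it
and the mutant gains nothing.

Does pleiotropy then evolve by between-group selection? A reduced
steady-state comparison at `K = 200`, `lambda = 20` (long-lived groups,
cooperation under threat):

```r
p0 <- model_params(phi = 0); p1 <- model_params(phi = 1)
ag <- age_grid(20, dy = 0.2)
for (p in list(p0, p1)) {
  profs <- compute_profiles(p, ag, n_replicates = 200, seed = 11)
  ss <- run_to_steady_state(p, profs, ag, t_max = 4000)
  fin <- ss$summaries[nrow(ss$summaries), ]
  cat(sprintf("phi = %g  z_u = %.3f  z_v = %.3f  z_p = %.3f\n",
              p$phi, fin$z_u, fin$z_v, fin$z_p))
}
```

```
phi = 0  z_u = 0.788  z_v = 1.000  z_p = 0.000
phi = 1  z_u = 0.977  z_v = 0.977  z_p = 0.973
```

Starting from a population of trait-less groups, with effective pleiotropy
(`phi = 1`) the pleiotropy trait itself sweeps to high frequency
(`z_p = 0.97`) and global cooperation settles markedly higher (0.98 vs
0.79). Run times: seconds for the first example, ~10 s per steady-state
point on one CPU.

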