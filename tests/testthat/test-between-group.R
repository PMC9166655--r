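test_that("advection at CFL 1 is an exact one-cell translation", {
  d <- matrix(0, 100, 2)
  d[20, 1] <- 3; d[21, 1] <- 5; d[50, 2] <- 1
  a <- advect_age_step(d, dy = 0.1, dt = 0.1)
  expect_equal(a$density[21, 1], 3)
  expect_equal(a$density[22, 1], 5)
  expect_equal(a$density[51, 2], 1)
  expect_equal(sum(a$density), sum(d))  # mass preserved exactly
  expect_equal(a$outflow, 0)
})

test_that("advection is conservative and TVD at CFL < 1", {
  set.seed(42)  # shaping the fixture only; the solver itself is deterministic
  d <- matrix(0, 200, 1)
  d[40:60, 1] <- runif(21, 0, 2)   # rough profile exercises the limiter
  d[100, 1] <- 5                    # sharp spike
  cur <- d
  for (s in 1:50) {
    nxt <- advect_age_step(cur, dy = 0.1, dt = 0.09)
    expect_equal(sum(nxt$density) * 0.1 + nxt$outflow, sum(cur) * 0.1,
                 tolerance = 1e-12)
    expect_lte(total_variation(nxt$density[, 1]),
               total_variation(cur[, 1]) + 1e-12)
    cur <- nxt$density
  }
  # pulse has moved by 50 * 0.09 = 4.5 age units (centre of mass)
  y <- (seq_len(200) - 0.5) * 0.1
  com0 <- sum(y * d[, 1]) / sum(d[, 1])
  com1 <- sum(y * cur[, 1]) / sum(cur[, 1])
  expect_equal(com1 - com0, 4.5, tolerance = 0.05)
  # a constant profile is invariant away from the boundaries
  cst <- matrix(1, 50, 1)
  a <- advect_age_step(cst, dy = 0.1, dt = 0.09)
  expect_equal(a$density[2:50, 1], rep(1, 49))
  expect_error(advect_age_step(cst, dy = 0.1, dt = 0.2), "CFL")
})

test_that("source/sink step: balance, placement and degenerate cases", {
  p <- model_params(s_g = 0, lambda = 10)
  n <- 50
  dens <- matrix(0, n, 2); dens[5, 1] <- 2; dens[9, 2] <- 1
  zr <- matrix(1, n, 2); zf <- matrix(0.5, n, 2)
  Hg <- array(0, dim = c(n, 2, 2))
  Hg[, 1, 1] <- 1; Hg[, 2, 2] <- 1   # type-faithful reproduction
  # dt = 0 is the identity
  r0 <- apply_sources_sinks(dens, dy = 0.1, dt = 0, zr, zf, Hg, p)
  expect_equal(r0$density, dens)
  # with s_g = 0 births balance deaths exactly (normalised rates)
  r <- apply_sources_sinks(dens, dy = 0.1, dt = 0.05, zr, zf, Hg, p)
  expect_equal(r$births, r$deaths, tolerance = 1e-12)
  expect_equal(sum(r$density), sum(dens), tolerance = 1e-12)
  # births land only in the age-0 cell, by ancestral type
  delta <- r$density - dens * (1 - (1 / 10) * 0.05)
  expect_true(all(abs(delta[-1, ]) < 1e-14))
  expect_equal(delta[1, 1] / delta[1, 2], 2, tolerance = 1e-9)
})

test_that("neutral single-type steady state matches rho * exp(-rho y)", {
  lambda <- 5
  ag <- age_grid(lambda, dy = 0.05)
  n <- length(ag$centers)
  dens <- matrix(0, n, 1); dens[1, 1] <- 1 / ag$dy
  zr <- matrix(1, n, 1); zf <- matrix(1, n, 1)
  Hg <- array(1, dim = c(n, 1, 1))
  dt <- 0.5 * ag$dy   # splitting is first order in dt; CFL 0.5 for accuracy
  res <- pleiosim:::pde_advance_cpp(dens, ag$dy, dt, round(200 / dt),
                                    zr, zf, as.numeric(Hg),
                                    1 / lambda, 0, TRUE)
  exact <- (1 / lambda) * exp(-ag$centers / lambda)
  l2 <- sqrt(sum((res$density[, 1] - exact)^2) * ag$dy)
  expect_lt(l2, 1e-3)
  expect_true(all(res$density >= 0))
})

test_that("total density is conserved under normalised rates", {
  # renormalisation off: mass must stay 1 to <= 1e-6 per lambda on its own
  lambda <- 20
  ag <- age_grid(lambda, dy = 0.1)
  n <- length(ag$centers)
  dens <- matrix(0, n, 2); dens[1, 1] <- 0.7 / ag$dy; dens[1, 2] <- 0.3 / ag$dy
  zr <- matrix(1, n, 2)
  zf <- matrix(rep(c(0.2, 0.9), each = n), n, 2)  # unequal death rates
  Hg <- array(0, dim = c(n, 2, 2)); Hg[, 1, 1] <- 1; Hg[, 2, 2] <- 1
  dt <- 0.09
  nsteps <- round(2 * lambda / dt)
  res <- pleiosim:::pde_advance_cpp(dens, ag$dy, dt, nsteps, zr, zf,
                                    as.numeric(Hg), 1 / lambda, 0.95, FALSE)
  mass <- sum(res$density) * ag$dy + res$outflow
  expect_lt(abs(mass - 1), 2 * 1e-6)          # 1e-6 per lambda over 2 lambda
  expect_lt(res$max_mass_step_dev, 1e-9)
})

test_that("global summaries: weighting contracts on synthetic profiles", {
  ag <- age_grid(5, dy = 1, ymax_mult = 2)  # 10 cells
  n <- length(ag$centers)
  mk <- function(founder, tra, N) {
    tm <- matrix(tra, 3, n, dimnames = list(c("z_u", "z_v", "z_p"), NULL))
    fr <- matrix(0, 8, n, dimnames = list(paste0("g", 1:8), NULL))
    fr[founder, ] <- 1
    structure(list(age_grid = ag$centers, mean_trait = tm, mean_freq = fr,
                   mean_N = rep(N, n), zf = tm[1, ] * tm[2, ],
                   zr = rep(1, n), founders = founder, n_replicates = 1L),
              class = "group_profile")
  }
  profs <- list(mk(1, 0, 10), mk(8, 1, 10))
  dens <- matrix(0, n, 2); dens[1, ] <- c(1, 1)  # equal masses
  pop <- structure(list(density = dens, grid = ag, time = 0),
                   class = "pleio_population")
  s <- global_trait_averages(pop, profs)
  expect_equal(s$z_u, 0.5)
  expect_equal(unname(s$freq["g8"]), 0.5)
  expect_equal(s$zbar_f, 0.5)
  # doubling one type's group size shifts the cell-weighted mean
  profs2 <- list(mk(1, 0, 10), mk(8, 1, 20))
  s2 <- global_trait_averages(pop, profs2)
  expect_equal(s2$z_u, 20 / 30)   # direct weighted-sum oracle
  expect_equal(s2$zbar_f, 0.5)    # group-density weighting unchanged
  # mutational load: founder trait minus current trait, density-weighted
  expect_equal(unname(mutational_load(pop, profs)), c(0, 0, 0))
  profs3 <- list(mk(1, 0, 10), mk(8, 0.75, 10))  # g8 groups lost 0.25
  expect_equal(unname(mutational_load(pop, profs3)),
               c(0.125, 0.125, 0.125))
})

test_that("mutational load is zero without mutation and at age zero", {
  p <- model_params(mu = 0, lambda = 5)
  ag <- age_grid(p$lambda, dy = 0.5, ymax_mult = 4)
  profs <- compute_profiles(p, ag, n_replicates = 20, seed = 8)
  pop <- init_population(group_types(1), ag)   # all mass at age 0
  expect_equal(max(abs(mutational_load(pop, profs))), 0)
  # spread mass over ages: still zero because mu = 0
  pop$density[] <- 1
  expect_equal(max(abs(mutational_load(pop, profs))), 0)
})

test_that("group-level rates: normalisation endpoints and hand arithmetic", {
  p <- model_params(s_g = 0.95, lambda = 20, alpha = 0.5)
  rho <- 1 / 20
  # a mature group in a population with half the groups mature
  expect_equal(group_birth_rate(1, 0.5, p), rho * 1 / 0.525)
  expect_equal(group_death_rate(0, 0.5, p), rho * 1 / 0.525)
  p0 <- model_params(s_g = 0, lambda = 20)
  expect_equal(group_birth_rate(0, 0.9, p0), rho)
  expect_equal(group_death_rate(0.3, 0.9, p0), rho)
  # alpha = 0: everyone mature, numerator equals denominator
  expect_equal(group_birth_rate(1, 1, p), rho)
  expect_equal(group_death_rate(1, 1, p), rho)
})

test_that("trivial steady state: nothing moves without mutation/selection", {
  p <- model_params(s_g = 0, mu = 0, lambda = 5)
  ag <- age_grid(p$lambda, dy = 0.25, ymax_mult = 4)
  profs <- compute_profiles(p, ag, n_replicates = 10, seed = 4)
  ss <- run_to_steady_state(p, profs, ag, t_max = 200)
  fin <- ss$summaries[nrow(ss$summaries), ]
  expect_equal(fin$z_u, 0); expect_equal(fin$z_v, 0); expect_equal(fin$z_p, 0)
  expect_equal(fin$g1, 1)
  expect_equal(fin$mass, 1, tolerance = 1e-9)
})
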