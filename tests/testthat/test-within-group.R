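test_that("cell birth rate: frequency-dependent ratio form", {
  p <- quick_params()  # s_c = 0.95
  clonal8 <- c(0, 0, 0, 0, 0, 0, 0, 200)
  expect_equal(cell_birth_rate(8, clonal8, p), 1)
  p0 <- quick_params(s_c = 0)
  for (i in 1:8) expect_equal(cell_birth_rate(i, clonal8, p0), 1)
  # 50% g8 / 50% g4: zbar_u = 0.5; hand arithmetic on the ratio form
  half <- c(0, 0, 0, 100, 0, 0, 0, 100)
  expect_equal(cell_birth_rate(8, half, p), 0.05 / 0.525)
  expect_equal(cell_birth_rate(4, half, p), 1 / 0.525)
  expect_error(cell_birth_rate(1, rep(0, 8), p), "empty group")
})

test_that("control model: second private trait raises the birth rate", {
  p <- quick_params(control_private = TRUE)
  half <- c(0, 0, 0, 100, 0, 0, 0, 100)  # zbar_w = 0.5
  # b_i = (1 - s_c + s_c z_w,i) / (1 - s_c + s_c zbar_w)
  expect_equal(cell_birth_rate(8, half, p), 1 / 0.525)
  expect_equal(cell_birth_rate(4, half, p), 0.05 / 0.525)
})

test_that("cell death rate: crowding with extinction protection", {
  p <- quick_params(K = 200)
  single <- c(1, 0, 0, 0, 0, 0, 0, 0)
  for (i in 1:8) expect_equal(cell_death_rate(i, single, p), 0)  # N = 1
  clonal <- c(0, 0, 0, 0, 0, 0, 0, 201)  # N = K + 1, clonal g8
  expect_equal(cell_death_rate(8, clonal, p), 1)  # balances birth rate 1
  p0 <- quick_params(s_c = 0, K = 200)
  mixed <- c(50, 0, 0, 0, 0, 0, 0, 51)
  for (i in c(1, 8))
    expect_equal(cell_death_rate(i, mixed, p0), 100 / 200)
})

test_that("fixed seed gives bit-identical trajectories", {
  p <- quick_params(K = 50)
  a <- simulate_group(8, p, horizon = 10, seed = 123)
  b <- simulate_group(8, p, horizon = 10, seed = 123)
  expect_identical(a$mean_counts, b$mean_counts)
  d <- simulate_group(8, p, horizon = 10, seed = 124)
  expect_false(identical(a$mean_counts, d$mean_counts))
})

test_that("clonal growth without mutation approaches the logistic", {
  K <- 60
  p <- quick_params(mu = 0, K = K)
  prof <- group_profile(8, p, n_replicates = 300, horizon = 25, seed = 3)
  expect_true(all(prof$mean_counts[c(1:7), ] == 0))  # stays clonal g8
  # oracle: the logistic solution dN/dy = N (1 - (N-1)/K) averaged over the
  # stochastic takeoff factor W ~ Exp(1) of the near-Yule early phase
  # (N e^{-y} -> W), evaluated by quadrature over Exp(1) quantiles
  orac <- takeoff_logistic_oracle(K, prof$age_grid)
  expect_true(all(abs(prof$mean_N - orac) < 0.1 * orac + 2))
  # stationary mean within K +/- 3 sqrt(K)
  final <- prof$mean_N[length(prof$mean_N)]
  expect_gt(final, K - 3 * sqrt(K))
  expect_lt(final, K + 3 * sqrt(K))
})

test_that("neutral dynamics: founder frequencies are a martingale", {
  p <- quick_params(s_c = 0, mu = 0, K = 50)
  prof <- group_profile(c(4, 8), p, n_replicates = 400, horizon = 10,
                        seed = 17)
  f8 <- prof$mean_freq[8, ncol(prof$mean_freq)]
  expect_lt(abs(f8 - 0.5), 0.06)  # ~4 SE at 400 replicates
})

test_that("neutral mean frequency flow matches the mutation-flow ODE", {
  # with s_c = 0 births occur at rate 1 per cell, so mean frequencies obey
  # dx/dt = x (H - I); oracle = forward-Euler integration at dt = 0.005
  p <- quick_params(s_c = 0, mu = 0.02, nu = 0.5, phi = 0.3, K = 100)
  prof <- group_profile(8, p, n_replicates = 300, horizon = 15, seed = 5)
  H <- mutation_matrix(0.02, 0.5, 0.3)
  x <- c(0, 0, 0, 0, 0, 0, 0, 1)
  for (s in seq_len(15 / 0.005)) x <- x + 0.005 * (as.vector(x %*% H) - x)
  expect_lt(max(abs(prof$mean_freq[, ncol(prof$mean_freq)] - x)), 0.05)
})

test_that("profile invariants hold on a mixed stochastic run", {
  p <- quick_params(mu = 0.01, phi = 0.5, K = 50)
  prof <- group_profile(8, p, n_replicates = 50, horizon = 20, seed = 21)
  expect_lt(max(abs(colSums(prof$mean_freq) - 1)), 1e-9)
  expect_lt(max(abs(colSums(prof$offspring_dist) - 1)), 1e-9)
  expect_true(all(prof$mean_trait >= 0 & prof$mean_trait <= 1))
  expect_true(all(prof$mean_N >= 1))
  # n_replicates = 1 equals a single trajectory
  one <- group_profile(8, p, n_replicates = 1, horizon = 5, seed = 33)
  tra <- simulate_group(8, p, horizon = 5, seed = 33)
  expect_identical(one$mean_counts, tra$mean_counts)
})

test_that("trait-less founder groups stay trait-less", {
  p <- quick_params()  # gain rate nu*mu = 1e-6
  prof <- group_profile(1, p, n_replicates = 100, horizon = 50, seed = 2)
  expect_true(all(prof$mean_trait["z_u", ] < 0.01))
})

test_that("group function and maturity", {
  expect_equal(group_function(1, 1, 1, zeta = 0), 1)
  expect_equal(group_function(0, 1, 1, zeta = 0), 0)
  expect_equal(group_function(1, 1, 1, zeta = 0.02), 0.98)
  expect_equal(group_function(0.5, 0.8, 0, zeta = 0.5), 0.4)
  expect_equal(maturity_indicator(25, 0.5, 50), 1)
  expect_equal(maturity_indicator(24.999, 0.5, 50), 0)
  expect_equal(maturity_indicator(c(0, 100), 0, 50), c(1, 1))
  expect_equal(maturity_age(0.5, 50), 25)
})

test_that("fitness effects: signs, cancellations and classes", {
  p <- quick_params()  # s_c = 0.95
  bg <- c(0, 0, 0, 0, 0, 0, 0, 200)  # homogeneous g8 background
  expect_equal(fitness_effect(8, 1, bg, p)$effect, 0)  # double loss cancels
  expect_equal(fitness_effect(8, 7, bg, p)$effect, 0)  # z_p rate-neutral
  expect_equal(fitness_effect(8, 4, bg, p)$effect, log(1 / (1 - 0.95)))
  expect_equal(fitness_effect(8, 6, bg, p)$effect, -log(1 / (1 - 0.95)))
  expect_error(fitness_effect(8, 4, c(0, 0, 0, 0, 0, 0, 0, 1), p), "N = 1")
  expect_equal(classify_mutation(8, 4), "loss-cooperation")
  expect_equal(classify_mutation(8, 6), "loss-private")
  expect_equal(classify_mutation(8, 7), "loss-pleiotropy")
  expect_equal(classify_mutation(8, 1), "pleiotropic-double-loss")
  expect_equal(classify_mutation(8, 2), "pleiotropic-double-loss")
  expect_equal(classify_mutation(1, 5), "other")
})

test_that("profile CSV export has the long format contract", {
  p <- quick_params(K = 30)
  prof <- group_profile(8, p, n_replicates = 5, horizon = 2, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_profile_csv(prof, f)
  df <- read.csv(f)
  expect_equal(names(df),
               c("group_type", "age", "genotype", "mean_count", "mean_freq"))
  expect_equal(nrow(df), 8 * length(prof$age_grid))
  expect_equal(unique(df$group_type), "g8")
})
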