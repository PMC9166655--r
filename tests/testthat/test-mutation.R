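test_that("null matrix equals the independent-channel brute-force oracle", {
  for (pars in list(c(1e-4, 0.01), c(0.03, 0.5), c(0.2, 1))) {
    Q <- mutation_null(pars[1], pars[2])
    expect_equal(unname(Q), oracle_null_matrix(pars[1], pars[2]),
                 tolerance = 1e-15)
  }
  expect_equal(unname(mutation_null(0, 0.01)), diag(8))  # mu = 0: no mutation
  Q <- mutation_null(1e-4, 0.01)
  expect_equal(Q[1, 1], (1 - 0.01 * 1e-4)^3)
})

test_that("pleiotropic matrix differs from the null only in row 8", {
  mu <- 1e-4; nu <- 0.01
  Q <- mutation_null(mu, nu)
  P <- mutation_pleiotropic(mu, nu)
  expect_equal(P[1:7, ], Q[1:7, ])
  # final row exactly as defined: double loss to g1, pleiotropy loss to g7,
  # remainder on the diagonal; no gain-of-function terms
  expect_equal(unname(P[8, ]),
               c(2 * mu - mu^2, 0, 0, 0, 0, 0, (1 - mu)^2 * mu,
                 1 - (2 * mu - mu^2) - (1 - mu)^2 * mu))
  expect_equal(P[8, 1], 2e-4 - 1e-8)  # independent hand arithmetic
  # row 8 sums to 1 algebraically for any mu
  for (m in c(0, 1e-4, 0.05, 0.5))
    expect_equal(sum(mutation_pleiotropic(m, 0.01)[8, ]), 1)
})

test_that("all matrices are row-stochastic and phi-blend is linear", {
  for (mu in c(1e-5, 1e-3, 0.1)) for (nu in c(0.01, 1)) {
    for (phi in c(0, 0.3, 1)) {
      H <- mutation_matrix(mu, nu, phi)
      expect_true(all(H >= 0 & H <= 1))
      expect_lt(max(abs(rowSums(H) - 1)), 1e-12)
    }
  }
  Q <- mutation_null(1e-4, 0.01); P <- mutation_pleiotropic(1e-4, 0.01)
  expect_equal(mutation_matrix(1e-4, 0.01, 0), Q)
  expect_equal(mutation_matrix(1e-4, 0.01, 1), P)
  expect_equal(mutation_matrix(1e-4, 0.01, 0.5), 0.5 * P + 0.5 * Q)
  expect_equal(mutation_matrix(1e-4, 0.01, 0.5)[8, 4], 0.5 * Q[8, 4])
  # entries move monotonically between Q and P
  H3 <- mutation_matrix(1e-4, 0.01, 0.3)
  expect_equal(unname(H3), unname(0.3 * P + 0.7 * Q))
})

test_that("diagonal dominance for small mu", {
  H <- mutation_matrix(1e-3, 0.01, 0.7)
  expect_true(all(diag(H) > 1 - 4 * 1e-3))
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(mutation_null(-0.1, 0.01))
  expect_error(mutation_null(0.1, 0))
  expect_error(mutation_matrix(0.1, 0.01, 1.5))
})

test_that("offspring sampling follows the matrix row", {
  id <- diag(8)
  expect_true(all(sample_offspring(3, id, n = 50, seed = 9) == 3))
  # empirical frequencies from row 8 within 4 binomial standard errors
  H <- mutation_matrix(0.01, 0.01, 0)
  n <- 2e5
  draws <- sample_offspring(8, H, n = n, seed = 4)
  expect_true(all(draws %in% 1:8))
  emp <- tabulate(draws, 8) / n
  se <- sqrt(H[8, ] * (1 - H[8, ]) / n)
  expect_true(all(abs(emp - H[8, ]) <= 4 * se + 1e-12))
  # determinism of the stream
  expect_identical(draws, sample_offspring(8, H, n = n, seed = 4))
})

test_that("matrix CSV export round-trips", {
  H <- mutation_matrix(1e-4, 0.01, 0.5)
  f <- tempfile(fileext = ".csv")
  write_matrix_csv(H, f)
  expect_equal(read_matrix_csv(f), H, tolerance = 1e-12)
})
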