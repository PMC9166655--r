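# Shared fixtures: small parameter sets and an independent brute-force
# oracle for the null mutation matrix (per-trait channel enumeration,
# deliberately written differently from the package implementation).

quick_params <- function(...) model_params(...)

oracle_null_matrix <- function(mu, nu) {
  Z <- genotype_table()
  M <- matrix(NA_real_, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    p <- 1
    for (tr in 1:3) {
      from <- Z[i, tr]; to <- Z[j, tr]
      p <- p * if (from == 1 && to == 0) mu else
               if (from == 1 && to == 1) 1 - mu else
               if (from == 0 && to == 1) nu * mu else 1 - nu * mu
    }
    M[i, j] <- p
  }
  M
}

# Independent oracle for clonal growth from a single founder without
# mutation: the deterministic logistic N(t) = (K+1) / (1 + K e^{-(K+1)t/K})
# averaged over the stochastic takeoff factor W ~ Exp(1) of the near-Yule
# early phase (N e^{-t} -> W), by quadrature over Exp(1) quantiles.
takeoff_logistic_oracle <- function(K, ages, nq = 2000) {
  w <- -log((seq_len(nq) - 0.5) / nq)
  vapply(ages, function(t)
    mean((K + 1) / (1 + K * exp(-(K + 1) * t / K) / w)), numeric(1))
}

founder_count_vec <- function(i) {
  v <- rep(0, 8); v[i] <- 1; v
}

# total variation of a density column (zero boundary values)
total_variation <- function(x) sum(abs(diff(c(0, x, 0))))
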