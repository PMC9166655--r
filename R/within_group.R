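# Within-group stochastic dynamics: frequency-dependent birth/death rates,
# exact Gillespie simulation, replicate-averaged developmental profiles per
# group type, group function, maturity and fitness effects of mutations.

founder_counts <- function(founders) {
  cnt <- integer(8)
  for (i in as.integer(founders)) cnt[i] <- cnt[i] + 1L
  cnt
}

state_means <- function(counts) {
  N <- sum(counts)
  if (N < 1) stop("invalid state: empty group")
  Z <- genotype_table()
  c(z_u = sum(counts * Z[, "z_u"]) / N,
    z_v = sum(counts * Z[, "z_v"]) / N,
    z_p = sum(counts * Z[, "z_p"]) / N,
    N = N)
}

#' Within-group cell birth rate
#'
#' Relative division rate of a genotype in the current group background:
#' `b_i = (1 - s_c z_u,i) / (1 - s_c zbar_u)`. Expressing the cooperative
#' trait is costly relative to the other cells in the group. Under the
#' control model (`control_private = TRUE`) the trait in the `z_u` slot is a
#' second private trait that instead raises the carrier's birth rate:
#' `b_i = (1 - s_c + s_c z_w,i) / (1 - s_c + s_c zbar_w)`.
#'
#' @param i Genotype index in 1..8 (vectorised).
#' @param counts Length-8 vector of genotype abundances in the group.
#' @param params A [model_params()] object.
#' @return Birth rate(s) per unit time.
#' @export
#' @examples
#' p <- model_params()
#' counts <- c(0, 0, 0, 100, 0, 0, 0, 100)  # half g4, half g8
#' cell_birth_rate(8, counts, p)
cell_birth_rate <- function(i, counts, params) {
  sm <- state_means(counts)
  zu_i <- genotype_table()[i, "z_u"]
  if (params$control_private)
    (1 - params$s_c + params$s_c * zu_i) /
      (1 - params$s_c + params$s_c * sm["z_u"][[1]])
  else
    (1 - params$s_c * zu_i) / (1 - params$s_c * sm["z_u"][[1]])
}

#' Within-group cell death rate
#'
#' `d_i = (1 - s_c z_v,i) / (1 - s_c zbar_v) * (N - 1) / K`: the private
#' trait confers a survival advantage relative to the group, and crowding
#' scales the rate so that a clonal group equilibrates near `K + 1` cells.
#' The factor `(N - 1)` makes the death rate vanish at `N = 1`, so a group
#' can never lose all of its cells.
#'
#' @inheritParams cell_birth_rate
#' @return Death rate(s) per unit time.
#' @export
cell_death_rate <- function(i, counts, params) {
  sm <- state_means(counts)
  zv_i <- genotype_table()[i, "z_v"]
  (1 - params$s_c * zv_i) / (1 - params$s_c * sm["z_v"][[1]]) *
    (sm["N"][[1]] - 1) / params$K
}

#' Simulate a single group trajectory
#'
#' Runs one exact Gillespie sample path of the birth-death-mutation process
#' for a group, recording the state on `age_grid` by last value carried
#' forward between events. Event channels are birth and death of each
#' genotype (propensities `n_i b_i`, `n_i d_i`), with all 16 propensities
#' recomputed after every event; on birth the offspring genotype is drawn
#' from the effective mutation matrix at the group's `phi`.
#'
#' @param founders Integer vector of founding cell genotypes (1 or 2 cells).
#' @param params A [model_params()] object.
#' @param horizon Final age to simulate to (defaults to the last grid age).
#' @param age_grid Increasing vector of recording ages (default
#'   `seq(0, horizon, by = 0.25)`).
#' @param seed Integer seed; a fixed seed gives a bit-identical trajectory.
#' @return A `group_profile` object with `n_replicates = 1`; its
#'   `mean_counts` matrix is the recorded trajectory.
#' @export
#' @examples
#' tr <- simulate_group(8, model_params(), horizon = 10, seed = 1)
#' tr$mean_N[length(tr$mean_N)]
simulate_group <- function(founders, params, horizon = NULL, age_grid = NULL,
                           seed = 1L) {
  group_profile(founders, params, n_replicates = 1L, horizon = horizon,
                age_grid = age_grid, seed = seed)
}

#' Replicate-averaged developmental profile of a group type
#'
#' Simulates `n_replicates` independent Gillespie sample paths for a group
#' founded by `founders` and averages counts, genotype frequencies, trait
#' means and group size on a shared age grid. The offspring-cell
#' distribution at each age (the probability that a cell sampled for group
#' reproduction founds each descendant genotype) is the mean genotype
#' frequency vector composed with the cell mutation matrix, optionally
#' blended with the founder row by the germ-line strength `gamma`.
#'
#' @inheritParams simulate_group
#' @param n_replicates Number of replicate sample paths (>= 1).
#' @param record_dfe If `TRUE`, record every mutation event's within-group
#'   fitness effect (see [fitness_effect()]).
#' @return A `group_profile` object: list with `age_grid`, `mean_counts`
#'   (8 x ages), `mean_freq`, `mean_trait` (3 x ages), `mean_N`,
#'   `offspring_dist` (8 x ages), `zf`, `zr`, `founders`, `n_replicates`,
#'   and (if requested) a `dfe` data frame.
#' @export
group_profile <- function(founders, params, n_replicates = 10000L,
                          horizon = NULL, age_grid = NULL, seed = 1L,
                          record_dfe = FALSE) {
  stopifnot(inherits(params, "pleio_params"), n_replicates >= 1)
  if (is.null(age_grid)) {
    if (is.null(horizon)) horizon <- 50
    age_grid <- seq(0, horizon, by = 0.25)
  }
  stopifnot(length(age_grid) >= 2, all(diff(age_grid) > 0), age_grid[1] >= 0)
  H <- mutation_matrix(params$mu, params$nu, params$phi)
  res <- sim_group_cpp(founder_counts(founders), H, params$s_c, params$K,
                       params$control_private, as.numeric(age_grid),
                       as.integer(n_replicates), as.double(seed),
                       isTRUE(record_dfe))
  gl <- paste0("g", 1:8)
  dimnames(res$mean_counts) <- list(gl, NULL)
  dimnames(res$mean_freq) <- list(gl, NULL)
  dimnames(res$mean_trait) <- list(c("z_u", "z_v", "z_p"), NULL)

  # age-dependent offspring-cell distribution (germ-line blend):
  # p(y) = gamma * founder_row + (1 - gamma) * t(H) %*% x(y)
  germ <- colMeans(H[as.integer(founders), , drop = FALSE])
  resident <- t(H) %*% res$mean_freq       # 8 x ages
  off <- params$gamma * germ + (1 - params$gamma) * resident
  off <- sweep(off, 2, colSums(off), "/")  # guard roundoff
  rownames(off) <- gl

  prof <- list(
    age_grid = as.numeric(age_grid),
    mean_counts = res$mean_counts,
    mean_freq = res$mean_freq,
    mean_trait = res$mean_trait,
    mean_N = as.numeric(res$mean_N),
    offspring_dist = off,
    zf = group_function(res$mean_trait["z_u", ], res$mean_trait["z_v", ],
                        res$mean_trait["z_p", ], params$zeta),
    zr = maturity_indicator(age_grid, params$alpha, params$lambda),
    founders = sort(as.integer(founders)),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  )
  if (isTRUE(record_dfe)) {
    d <- res$dfe
    prof$dfe <- data.frame(
      replicate = as.integer(d[, 1]), age = d[, 2],
      ancestor = as.integer(d[, 3]), descendant = as.integer(d[, 4]),
      effect = d[, 5],
      class = classify_mutation(as.integer(d[, 3]), as.integer(d[, 4])))
  }
  class(prof) <- "group_profile"
  prof
}

#' @export
print.group_profile <- function(x, ...) {
  cat(sprintf(
    "Group profile: founders %s, %d replicate(s), ages [%g, %g] (%d points)\n",
    group_type_label(x$founders), x$n_replicates,
    min(x$age_grid), max(x$age_grid), length(x$age_grid)))
  invisible(x)
}

#' Group function
#'
#' `z_f = zbar_u * zbar_v * (1 - zeta * zbar_p)`: group function requires
#' both the cooperative and the private trait, multiplicatively, and is
#' discounted by the pleiotropy cost `zeta` (the cost-free form is the
#' `zeta = 0` special case).
#'
#' @param z_u,z_v,z_p Mean trait expression values in \[0, 1\] (vectorised).
#' @param zeta Cost of pleiotropy in \[0, 1\].
#' @return Group function value(s) in \[0, 1\].
#' @export
#' @examples
#' group_function(1, 1, 1, zeta = 0.02)  # 0.98
group_function <- function(z_u, z_v, z_p = 0, zeta = 0) {
  z_u * z_v * (1 - zeta * z_p)
}

#' Reproductive maturity indicator
#'
#' A group can reproduce only after it has reached the maturity age
#' `alpha * lambda`: the indicator is 0 for `y < alpha * lambda` and 1 for
#' `y >= alpha * lambda`.
#'
#' @param y Group age(s).
#' @param alpha Maturity fraction of the expected life span, in \[0, 1\].
#' @param lambda Expected group life span.
#' @return 0/1 vector.
#' @export
#' @examples
#' maturity_indicator(25, alpha = 0.5, lambda = 50)  # 1
maturity_indicator <- function(y, alpha, lambda) {
  as.numeric(y >= alpha * lambda)
}

#' Age of reproductive maturity
#'
#' @inheritParams maturity_indicator
#' @return `alpha * lambda`, the threshold age below which the maturity
#'   indicator is 0 and at or above which it is 1.
#' @export
maturity_age <- function(alpha, lambda) alpha * lambda

#' Phenotypic class of a mutation
#'
#' Classifies a genotype transition by its trait-vector difference:
#' `"loss-cooperation"`, `"loss-private"`, `"loss-pleiotropy"`,
#' `"pleiotropic-double-loss"` (cooperative and private traits lost
#' together), or `"other"`.
#'
#' @param ancestor,descendant Genotype indices (vectorised).
#' @return Character vector of class labels.
#' @export
classify_mutation <- function(ancestor, descendant) {
  Z <- genotype_table()
  d <- Z[descendant, , drop = FALSE] - Z[ancestor, , drop = FALSE]
  lab <- rep("other", length(ancestor))
  lab[d[, "z_u"] == -1 & d[, "z_v"] == -1] <- "pleiotropic-double-loss"
  only <- function(col) {
    others <- setdiff(colnames(Z), col)
    d[, col] == -1 & rowSums(d[, others, drop = FALSE] != 0) == 0
  }
  lab[only("z_u")] <- "loss-cooperation"
  lab[only("z_v")] <- "loss-private"
  lab[only("z_p")] <- "loss-pleiotropy"
  lab
}

#' Within-group fitness effect of a mutation
#'
#' Log-ratio fitness change of a mutant descendant relative to its ancestor
#' in the current group background:
#' `effect = ln(b_desc / b_anc) - ln(d_desc / d_anc)`. Because the costs of
#' the cooperative and private traits are equal and opposite, a pleiotropic
#' double loss has effect exactly 0, as does loss of the (rate-neutral)
#' pleiotropy trait.
#'
#' @param ancestor,descendant Genotype indices in 1..8.
#' @param counts Length-8 vector of genotype abundances (must have
#'   `sum(counts) >= 2` so death rates are positive).
#' @param params A [model_params()] object.
#' @return A one-row data frame: `ancestor`, `descendant`, `effect`,
#'   `class`.
#' @export
#' @examples
#' p <- model_params()
#' counts <- c(0, 0, 0, 0, 0, 0, 0, 200)
#' fitness_effect(8, 4, counts, p)$effect  # log(1 / (1 - s_c))
fitness_effect <- function(ancestor, descendant, counts, params) {
  if (sum(counts) < 2)
    stop("undefined log-ratio: death rates vanish at N = 1")
  b <- cell_birth_rate(c(ancestor, descendant), counts, params)
  d <- cell_death_rate(c(ancestor, descendant), counts, params)
  data.frame(ancestor = ancestor, descendant = descendant,
             effect = log(b[2] / b[1]) - log(d[2] / d[1]),
             class = classify_mutation(ancestor, descendant))
}

#' First age at which the mean cheater frequency crosses a threshold
#'
#' Cheaters are the genotypes lacking the active cooperative trait
#' (`z_u = 0`: g1-g4). Returns the first age at which their summed
#' replicate-mean frequency reaches `threshold`, linearly interpolated
#' between grid ages; `Inf` if no crossing occurs within the profile's
#' horizon.
#'
#' @param profile A `group_profile` object.
#' @param threshold Frequency threshold (default 0.25).
#' @return Crossing age, or `Inf`.
#' @export
cheater_crossing_age <- function(profile, threshold = 0.25) {
  zu0 <- genotype_table()[, "z_u"] == 0
  f <- colSums(profile$mean_freq[zu0, , drop = FALSE])
  idx <- which(f >= threshold)
  if (length(idx) == 0) return(Inf)
  i <- idx[1]
  if (i == 1) return(profile$age_grid[1])
  y0 <- profile$age_grid[i - 1]; y1 <- profile$age_grid[i]
  f0 <- f[i - 1]; f1 <- f[i]
  y0 + (threshold - f0) / (f1 - f0) * (y1 - y0)
}

#' Export a profile as a long-format CSV table
#'
#' Columns: `group_type`, `age`, `genotype`, `mean_count`, `mean_freq`.
#'
#' @param profile A `group_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  ages <- profile$age_grid
  df <- data.frame(
    group_type = group_type_label(profile$founders),
    age = rep(ages, each = 8),
    genotype = rep(paste0("g", 1:8), length(ages)),
    mean_count = as.vector(profile$mean_counts),
    mean_freq = as.vector(profile$mean_freq))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
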