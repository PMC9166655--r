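# Scripted experiment drivers: within-group invasion dynamics across
# pleiotropy strengths, steady-state parameter sweeps, and long-run
# evolutionary time series.

#' Within-group dynamics across pleiotropy strengths
#'
#' For a group founded by a single fully active cell (genotype g8 by
#' default), simulates replicate-averaged within-group dynamics at each
#' requested pleiotropy strength and summarises: the developmental profile,
#' the age at which the mean cheater frequency (genotypes with `z_u = 0`)
#' crosses a threshold, and the distribution of within-group fitness
#' effects of the mutations that occurred.
#'
#' @param params A [model_params()] object (`phi` is overridden per run).
#' @param phis Pleiotropy strengths to compare (default `c(0, 0.5, 1)`).
#' @param founder Founding genotype (default 8).
#' @param n_replicates Replicates per strength (default 1000).
#' @param horizon Simulation horizon in time units (default 50).
#' @param threshold Cheater-frequency threshold (default 0.25).
#' @param seed Master seed.
#' @param record_dfe Record per-mutation fitness effects (default `TRUE`).
#' @return List with `profiles` (per phi), `crossing` (data frame of
#'   crossing ages), and `dfe` (combined data frame, if recorded).
#' @export
within_group_figure <- function(params, phis = c(0, 0.5, 1), founder = 8L,
                                n_replicates = 1000L, horizon = 50,
                                threshold = 0.25, seed = 1L,
                                record_dfe = TRUE) {
  profiles <- list()
  crossing <- data.frame(phi = phis, crossing_age = NA_real_)
  dfe_all <- list()
  for (j in seq_along(phis)) {
    pj <- model_params(s_c = params$s_c, s_g = params$s_g,
                       lambda = params$lambda, K = params$K, mu = params$mu,
                       nu = params$nu, phi = phis[j], zeta = params$zeta,
                       alpha = params$alpha, gamma = params$gamma,
                       control_private = params$control_private)
    prof <- group_profile(founder, pj, n_replicates = n_replicates,
                          horizon = horizon,
                          seed = (as.integer(seed) + 131L * j) %%
                            .Machine$integer.max,
                          record_dfe = record_dfe)
    profiles[[paste0("phi", phis[j])]] <- prof
    crossing$crossing_age[j] <- cheater_crossing_age(prof, threshold)
    if (record_dfe && !is.null(prof$dfe) && nrow(prof$dfe) > 0)
      dfe_all[[j]] <- cbind(phi = phis[j], prof$dfe)
  }
  list(profiles = profiles, crossing = crossing,
       dfe = if (length(dfe_all)) do.call(rbind, dfe_all) else NULL)
}

#' Steady-state sweep over a parameter grid
#'
#' Runs the full two-level model (profiles plus PDE) to steady state at
#' every combination of the supplied parameter grids and records the
#' global trait means. Failures at individual grid points are reported and
#' the sweep continues.
#'
#' @param base A `pleio_config` (or list accepted by [as_config()]) giving
#'   fixed settings; grid arguments below override it pointwise.
#' @param phi,lambda,K,gamma,alpha,zeta,mu,nu,s_g Vectors of values to
#'   sweep (default: the single value in `base`).
#' @param n_founders 1 or 2 founding cells.
#' @param control_private Logical values to sweep.
#' @param n_replicates Replicates per group-type profile.
#' @param seed Master seed.
#' @param cache_dir Optional profile cache directory.
#' @return Data frame: one row per grid point with the swept parameters,
#'   steady-state `z_u`, `z_v`, `z_p`, `zbar_f`, and `converged`.
#' @export
steady_state_heatmap <- function(base = as_config(), phi = NULL,
                                 lambda = NULL, K = NULL, gamma = NULL,
                                 alpha = NULL, zeta = NULL, mu = NULL,
                                 nu = NULL, s_g = NULL, n_founders = NULL,
                                 control_private = NULL,
                                 n_replicates = NULL, seed = NULL,
                                 cache_dir = NULL) {
  if (!inherits(base, "pleio_config")) base <- as_config(base)
  pick <- function(v, nm) if (is.null(v)) base[[nm]] else v
  grid <- expand.grid(
    phi = pick(phi, "phi"), lambda = pick(lambda, "lambda"),
    K = pick(K, "K"), gamma = pick(gamma, "gamma"),
    alpha = pick(alpha, "alpha"), zeta = pick(zeta, "zeta"),
    mu = pick(mu, "mu"), nu = pick(nu, "nu"), s_g = pick(s_g, "s_g"),
    n_founders = pick(n_founders, "n_founders"),
    control_private = pick(control_private, "control_private"),
    KEEP.OUT.ATTRS = FALSE)
  n_replicates <- if (is.null(n_replicates)) base$n_replicates else n_replicates
  seed <- if (is.null(seed)) base$seed else seed

  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    rows[[r]] <- tryCatch({
      p <- model_params(s_c = base$s_c, s_g = g$s_g, lambda = g$lambda,
                        K = g$K, mu = g$mu, nu = g$nu, phi = g$phi,
                        zeta = g$zeta, alpha = g$alpha, gamma = g$gamma,
                        control_private = g$control_private)
      ag <- age_grid(p$lambda, dy = base$dy, ymax_mult = base$ymax_mult)
      profs <- compute_profiles(p, ag, n_founders = g$n_founders,
                                n_replicates = n_replicates, seed = seed,
                                cache_dir = cache_dir)
      ss <- run_to_steady_state(p, profs, ag, dt_safety = base$dt_safety,
                                tol = base$tol, t_max = base$t_max)
      fin <- ss$summaries[nrow(ss$summaries), ]
      cbind(g, z_u = fin$z_u, z_v = fin$z_v, z_p = fin$z_p,
            zbar_f = fin$zbar_f, converged = ss$converged,
            row.names = NULL)
    }, error = function(e) {
      warning("grid point ", r, " failed: ", conditionMessage(e))
      cbind(g, z_u = NA, z_v = NA, z_p = NA, zbar_f = NA, converged = NA,
            row.names = NULL)
    })
  }
  do.call(rbind, rows)
}

#' Long-run evolutionary dynamics across pleiotropy strengths
#'
#' Integrates the full model from a population of trait-less groups for
#' each pleiotropy strength, returning the global summary time series
#' (trait means, genotype frequencies, per-trait mutational load) and the
#' order in which genotypes invade the global cell population (first time
#' each genotype's global frequency exceeds `threshold`).
#'
#' @inheritParams steady_state_heatmap
#' @param params A [model_params()] object (`phi` overridden per run).
#' @param phis Pleiotropy strengths (default `c(0, 0.5, 1)`).
#' @param dy,ymax_mult,dt_safety,tol,t_max PDE grid and run controls.
#' @param threshold Invasion threshold on global genotype frequency
#'   (default 0.25; a threshold of 1 gives an empty order).
#' @return List per phi, each with `summaries` (data frame time series),
#'   `invasion_order` (data frame genotype/time, ordered), `converged`.
#' @export
longrun_dynamics <- function(params, phis = c(0, 0.5, 1),
                             n_replicates = 1000L, dy = 0.1, ymax_mult = 10,
                             dt_safety = 0.9, tol = 1e-4, t_max = 1e4,
                             threshold = 0.25, seed = 1L, cache_dir = NULL) {
  out <- list()
  for (ph in phis) {
    p <- model_params(s_c = params$s_c, s_g = params$s_g,
                      lambda = params$lambda, K = params$K, mu = params$mu,
                      nu = params$nu, phi = ph, zeta = params$zeta,
                      alpha = params$alpha, gamma = params$gamma,
                      control_private = params$control_private)
    ag <- age_grid(p$lambda, dy = dy, ymax_mult = ymax_mult)
    profs <- compute_profiles(p, ag, n_replicates = n_replicates,
                              seed = seed, cache_dir = cache_dir)
    ss <- run_to_steady_state(p, profs, ag, dt_safety = dt_safety,
                              tol = tol, t_max = t_max)
    inv <- invasion_order(ss$summaries, threshold)
    out[[paste0("phi", ph)]] <- list(summaries = ss$summaries,
                                     invasion_order = inv,
                                     converged = ss$converged)
  }
  out
}

#' Genotype invasion order from a summary time series
#'
#' @param summaries Summary data frame from [run_to_steady_state()] (needs
#'   columns `time` and `g1`..`g8`).
#' @param threshold Frequency threshold; genotypes never exceeding it are
#'   omitted (threshold 1 gives an empty result).
#' @return Data frame `genotype`, `time`, ordered by invasion time.
#' @export
invasion_order <- function(summaries, threshold = 0.25) {
  gl <- paste0("g", 1:8)
  t_first <- vapply(gl, function(g) {
    i <- which(summaries[[g]] > threshold)
    if (length(i)) summaries$time[i[1]] else NA_real_
  }, numeric(1))
  ok <- !is.na(t_first)
  res <- data.frame(genotype = gl[ok], time = t_first[ok])
  res[order(res$time), , drop = FALSE]
}
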