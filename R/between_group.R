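# Between-group dynamics: an age-structured PDE for the relative density
# n_k(t, y) of k-type groups aged y, advanced by operator splitting:
# conservative finite-volume advection in age (superbee flux limiter),
# then explicit-Euler group births and deaths. Births always enter at age
# 0. Rates are normalised so the population-average birth and death rates
# both equal rho = 1/lambda, which conserves total density.

#' Uniform age grid for the group-population PDE
#'
#' Cell-centred uniform grid from 0 to `ymax_mult * lambda`. The default
#' truncation at 10 expected life spans leaves ~`exp(-10)` of neutral
#' steady-state mass beyond the boundary.
#'
#' @param lambda Expected group life span.
#' @param dy Cell width (default 0.1 time units).
#' @param ymax_mult Domain length in units of `lambda` (default 10).
#' @return List with `centers`, `edges`, `dy`, `y_max`.
#' @export
age_grid <- function(lambda, dy = 0.1, ymax_mult = 10) {
  y_max <- ymax_mult * lambda
  n <- ceiling(y_max / dy)
  list(centers = (seq_len(n) - 0.5) * dy,
       edges = seq(0, n * dy, by = dy),
       dy = dy, y_max = n * dy)
}

#' Group-level birth rate
#'
#' `b_k(y) = rho * (1 - s_g + s_g z_r,k(y)) / (1 - s_g + s_g zbar_r(t))`
#' with `rho = 1/lambda`: only mature groups reproduce at the full relative
#' rate, normalised by the population fraction of mature groups so that the
#' population-average birth rate is exactly `rho`.
#'
#' @param zr Maturity indicator(s) of the focal group(s), 0/1.
#' @param zbar_r Population (group-density-weighted) mean maturity.
#' @param params A [model_params()] object.
#' @return Birth rate(s) per unit time.
#' @export
#' @examples
#' group_birth_rate(1, 0.5, model_params(s_g = 0.95, lambda = 20))
group_birth_rate <- function(zr, zbar_r, params) {
  rho_of(params) * (1 - params$s_g + params$s_g * zr) /
    (1 - params$s_g + params$s_g * zbar_r)
}

#' Group-level death rate
#'
#' `d_k(y) = rho * (1 - s_g z_f,k(y)) / (1 - s_g zbar_f(t))`: groups with
#' higher function survive longer, normalised by the population mean
#' function so that the population-average death rate is exactly `rho`.
#'
#' @param zf Group function value(s) of the focal group(s) in \[0, 1\].
#' @param zbar_f Population (group-density-weighted) mean group function.
#' @inheritParams group_birth_rate
#' @return Death rate(s) per unit time.
#' @export
group_death_rate <- function(zf, zbar_f, params) {
  rho_of(params) * (1 - params$s_g * zf) / (1 - params$s_g * zbar_f)
}

#' Offspring group-type distribution of an ancestral group
#'
#' For a single-founder group of type k at age y, the probability that its
#' descendant group is of type l is the germ-line blend
#' `gamma * h_kl + (1 - gamma) * sum_i x_ki(y) h_il` of the founder's
#' mutation row and the resident-cell sampling distribution (already stored
#' in the profile). For two-founder groups the two founding cells are drawn
#' independently from that per-cell distribution and the descendant type is
#' their unordered pair.
#'
#' @param profile A `group_profile` for the ancestral type.
#' @param y Ancestral group age (matched to the nearest profile grid age).
#' @param gtypes Group-type enumeration from [group_types()] giving the
#'   descendant type space.
#' @return Probability vector over `gtypes`.
#' @export
offspring_type_distribution <- function(profile, y, gtypes) {
  iy <- which.min(abs(profile$age_grid - y))
  if (abs(profile$age_grid[iy] - y) > max(diff(profile$age_grid)))
    stop("configuration error: profile does not cover age ", y)
  p <- profile$offspring_dist[, iy]
  n_found <- length(gtypes[[1]])
  if (n_found == 1) {
    out <- p
  } else {
    out <- vapply(gtypes, function(fd) {
      if (fd[1] == fd[2]) p[fd[1]]^2 else 2 * p[fd[1]] * p[fd[2]]
    }, numeric(1))
  }
  setNames(out, names(gtypes))
}

# Build the dense offspring kernel Hg[y, k, l] for the PDE from profiles.
build_offspring_kernel <- function(profiles, gtypes) {
  T_ <- length(gtypes)
  n_age <- length(profiles[[1]]$age_grid)
  n_found <- length(gtypes[[1]])
  Hg <- array(0, dim = c(n_age, T_, T_))
  for (k in seq_len(T_)) {
    p <- profiles[[k]]$offspring_dist  # 8 x n_age
    if (n_found == 1) {
      Hg[, k, ] <- t(p)
    } else {
      for (l in seq_len(T_)) {
        fd <- gtypes[[l]]
        Hg[, k, l] <- if (fd[1] == fd[2]) p[fd[1], ]^2
                      else 2 * p[fd[1], ] * p[fd[2], ]
      }
    }
  }
  Hg
}

#' Compute within-group profiles for every group type
#'
#' Runs [group_profile()] for each group type on the PDE age grid. With a
#' cache directory, profiles are computed once per (type, parameter set)
#' and re-loaded afterwards (see [profile_cache()]).
#'
#' @param params A [model_params()] object.
#' @param grid An [age_grid()] list.
#' @param n_founders 1 or 2 founding cells per group.
#' @param n_replicates Replicates per group type.
#' @param seed Integer master seed; each type uses an offset stream.
#' @param cache_dir Optional cache directory.
#' @return Named list of `group_profile` objects, one per group type.
#' @export
compute_profiles <- function(params, grid, n_founders = 1L,
                             n_replicates = 1000L, seed = 1L,
                             cache_dir = NULL) {
  gtypes <- group_types(n_founders)
  profiles <- vector("list", length(gtypes))
  names(profiles) <- names(gtypes)
  for (k in seq_along(gtypes)) {
    sk <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max
    profiles[[k]] <- profile_cache(gtypes[[k]], params,
                                   n_replicates = n_replicates,
                                   age_grid = grid$centers, seed = sk,
                                   cache_dir = cache_dir)
  }
  profiles
}

# Stack a per-profile age-vector field into an (n_age x T) matrix.
profile_field <- function(profiles, field) {
  vapply(profiles, function(p) as.numeric(p[[field]]),
         numeric(length(profiles[[1]]$age_grid)))
}

#' Initial group population density
#'
#' All mass (total 1) on the trait-less founder type (`g1`, or `g1+g1` for
#' two-founder groups), concentrated in the age-0 cell.
#'
#' @param gtypes Group-type enumeration.
#' @param grid An [age_grid()] list.
#' @return A `pleio_population` object (density matrix `n_age x n_types`,
#'   plus grid metadata).
#' @export
init_population <- function(gtypes, grid) {
  dens <- matrix(0, length(grid$centers), length(gtypes),
                 dimnames = list(NULL, names(gtypes)))
  dens[1, 1] <- 1 / grid$dy
  structure(list(density = dens, grid = grid, time = 0),
            class = "pleio_population")
}

#' @export
print.pleio_population <- function(x, ...) {
  cat(sprintf(
    "Group population at t = %g: %d types x %d age cells (dy = %g), mass %.6f\n",
    x$time, ncol(x$density), nrow(x$density), x$grid$dy,
    sum(x$density) * x$grid$dy))
  invisible(x)
}

#' One advection step of the group density in age
#'
#' Conservative finite-volume update of `dn/dt + dn/dy = 0` per group type
#' with superbee-limited fluxes, zero inflow and outflow at the upper age
#' boundary. Requires the CFL condition `dt <= dy`.
#'
#' @param density `n_age x n_types` matrix of densities.
#' @param dy Cell width.
#' @param dt Time step (`dt <= dy`; `dt = dy` advects exactly one cell).
#' @return List with updated `density` and scalar `outflow` mass.
#' @export
advect_age_step <- function(density, dy, dt) {
  advect_step_cpp(as.matrix(density), dy, dt)
}

#' Apply group births and deaths for one explicit-Euler step
#'
#' Removes `d_k(y) n_k(y) dt` per cell and injects all births
#' `B_l = sum_k int n_k b_k Hg[.,k,l] dy * dt` into the age-0 cell of type
#' l; both rates are evaluated from the same pre-step state. Used on its
#' own mainly for testing; [run_to_steady_state()] performs the identical
#' update in compiled code.
#'
#' @param density `n_age x n_types` density matrix.
#' @param dy,dt Grid spacing and time step.
#' @param zr,zf `n_age x n_types` maturity and function profiles.
#' @param Hg Offspring kernel array `[y, k, l]`.
#' @param params A [model_params()] object.
#' @return List with updated `density`, and the step's `births` and
#'   `deaths` mass totals.
#' @export
apply_sources_sinks <- function(density, dy, dt, zr, zf, Hg, params) {
  mass <- sum(density)
  if (mass <= 0) stop("population mass vanished")
  zbar_r <- sum(density * zr) / mass
  zbar_f <- sum(density * zf) / mass
  b <- group_birth_rate(zr, zbar_r, params)
  d <- group_death_rate(zf, zbar_f, params)
  w <- density * b * dy                     # n_age x T
  B <- vapply(seq_len(dim(Hg)[3]),
              function(l) sum(w * Hg[, , l]), numeric(1))
  out <- density * (1 - d * dt)
  if (any(out < 0)) stop("negative density: dt too large")
  out[1, ] <- out[1, ] + B * dt / dy
  list(density = out, births = sum(B) * dt, deaths = sum(density * d * dt) * dy)
}

#' Global population summaries
#'
#' Cell-weighted global trait means (weight of type k at age y is
#' `n_k(y) * N_k(y)`), global genotype frequencies, and group-density-
#' weighted mean function `zbar_f` and mature fraction `zbar_r`.
#'
#' @param pop A `pleio_population`.
#' @param profiles Profile list matching the population's type space.
#' @return Named list: `z_u`, `z_v`, `z_p`, `zbar_f`, `zbar_r`, `freq`
#'   (length-8 genotype frequency vector), `mass`.
#' @export
global_trait_averages <- function(pop, profiles) {
  dens <- pop$density
  Nk <- profile_field(profiles, "mean_N")
  w_cell <- dens * Nk
  wc <- sum(w_cell)
  tm <- function(tr) {
    m <- vapply(profiles, function(p) p$mean_trait[tr, ], numeric(nrow(dens)))
    sum(w_cell * m) / wc
  }
  mass <- sum(dens)
  zf <- profile_field(profiles, "zf")
  zr <- profile_field(profiles, "zr")
  freq <- vapply(1:8, function(l) {
    fl <- vapply(profiles, function(p) p$mean_freq[l, ], numeric(nrow(dens)))
    sum(w_cell * fl) / wc
  }, numeric(1))
  list(z_u = tm("z_u"), z_v = tm("z_v"), z_p = tm("z_p"),
       zbar_f = sum(dens * zf) / mass, zbar_r = sum(dens * zr) / mass,
       freq = setNames(freq, paste0("g", 1:8)),
       mass = mass * pop$grid$dy)
}

#' Per-trait mutational load of the group population
#'
#' For each trait, the group-density-weighted mean over (type, age) of the
#' founder trait value minus the mean trait value among the group's cells
#' at its current age: how much trait expression groups have lost since
#' birth, averaged over the population.
#'
#' @inheritParams global_trait_averages
#' @return Named numeric vector `(z_u, z_v, z_p)`.
#' @export
mutational_load <- function(pop, profiles) {
  dens <- pop$density
  mass <- sum(dens)
  out <- vapply(c("z_u", "z_v", "z_p"), function(tr) {
    lost <- vapply(profiles, function(p)
      founder_traits(p$founders)[tr] - p$mean_trait[tr, ],
      numeric(nrow(dens)))
    sum(dens * lost) / mass
  }, numeric(1))
  setNames(out, c("z_u", "z_v", "z_p"))
}

#' Integrate the group-population PDE to a stable distribution
#'
#' Advances the density by operator splitting (superbee advection, then
#' explicit-Euler births/deaths) in chunks, recording global summaries
#' after every chunk, until the sup-norm change of the global trait means
#' `(z_u, z_v, z_p)` over a sliding window of `window` time units falls
#' below `tol`, or until `t_max`. Total density is renormalised to 1 after
#' each step (a no-op up to solver tolerance, since the normalised rates
#' conserve mass).
#'
#' @param params A [model_params()] object.
#' @param profiles Profile list from [compute_profiles()].
#' @param grid The [age_grid()] the profiles were computed on.
#' @param init Optional initial `pleio_population` (default:
#'   [init_population()], all mass on the trait-less type at age 0).
#' @param dt_safety CFL safety factor, `dt = dt_safety * dy` (default 0.9).
#' @param tol Steady-state tolerance on the trait means (default 1e-4).
#' @param t_max Maximum integration time (default 1e4).
#' @param window Sliding window for the convergence test (default
#'   `5 * lambda`).
#' @param check_every Chunk length in time units between summary records
#'   (default `lambda`).
#' @return List: `population` (final state), `summaries` (data frame time
#'   series of global summaries and mutational loads), `converged`.
#' @export
run_to_steady_state <- function(params, profiles, grid, init = NULL,
                                dt_safety = 0.9, tol = 1e-4, t_max = 1e4,
                                window = NULL, check_every = NULL) {
  gtypes <- group_types(length(profiles[[1]]$founders))
  stopifnot(length(gtypes) == length(profiles))
  if (is.null(init)) init <- init_population(gtypes, grid)
  if (is.null(window)) window <- 5 * params$lambda
  if (is.null(check_every)) check_every <- params$lambda
  dy <- grid$dy
  dt <- dt_safety * dy
  zr <- profile_field(profiles, "zr")
  zf <- profile_field(profiles, "zf")
  Hg <- build_offspring_kernel(profiles, gtypes)
  rho <- rho_of(params)

  pop <- init
  steps_per_chunk <- max(1L, round(check_every / dt))
  n_chunks <- ceiling(t_max / (steps_per_chunk * dt))
  rows <- list()
  converged <- FALSE
  for (ch in seq_len(n_chunks)) {
    res <- pde_advance_cpp(pop$density, dy, dt, steps_per_chunk,
                           zr, zf, as.numeric(Hg), rho, params$s_g, TRUE)
    pop$density <- res$density
    pop$time <- pop$time + steps_per_chunk * dt
    s <- global_trait_averages(pop, profiles)
    ml <- mutational_load(pop, profiles)
    rows[[ch]] <- data.frame(time = pop$time, z_u = s$z_u, z_v = s$z_v,
                             z_p = s$z_p, zbar_f = s$zbar_f,
                             zbar_r = s$zbar_r,
                             load_u = ml["z_u"], load_v = ml["z_v"],
                             load_p = ml["z_p"], mass = s$mass,
                             t(s$freq), row.names = NULL)
    nw <- ceiling(window / (steps_per_chunk * dt))
    if (ch > nw) {
      recent <- do.call(rbind, rows[(ch - nw):ch])
      dev <- max(apply(recent[, c("z_u", "z_v", "z_p")], 2,
                       function(x) diff(range(x))))
      if (dev < tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    message("run_to_steady_state: no convergence by t_max = ", t_max,
            "; returning final state")
  list(population = pop, summaries = do.call(rbind, rows),
       converged = converged)
}
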