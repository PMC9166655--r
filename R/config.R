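# Run configuration, content-addressed profile caching and run manifests.
# Configs are JSON; every field has a default, unknown keys are rejected.

.config_defaults <- function() {
  c(.param_defaults,
    list(dy = 0.1, dt_safety = 0.9, ymax_mult = 10,
         n_replicates = 10000L, n_founders = 1L, seed = 1L,
         threshold = 0.25, t_max = 1e4, tol = 1e-4,
         cache_dir = NULL, out_dir = NULL))
}

#' Load a run configuration
#'
#' Reads a JSON configuration file, fills every missing field with its
#' default (model parameters take the standard defaults, see
#' [model_params()]), validates all values, and rejects unknown keys.
#'
#' @param path Path to a JSON file; an empty object `{}` (or empty file)
#'   yields the full default configuration.
#' @return A validated named list of class `pleio_config`.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt) else list()
  if (!is.list(cfg)) stop("config must be a JSON object")
  as_config(cfg)
}

#' Build a configuration from a list
#'
#' @param cfg Named list of overrides (may be empty).
#' @return A validated `pleio_config` list.
#' @export
as_config <- function(cfg = list()) {
  defaults <- .config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  full <- modifyList(defaults, cfg, keep.null = TRUE)
  # validate model parameters by constructing them
  p <- do.call(model_params, full[names(.param_defaults)])
  full[names(.param_defaults)] <- p[names(.param_defaults)]
  stopifnot(full$dy > 0, full$dt_safety > 0, full$dt_safety <= 1,
            full$ymax_mult >= 1, full$n_replicates >= 1,
            full$n_founders %in% c(1L, 2L),
            full$threshold > 0, full$t_max > 0, full$tol > 0)
  full$n_replicates <- as.integer(full$n_replicates)
  full$n_founders <- as.integer(full$n_founders)
  full$seed <- as.integer(full$seed)
  structure(full, class = "pleio_config")
}

#' Save a configuration as JSON
#'
#' [load_config()] of the saved file round-trips to the same configuration.
#'
#' @param cfg A `pleio_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Extract model parameters from a configuration
#'
#' @param cfg A `pleio_config`.
#' @return A [model_params()] object.
#' @export
config_params <- function(cfg) do.call(model_params, cfg[names(.param_defaults)])

# Deterministic cache key: every parameter that changes the simulated
# profile enters the key; output paths and the like do not.
profile_cache_key <- function(founders, params, n_replicates, age_grid, seed) {
  fields <- c(
    sprintf("f%s", paste(sort(as.integer(founders)), collapse = "_")),
    sprintf("sc%.17g_K%d_mu%.17g_nu%.17g_phi%.17g_ctl%d",
            params$s_c, params$K, params$mu, params$nu, params$phi,
            as.integer(params$control_private)),
    sprintf("gam%.17g_zeta%.17g_al%.17g_lam%.17g",
            params$gamma, params$zeta, params$alpha, params$lambda),
    sprintf("r%d_s%d", as.integer(n_replicates), as.integer(seed)),
    sprintf("a%.17g_%.17g_%d", min(age_grid), max(age_grid),
            length(age_grid)))
  key <- paste(fields, collapse = "|")
  # short stable hex digest of the key for the filename
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2^31
  list(key = key, file = sprintf("profile_%s_%08x.rds",
                                 group_type_label(founders), h))
}

#' Compute-or-load a cached group profile
#'
#' Content-addressed cache: the key covers the founder multiset, every
#' model parameter that affects the within-group dynamics or derived
#' profile fields, the replicate count, seed, and age grid. Identical
#' requests never recompute; a corrupt or mismatching cache entry is
#' recomputed and rewritten. With `cache_dir = NULL` this is just
#' [group_profile()].
#'
#' @inheritParams group_profile
#' @param cache_dir Directory for cached profiles (created if missing).
#' @return A `group_profile` object.
#' @export
profile_cache <- function(founders, params, n_replicates, age_grid,
                          seed = 1L, cache_dir = NULL) {
  if (is.null(cache_dir))
    return(group_profile(founders, params, n_replicates = n_replicates,
                         age_grid = age_grid, seed = seed))
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  ck <- profile_cache_key(founders, params, n_replicates, age_grid, seed)
  f <- file.path(cache_dir, ck$file)
  if (file.exists(f)) {
    obj <- tryCatch(readRDS(f), error = function(e) NULL)
    if (!is.null(obj) && identical(obj$key, ck$key)) return(obj$profile)
  }
  prof <- group_profile(founders, params, n_replicates = n_replicates,
                        age_grid = age_grid, seed = seed)
  saveRDS(list(key = ck$key, profile = prof), f)
  prof
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the configuration, the
#' seed actually used, and the package version.
#'
#' @param cfg A `pleio_config`.
#' @param path Output JSON path.
#' @param seed Seed used for the run (defaults to `cfg$seed`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, path, seed = cfg$seed) {
  jsonlite::write_json(
    list(config = unclass(cfg), seed = seed,
         package = "pleiosim",
         version = as.character(utils::packageVersion("pleiosim")),
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
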