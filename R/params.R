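# Model parameters and validation. Defaults are the standard parameter set
# used throughout: strong selection at both levels, groups of ~200 cells
# living an expected 20 time units (a cell lives ~1), rare loss-of-function
# mutations and 100-fold rarer gains.

.param_defaults <- list(
  s_c   = 0.95,    # strength of within-group selection
  s_g   = 0.95,    # strength of between-group selection
  lambda = 20,     # expected group life span (time units)
  K     = 200L,    # carrying capacity (group size at maturity)
  mu    = 1e-4,    # loss-of-function mutation rate per trait per division
  nu    = 0.01,    # gain-of-function rate relative to mu
  phi   = 0,       # strength of pleiotropy
  zeta  = 0,       # cost of pleiotropy on group function
  alpha = 0,       # maturity fraction of life span before reproduction
  gamma = 0,       # germ-line strength (founder-genotype transmission)
  control_private = FALSE  # variant: cooperative trait replaced by a
                           # second private trait
)

#' Model parameters
#'
#' Constructs and validates the full scalar parameter set of the model.
#' Any subset may be supplied; the rest take the standard defaults
#' (`s_c = s_g = 0.95`, `lambda = 20`, `K = 200`, `mu = 1e-4`, `nu = 0.01`,
#' `phi = zeta = alpha = gamma = 0`).
#'
#' @param s_c Strength of within-group selection, in \[0, 1).
#' @param s_g Strength of between-group selection, in \[0, 1).
#' @param lambda Expected group life span in time units, > 1. The group
#'   reproduction rate is `rho = 1/lambda` (derived, never stored).
#' @param K Carrying capacity of groups (integer >= 2).
#' @param mu Loss-of-function mutation rate per trait per cell division.
#' @param nu Gain-of-function rate relative to `mu`, in (0, 1\].
#' @param phi Strength of pleiotropy, in \[0, 1\].
#' @param zeta Cost of pleiotropy on group function, in \[0, 1\].
#' @param alpha Fraction of `lambda` a group must age before it can
#'   reproduce, in \[0, 1\].
#' @param gamma Germ-line strength: probability a reproducing group
#'   transmits its founder genotype rather than a random resident cell.
#' @param control_private If `TRUE`, the cooperative trait slot is
#'   reinterpreted as a second private trait that *raises* the carrier's
#'   birth rate (control model).
#' @param ... Ignored; present so a config list can be spliced in.
#' @return An object of class `pleio_params` (a validated named list).
#' @export
#' @examples
#' p <- model_params(phi = 1, lambda = 50)
#' p$lambda
model_params <- function(s_c = NULL, s_g = NULL, lambda = NULL, K = NULL,
                         mu = NULL, nu = NULL, phi = NULL, zeta = NULL,
                         alpha = NULL, gamma = NULL, control_private = NULL,
                         ...) {
  supplied <- list(s_c = s_c, s_g = s_g, lambda = lambda, K = K, mu = mu,
                   nu = nu, phi = phi, zeta = zeta, alpha = alpha,
                   gamma = gamma, control_private = control_private)
  supplied <- supplied[!vapply(supplied, is.null, logical(1))]
  p <- modifyList(.param_defaults, supplied)

  in01 <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  ok <- c(
    s_c   = in01(p$s_c) && p$s_c < 1,
    s_g   = in01(p$s_g) && p$s_g < 1,
    lambda = is.numeric(p$lambda) && length(p$lambda) == 1L && p$lambda > 1,
    K     = is.numeric(p$K) && length(p$K) == 1L && p$K >= 2 &&
            p$K == as.integer(p$K),
    mu    = in01(p$mu),
    nu    = is.numeric(p$nu) && length(p$nu) == 1L && p$nu > 0 && p$nu <= 1,
    phi   = in01(p$phi),
    zeta  = in01(p$zeta),
    alpha = in01(p$alpha),
    gamma = in01(p$gamma),
    control_private = is.logical(p$control_private) &&
      length(p$control_private) == 1L && !is.na(p$control_private)
  )
  if (!all(ok))
    stop("invalid parameter value(s): ", paste(names(ok)[!ok], collapse = ", "))
  p$K <- as.integer(p$K)
  structure(p, class = "pleio_params")
}

#' @export
print.pleio_params <- function(x, ...) {
  cat("Model parameters:\n")
  for (nm in names(x))
    cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Group reproduction rate rho = 1/lambda (derived quantity).
rho_of <- function(params) 1 / params$lambda
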