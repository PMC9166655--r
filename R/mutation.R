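# Mutation kernel: null and pleiotropic 8 x 8 transition matrices and their
# convex blend, plus offspring sampling.
#
# Loss-of-function mutations occur at rate mu per trait per cell division;
# gain-of-function at rate nu * mu (nu <= 1, reflecting the bias that it is
# easier to break a trait than to create one). Under the null model traits
# mutate independently. Under the pleiotropic model, a fully active cell
# (genotype g8) that suffers a loss-of-function mutation in the cooperative
# or private trait loses both together; the blend parameter phi in [0, 1]
# is the strength of pleiotropy.

check_mutation_params <- function(mu, nu, phi = 0) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0, mu <= 1,
            is.numeric(nu), length(nu) == 1L, nu > 0, nu <= 1,
            nu * mu <= 1,
            is.numeric(phi), length(phi) == 1L, phi >= 0, phi <= 1)
  invisible(TRUE)
}

#' Null (independent-trait) mutation matrix
#'
#' Builds the 8 x 8 genotype transition matrix under the null model in which
#' each of the three traits mutates independently during a cell division:
#' active -> inactive with probability `mu`, inactive -> active with
#' probability `nu * mu`. Entry (i, j) is the product over the three traits
#' of the per-trait channel probabilities.
#'
#' @param mu Loss-of-function mutation rate per trait per division, in
#'   \[0, 1\].
#' @param nu Gain-of-function rate relative to `mu`, in (0, 1\].
#' @return Row-stochastic 8 x 8 matrix with dimnames `g1..g8`.
#' @export
#' @examples
#' Q <- mutation_null(1e-4, 0.01)
#' Q[1, 1]  # (1 - nu*mu)^3
mutation_null <- function(mu, nu) {
  check_mutation_params(mu, nu)
  Z <- genotype_table()
  M <- matrix(1, 8, 8, dimnames = list(rownames(Z), rownames(Z)))
  for (tr in 1:3) {
    a <- Z[, tr]                       # ancestor trait state, length 8
    # per-trait channel probability matrix: rows ancestor, cols descendant
    ch <- outer(a, Z[, tr], function(from, to)
      ifelse(from == 1,
             ifelse(to == 0, mu, 1 - mu),
             ifelse(to == 1, nu * mu, 1 - nu * mu)))
    M <- M * ch
  }
  M
}

#' Pleiotropic mutation matrix
#'
#' Identical to [mutation_null()] except for the final row (ancestor `g8`,
#' all traits active), where loss-of-function mutations of the cooperative
#' and private traits are fully coupled:
#' \deqn{p_{8,1} = 2\mu - \mu^2,\quad p_{8,7} = (1-\mu)^2\mu,\quad
#'       p_{8,8} = 1 - (2\mu - \mu^2) - (1-\mu)^2\mu,}
#' with all other entries of that row zero. A pleiotropic double loss
#' removes all three traits (descendant `g1`); loss of the pleiotropy trait
#' alone gives `g7`; no gain-of-function terms appear in this row.
#'
#' @inheritParams mutation_null
#' @return Row-stochastic 8 x 8 matrix.
#' @export
mutation_pleiotropic <- function(mu, nu) {
  P <- mutation_null(mu, nu)
  row8 <- c(2 * mu - mu^2, 0, 0, 0, 0, 0, (1 - mu)^2 * mu,
            1 - (2 * mu - mu^2) - (1 - mu)^2 * mu)
  P[8, ] <- row8
  P
}

#' Effective mutation matrix at pleiotropy strength phi
#'
#' Convex combination `phi * P + (1 - phi) * Q` of the pleiotropic and null
#' matrices; `phi` scales how often a mutation in a fully active cell has a
#' pleiotropic (joint-loss) outcome.
#'
#' @inheritParams mutation_null
#' @param phi Strength of pleiotropy in \[0, 1\].
#' @return Row-stochastic 8 x 8 matrix.
#' @export
#' @examples
#' H <- mutation_matrix(1e-4, 0.01, phi = 0.5)
mutation_matrix <- function(mu, nu, phi = 0) {
  check_mutation_params(mu, nu, phi)
  if (phi == 0) return(mutation_null(mu, nu))
  if (phi == 1) return(mutation_pleiotropic(mu, nu))
  phi * mutation_pleiotropic(mu, nu) + (1 - phi) * mutation_null(mu, nu)
}

#' Sample offspring genotypes from a mutation matrix
#'
#' Draws descendant genotypes for a dividing cell of genotype `i` by
#' inverse-CDF sampling on row `i` of the transition matrix, using the
#' package's counter-based random stream so that results are reproducible
#' given `seed` (independently of R's global RNG state).
#'
#' @param i Ancestor genotype index in 1..8.
#' @param matrix An 8 x 8 row-stochastic mutation matrix.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Integer vector of descendant genotype indices.
#' @export
sample_offspring <- function(i, matrix, n = 1L, seed = 1L) {
  stopifnot(i %in% 1:8, is.matrix(matrix), all(dim(matrix) == c(8, 8)))
  u <- runif_stream_cpp(as.integer(n), as.double(seed))
  cdf <- cumsum(matrix[i, ])
  as.integer(findInterval(u, cdf, left.open = TRUE) + 1L)
}

#' Write a mutation matrix to CSV
#'
#' Exports an 8 x 8 matrix with a `g1..g8` header row and an `ancestor`
#' label column, the format used by the test fixtures.
#'
#' @param m Matrix to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(ancestor = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mutation matrix written by [write_matrix_csv()]
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
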