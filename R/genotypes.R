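# Genotype-phenotype map for cells and enumeration of group types.
#
# Cells carry three binary traits: a cooperative (public) trait z_u, a
# private trait z_v, and a pleiotropy trait z_p. The 2^3 = 8 genotypes are
# labelled g1..g8 in the fixed row order of the trait map below. Internally
# all matrix code is plain 1..8 integer indexing; the g-labels appear on
# every user-facing table.

# 8 x 3 binary trait map, rows g1..g8, columns (z_u, z_v, z_p).
.Z <- matrix(c(
  0L, 0L, 0L,
  0L, 0L, 1L,
  0L, 1L, 0L,
  0L, 1L, 1L,
  1L, 0L, 0L,
  1L, 0L, 1L,
  1L, 1L, 0L,
  1L, 1L, 1L), nrow = 8L, ncol = 3L, byrow = TRUE,
  dimnames = list(paste0("g", 1:8), c("z_u", "z_v", "z_p")))

#' The cell genotype-phenotype map
#'
#' Returns the 8 x 3 binary matrix mapping each of the 8 cell genotypes
#' (rows `g1`..`g8`) to its trait vector (columns `z_u` = cooperative trait,
#' `z_v` = private trait, `z_p` = pleiotropy trait).
#'
#' @return An 8 x 3 integer matrix with dimnames.
#' @export
#' @examples
#' genotype_table()
genotype_table <- function() .Z

#' Trait vector of a genotype
#'
#' @param i Genotype index in 1..8 (may be a vector).
#' @return For scalar `i`, a named integer vector `(z_u, z_v, z_p)`;
#'   for vector `i`, the corresponding rows of [genotype_table()].
#' @export
#' @examples
#' genotype_traits(8)  # all three traits active
genotype_traits <- function(i) {
  if (!is.numeric(i) || any(is.na(i)) || any(i < 1) || any(i > 8) ||
      any(i != as.integer(i)))
    stop("invalid genotype index: must be an integer in 1..8")
  if (length(i) == 1L) .Z[i, ] else .Z[i, , drop = FALSE]
}

#' Genotype index of a trait vector
#'
#' Inverse of [genotype_traits()]: maps a binary triple
#' `(z_u, z_v, z_p)` to its genotype index.
#'
#' @param z_u,z_v,z_p Binary trait values (0 or 1). Alternatively pass a
#'   length-3 vector as `z_u` and leave the others missing.
#' @return Integer genotype index in 1..8.
#' @export
#' @examples
#' genotype_of(1, 1, 0)  # 7
genotype_of <- function(z_u, z_v, z_p) {
  if (missing(z_v) && length(z_u) == 3L) {
    z_p <- z_u[3]; z_v <- z_u[2]; z_u <- z_u[1]
  }
  z <- c(z_u, z_v, z_p)
  if (length(z) != 3L || !all(z %in% c(0, 1)))
    stop("trait vector must be a binary triple")
  as.integer(4 * z[1] + 2 * z[2] + z[3] + 1)
}

#' Enumerate group types by founding composition
#'
#' A group's type is the unordered multiset of its founding cell genotypes.
#' With a single founding cell there are 8 group types; with two founding
#' cells there are `choose(8, 2) + 8 = 36` (unordered pairs including
#' doubles).
#'
#' @param n_founders Number of founding cells, 1 or 2.
#' @return A list of integer vectors (sorted founder genotype indices), of
#'   length 8 (`n_founders = 1`) or 36 (`n_founders = 2`). Each element is
#'   named by its label, e.g. `"g4+g8"`.
#' @export
#' @examples
#' length(group_types(2))  # 36
group_types <- function(n_founders = 1L) {
  if (!n_founders %in% c(1L, 2L))
    stop("unsupported founding size: n_founders must be 1 or 2")
  if (n_founders == 1L) {
    out <- lapply(1:8, function(i) i)
  } else {
    out <- list()
    for (a in 1:8) for (b in a:8) out[[length(out) + 1L]] <- c(a, b)
  }
  names(out) <- vapply(out, group_type_label, character(1))
  out
}

#' Label for a group type
#'
#' @param founders Integer vector of founder genotype indices.
#' @return Character label such as `"g8"` or `"g4+g8"`.
#' @export
group_type_label <- function(founders) {
  paste(paste0("g", sort(as.integer(founders))), collapse = "+")
}

# Mean founder trait vector of a group type (used for mutational load and
# group-level initial traits).
founder_traits <- function(founders) {
  colMeans(.Z[as.integer(founders), , drop = FALSE])
}
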