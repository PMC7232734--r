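#' Restrict expression matrices to their common gene universe
#'
#' All downstream cross-tissue comparisons require a shared gene universe, so
#' every matrix is restricted to the set intersection of all gene identifier
#' sets, with rows reordered into a canonical (lexicographic, C-locale)
#' order. Sample columns are untouched.
#'
#' @param matrices List of [expression_matrix()] objects (>= 1).
#' @return List of `expression_matrix` objects, all with identical
#'   `gene_ids()`.
#' @export
intersect_genes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1L ||
      !all(vapply(matrices, inherits, logical(1), "expression_matrix")))
    stop("'matrices' must be a non-empty list of expression_matrix objects")
  common <- Reduce(intersect, lapply(matrices, gene_ids))
  if (length(common) == 0L)
    stop("no common genes across the input matrices")
  common <- sort(common, method = "radix")
  lapply(matrices, function(m)
    expression_matrix(m$values[common, , drop = FALSE], m$tissue))
}

#' Rank-based inverse normal transform (Blom offset)
#'
#' Maps a vector to standard normal quantiles of its ranks:
#' `qnorm((r - 3/8) / (n + 1/4))`, ties receiving the average rank. The
#' result is a nondecreasing function of the input, so absolute Pearson
#' correlations computed afterwards depend on the data only through ranks.
#'
#' @param x Numeric vector of length >= 2, no missing values.
#' @return Numeric vector of the same length.
#' @export
rank_inverse_normal <- function(x) {
  if (!is.numeric(x) || anyNA(x))
    stop("'x' must be numeric with no missing values")
  n <- length(x)
  if (n < 2L)
    stop("need at least 2 observations")
  if (max(x) == min(x))
    stop("zero variance: all values equal")
  r <- rank(x, ties.method = "average")
  qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Rank-normalize every gene of an expression matrix
#'
#' Applies [rank_inverse_normal()] independently to each gene's profile
#' across samples, so that every gene's expression is marginally standard
#' normal and Pearson correlation between genes becomes a rank-based
#' measure of association.
#'
#' @param m An [expression_matrix()].
#' @return An `expression_matrix` of the same shape.
#' @export
normalize_matrix <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  vals <- m$values
  rng <- apply(vals, 1L, function(v) max(v) - min(v))
  if (any(rng == 0))
    stop("constant expression for gene(s): ",
         paste(head(rownames(vals)[rng == 0], 5L), collapse = ", "))
  out <- t(apply(vals, 1L, rank_inverse_normal))
  dimnames(out) <- dimnames(vals)
  expression_matrix(out, m$tissue)
}
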