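#' Coexpression similarity matrix (absolute Pearson correlation)
#'
#' `S[m, n] = |cor(x_m, x_n)|` between gene profiles across samples. The
#' network is undirected, so the sign of the correlation is dropped; the
#' diagonal is 1.
#'
#' @param m An [expression_matrix()] with >= 3 samples and no constant gene.
#' @return Symmetric numeric matrix in \[0, 1\] with gene identifiers as
#'   dimnames.
#' @export
similarity_matrix <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  x <- m$values
  if (ncol(x) < 3L)
    stop("need at least 3 samples to estimate correlations")
  sds <- apply(x, 1L, sd)
  if (any(sds == 0))
    stop("constant expression for gene(s): ",
         paste(head(rownames(x)[sds == 0], 5L), collapse = ", "))
  S <- abs(cor(t(x)))
  S[S > 1] <- 1
  diag(S) <- 1
  S
}

#' Soft-threshold power adjacency
#'
#' Raises every similarity elementwise to the power `beta`
#' (`a[m, n] = S[m, n]^beta`), the soft-thresholding step that downweights
#' weak correlations while keeping the network weighted. The diagonal is
#' forced to 1.
#'
#' @param S Similarity matrix from [similarity_matrix()].
#' @param beta Soft power, >= 1 (conventionally an integer; default 6).
#' @return Adjacency matrix of the same shape.
#' @export
adjacency <- function(S, beta = 6) {
  .check_sym01(S, "S")
  if (length(beta) != 1L || !is.finite(beta) || beta < 1)
    stop("'beta' must be a single number >= 1")
  A <- S^beta
  diag(A) <- 1
  A
}

#' Weighted connectivity of each node
#'
#' `k[m] = sum_{u != m} a[m, u]`: the sum of a gene's adjacency weights to
#' all other genes, excluding the self term.
#'
#' @param A Adjacency matrix.
#' @return Numeric vector of connectivities.
#' @export
connectivity <- function(A) {
  .check_sym01(A, "A")
  rowSums(A) - diag(A)
}

#' Topological overlap matrix
#'
#' For `m != n`:
#' `omega[m, n] = (l[m, n] + a[m, n]) / (min(k[m], k[n]) + 1 - a[m, n])`
#' with `l[m, n] = sum_{u != m, n} a[m, u] * a[u, n]` the shared-neighbor
#' term and `k` the connectivity of [connectivity()]. The diagonal is 1.
#' With adjacencies in \[0, 1\] every entry lies in \[0, 1\]; two genes have
#' high topological overlap when they are directly connected and share
#' neighbors.
#'
#' @param A Symmetric adjacency matrix with entries in \[0, 1\].
#' @return Topological overlap matrix `Omega` of the same shape.
#' @export
tom <- function(A) {
  .check_sym01(A, "A", require_sym = TRUE)
  A0 <- A
  diag(A0) <- 0
  # l[m,n] = sum_u a_mu a_un over u != m, n: with a zeroed diagonal the
  # matrix product already omits u = m and u = n
  L <- A0 %*% A0
  k <- rowSums(A0)
  denom <- outer(k, k, pmin) + 1 - A0
  Omega <- (L + A0) / denom
  diag(Omega) <- 1
  Omega[Omega < 0] <- 0
  Omega[Omega > 1] <- 1
  Omega <- (Omega + t(Omega)) / 2
  dimnames(Omega) <- dimnames(A)
  Omega
}

#' Scale-free topology fit of a weighted network
#'
#' Bins the connectivities into `n_bins` equal-width bins, takes per
#' non-empty bin the mean connectivity and the empirical frequency, and
#' reports the signed squared Pearson correlation between `log10(mean k)`
#' and `log10(p(k))`. A strongly negative-sloped, near-perfect fit
#' (signed R^2 close to -1 in sign convention, |R^2| >= 0.8) indicates an
#' approximately power-law (scale-free) degree distribution.
#'
#' @param A Adjacency matrix.
#' @param n_bins Number of equal-width connectivity bins (>= 4).
#' @return List with `signed_r2` (sign(slope) * R^2; `NA` when degenerate),
#'   `r` (the raw correlation), `mean_connectivity`, `n_bins_used`, and
#'   `flag` (`"ok"` or `"degenerate"` when the fit is undefined, e.g. all
#'   connectivities equal).
#' @export
scale_free_fit <- function(A, n_bins = 10) {
  .check_sym01(A, "A")
  if (n_bins < 4) stop("'n_bins' must be >= 4")
  sf_fit_from_connectivity(connectivity(A), n_bins)
}

# binned log-log regression on a raw connectivity vector
sf_fit_from_connectivity <- function(k, n_bins = 10) {
  mk <- mean(k)
  if (max(k) - min(k) <= 1e-12 * max(max(k), 1)) {
    return(list(signed_r2 = NA_real_, r = NA_real_, mean_connectivity = mk,
                n_bins_used = 1L, flag = "degenerate"))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  keep <- cnt > 0L
  bmean <- vapply(levels(bin)[keep],
                  function(l) mean(k[bin == l]), numeric(1))
  p <- cnt[keep] / length(k)
  usable <- bmean > 0
  bmean <- bmean[usable]
  p <- p[usable]
  if (length(p) < 3L || max(p) == min(p) || max(bmean) == min(bmean)) {
    return(list(signed_r2 = NA_real_, r = NA_real_, mean_connectivity = mk,
                n_bins_used = length(p), flag = "degenerate"))
  }
  r <- cor(log10(bmean), log10(p))
  list(signed_r2 = sign(r) * r^2, r = r, mean_connectivity = mk,
       n_bins_used = length(p), flag = "ok")
}

#' Sweep candidate soft powers and pick the pipeline power
#'
#' Computes [scale_free_fit()] diagnostics at every candidate power. In
#' `"fixed"` mode (the default) the chosen power is `fixed_power` (6)
#' regardless of the sweep — one common power keeps networks comparable
#' across tissues — and the sweep is reported for inspection. In `"strict"`
#' mode the smallest power whose scale-free fit satisfies
#' `|signed_r2| >= r2_threshold` is chosen; if none qualifies, the power
#' with the best fit is chosen and flagged.
#'
#' @param m An [expression_matrix()] (already normalized).
#' @param powers Candidate powers (default 1:20).
#' @param mode `"fixed"` or `"strict"`.
#' @param fixed_power Power used in fixed mode (default 6).
#' @param r2_threshold Scale-free R^2 criterion for strict mode (default 0.8).
#' @param n_bins Bins for [scale_free_fit()].
#' @return Object of class `power_diagnostics`: list with `table`
#'   (data.frame power / signed_r2 / r / mean_connectivity / flag),
#'   `chosen_power`, `mode`, `criterion_met`.
#' @export
power_sweep <- function(m, powers = 1:20, mode = c("fixed", "strict"),
                        fixed_power = 6, r2_threshold = 0.8, n_bins = 10) {
  mode <- match.arg(mode)
  if (length(powers) < 1L || any(powers < 1))
    stop("'powers' must all be >= 1")
  S <- similarity_matrix(m)
  rows <- lapply(powers, function(b) {
    sf <- scale_free_fit(adjacency(S, b), n_bins = n_bins)
    data.frame(power = b, signed_r2 = sf$signed_r2, r = sf$r,
               mean_connectivity = sf$mean_connectivity, flag = sf$flag,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  criterion_met <- TRUE
  if (mode == "fixed") {
    chosen <- fixed_power
  } else {
    ok <- which(!is.na(tab$signed_r2) & abs(tab$signed_r2) >= r2_threshold)
    if (length(ok)) {
      chosen <- tab$power[ok[1L]]
    } else {
      criterion_met <- FALSE
      best <- which.max(abs(tab$signed_r2))
      chosen <- if (length(best)) tab$power[best] else fixed_power
    }
  }
  structure(list(table = tab, chosen_power = chosen, mode = mode,
                 criterion_met = criterion_met, tissue = m$tissue),
            class = "power_diagnostics")
}

#' @export
print.power_diagnostics <- function(x, ...) {
  cat(sprintf("power sweep (%s mode): chosen power %s%s\n", x$mode,
              x$chosen_power,
              if (x$criterion_met) "" else " [scale-free criterion not met]"))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Diagnostic plot of a power sweep
#'
#' Two panels: soft power versus signed scale-free fit index, and soft power
#' versus mean connectivity.
#'
#' @param x A `power_diagnostics` object.
#' @param ... Unused.
#' @export
plot.power_diagnostics <- function(x, ...) {
  tab <- x$table
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(tab$power, -tab$signed_r2, type = "b", xlab = "soft power",
       ylab = "scale-free fit, signed R^2 (sign flipped)",
       main = "Scale-free topology fit")
  graphics::abline(h = 0.8, col = "red", lty = 2)
  plot(tab$power, tab$mean_connectivity, type = "b", xlab = "soft power",
       ylab = "mean connectivity", main = "Mean connectivity")
  invisible(x)
}

#' Build the full coexpression network for one tissue
#'
#' Chains [similarity_matrix()], [adjacency()] at the given power, [tom()],
#' and the dissimilarity `D = 1 - Omega` used for clustering.
#'
#' @param m An [expression_matrix()] (already normalized).
#' @param beta Soft power (default 6).
#' @return Object of class `coexpression_network`: list with `tissue`,
#'   `gene_ids`, `S`, `beta`, `A`, `Omega`, `D`.
#' @export
build_network <- function(m, beta = 6) {
  S <- similarity_matrix(m)
  A <- adjacency(S, beta)
  Omega <- tom(A)
  D <- 1 - Omega
  structure(list(tissue = m$tissue, gene_ids = rownames(m$values),
                 S = S, beta = beta, A = A, Omega = Omega, D = D),
            class = "coexpression_network")
}

#' @export
gene_ids.coexpression_network <- function(x) x$gene_ids

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: tissue '%s', %d genes, power %s\n",
              x$tissue, length(x$gene_ids), format(x$beta)))
  invisible(x)
}

# shared validation for similarity/adjacency-like matrices
.check_sym01 <- function(M, name, require_sym = TRUE, tol = 1e-8) {
  if (!is.matrix(M) || !is.numeric(M) || nrow(M) != ncol(M))
    stop("'", name, "' must be a square numeric matrix")
  if (anyNA(M)) stop("'", name, "' contains missing values")
  if (min(M) < -tol || max(M) > 1 + tol)
    stop("'", name, "' entries must lie in [0, 1]")
  if (require_sym && max(abs(M - t(M))) > tol)
    stop("'", name, "' must be symmetric")
  invisible(TRUE)
}
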