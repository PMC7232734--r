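#' Build the 2x2 gene-overlap contingency table of two modules
#'
#' Counts over a common gene universe: genes in both modules, in A only, in
#' B only, and in neither.
#'
#' @param genes_a,genes_b Character vectors of gene identifiers, each a
#'   subset of `universe`.
#' @param universe Character vector: the common gene universe.
#' @return Named integer vector `c(both, a_only, b_only, neither)` summing
#'   to `length(unique(universe))`.
#' @export
overlap_table <- function(genes_a, genes_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("'universe' must be non-empty")
  genes_a <- unique(genes_a)
  genes_b <- unique(genes_b)
  if (!all(genes_a %in% universe))
    stop("genes_a contains genes outside the universe")
  if (!all(genes_b %in% universe))
    stop("genes_b contains genes outside the universe")
  both <- length(intersect(genes_a, genes_b))
  c(both = both,
    a_only = length(genes_a) - both,
    b_only = length(genes_b) - both,
    neither = length(universe) - length(genes_a) - length(genes_b) + both)
}

#' One-sided Fisher exact p-value for module overlap
#'
#' Upper-tail (enrichment) Fisher exact test: the probability, under the
#' hypergeometric null with the table's margins, of an overlap at least as
#' large as observed. Computed in log space via `phyper(log.p = TRUE)` so
#' that extremely small p-values (down to ~1e-300 and beyond on the log10
#' scale) are returned without underflow. A one-sided test is used because
#' module "relatedness" means over-overlap; depletion is not of interest.
#'
#' @param table Nonnegative integer vector `c(both, a_only, b_only,
#'   neither)` as from [overlap_table()].
#' @param log10 If `TRUE` return log10 of the p-value (finite even when the
#'   p-value underflows double precision); default `FALSE`.
#' @return The p-value (or its log10).
#' @export
fisher_p <- function(table, log10 = FALSE) {
  if (length(table) != 4L || anyNA(table) || any(table < 0) ||
      any(table != round(table)))
    stop("'table' must be 4 nonnegative integer counts")
  lp <- .fisher_log_p(table[1L], table[2L], table[3L], table[4L])
  if (log10) lp / log(10) else exp(lp)
}

# natural-log upper-tail hypergeometric p for counts (both, a_only, b_only,
# neither); vectorized over the four count vectors
.fisher_log_p <- function(both, a_only, b_only, neither) {
  size_a <- both + a_only
  size_b <- both + b_only
  n_univ <- both + a_only + b_only + neither
  lp <- phyper(both - 1, size_a, n_univ - size_a, size_b,
               lower.tail = FALSE, log.p = TRUE)
  # P(X >= 0) = 1 exactly (phyper already returns 0 here, incl. empty margins)
  lp[both <= 0] <- 0
  lp
}

#' All-pairs module overlap graph across tissues
#'
#' Tests every pair of non-grey modules from different tissues for gene
#' overlap with the one-sided Fisher exact test over the common gene
#' universe, and retains as edges the pairs with p below `alpha` (raw p by
#' default, mirroring the p < 0.05 edge rule; Bonferroni optionally). The
#' full results table is kept for every tested pair, significant or not.
#'
#' @param partitions List of `module_partition` objects (>= 1), all over the
#'   same gene universe.
#' @param universe Optional character vector; defaults to the partitions'
#'   (identical) gene sets.
#' @param alpha Edge significance threshold (default 0.05).
#' @param correction `"none"` (default, the raw-p rule) or `"bonferroni"`.
#' @return Object of class `module_overlap_graph`: list with
#'   `nodes` (data.frame tissue / module / size),
#'   `results` (data.frame tissue_a / module_a / tissue_b / module_b /
#'   n11 / n10 / n01 / n00 / log10_p / p — every tested pair once),
#'   `edges` (the significant subset), `alpha`, `correction`,
#'   `universe_size`.
#' @export
build_module_graph <- function(partitions, universe = NULL, alpha = 0.05,
                               correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (!is.list(partitions) || length(partitions) < 1L ||
      !all(vapply(partitions, inherits, logical(1), "module_partition")))
    stop("'partitions' must be a list of module_partition objects")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  tissues <- vapply(partitions, `[[`, character(1), "tissue")
  if (anyDuplicated(tissues)) stop("duplicate tissue identifiers")
  gene_sets <- lapply(partitions, function(p)
    sort(names(p$assignment), method = "radix"))
  for (i in seq_along(gene_sets)[-1])
    if (!identical(gene_sets[[i]], gene_sets[[1]]))
      stop("partitions are not over the same gene universe")
  if (is.null(universe)) universe <- gene_sets[[1]]
  universe <- unique(universe)
  if (!all(gene_sets[[1]] %in% universe))
    stop("partition genes fall outside the supplied universe")
  n_univ <- length(universe)

  nodes <- do.call(rbind, lapply(partitions, function(p) {
    sz <- module_sizes(p)
    if (!length(sz)) return(NULL)
    data.frame(tissue = p$tissue, module = names(sz), size = unname(sz),
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes))
    nodes <- data.frame(tissue = character(), module = character(),
                        size = integer(), stringsAsFactors = FALSE)

  res <- list()
  np <- length(partitions)
  if (np >= 2L) {
    for (i in seq_len(np - 1L)) {
      for (j in seq.int(i + 1L, np)) {
        pa <- partitions[[i]]; pb <- partitions[[j]]
        # cross-tabulate the two assignments over the shared genes
        ga <- pa$assignment[gene_sets[[1]]]
        gb <- pb$assignment[gene_sets[[1]]]
        keep_a <- setdiff(unique(ga), "grey")
        keep_b <- setdiff(unique(gb), "grey")
        if (!length(keep_a) || !length(keep_b)) next
        ct <- table(ga, gb)
        sa <- table(ga)[keep_a]
        sb <- table(gb)[keep_b]
        grid <- expand.grid(module_a = keep_a, module_b = keep_b,
                            stringsAsFactors = FALSE)
        n11 <- as.integer(ct[cbind(grid$module_a, grid$module_b)])
        n10 <- as.integer(sa[grid$module_a]) - n11
        n01 <- as.integer(sb[grid$module_b]) - n11
        n00 <- n_univ - n11 - n10 - n01
        lp <- .fisher_log_p(n11, n10, n01, n00)
        res[[length(res) + 1L]] <- data.frame(
          tissue_a = pa$tissue, module_a = grid$module_a,
          tissue_b = pb$tissue, module_b = grid$module_b,
          n11 = n11, n10 = n10, n01 = n01, n00 = n00,
          log10_p = lp / log(10), p = exp(lp),
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- if (length(res)) do.call(rbind, res) else
    data.frame(tissue_a = character(), module_a = character(),
               tissue_b = character(), module_b = character(),
               n11 = integer(), n10 = integer(), n01 = integer(),
               n00 = integer(), log10_p = numeric(), p = numeric(),
               stringsAsFactors = FALSE)
  results <- results[order(results$log10_p, results$tissue_a,
                           results$module_a, results$tissue_b,
                           results$module_b, method = "radix"), ,
                     drop = FALSE]
  rownames(results) <- NULL

  thr <- if (correction == "bonferroni" && nrow(results) > 0)
    alpha / nrow(results) else alpha
  # compare on the log10 scale so p-values that underflow to 0 still qualify
  edges <- results[results$log10_p < log10(thr), , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(nodes = nodes, results = results, edges = edges,
                 alpha = alpha, correction = correction,
                 universe_size = n_univ),
            class = "module_overlap_graph")
}

#' @export
print.module_overlap_graph <- function(x, ...) {
  cat(sprintf("module_overlap_graph: %d module nodes, %d/%d pairs significant at alpha = %s (%s)\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$results),
              format(x$alpha), x$correction))
  invisible(x)
}

#' Tissue-level similarity summary from the module overlap results
#'
#' Per tissue pair: the minimum module-pair p-value (reported on the log10
#' scale as well, since minima routinely underflow on real atlases) and the
#' count of significant module pairs. Ranking tissue pairs by `min_log10_p`
#' defines the "closest" tissues.
#'
#' @param graph A `module_overlap_graph` from [build_module_graph()].
#' @return data.frame with columns tissue_a, tissue_b, min_p, min_log10_p,
#'   n_significant, n_tested, sorted by `min_log10_p`.
#' @export
tissue_similarity <- function(graph) {
  stopifnot(inherits(graph, "module_overlap_graph"))
  res <- graph$results
  if (nrow(res) == 0L)
    return(data.frame(tissue_a = character(), tissue_b = character(),
                      min_p = numeric(), min_log10_p = numeric(),
                      n_significant = integer(), n_tested = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(res$tissue_a, res$tissue_b, sep = "\t")
  out <- do.call(rbind, lapply(split(res, key), function(d) {
    i <- which.min(d$log10_p)
    data.frame(tissue_a = d$tissue_a[1], tissue_b = d$tissue_b[1],
               min_p = d$p[i], min_log10_p = d$log10_p[i],
               n_significant = sum(d$log10_p < log10(graph$alpha)),
               n_tested = nrow(d), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$min_log10_p, out$tissue_a, out$tissue_b,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the overlap results or edge list as tab-separated text
#'
#' @param graph A `module_overlap_graph`.
#' @param path Output file path.
#' @param what `"results"` (every tested pair) or `"edges"` (significant
#'   pairs only).
#' @return `path`, invisibly.
#' @export
write_overlap <- function(graph, path, what = c("results", "edges")) {
  stopifnot(inherits(graph, "module_overlap_graph"))
  what <- match.arg(what)
  write.table(graph[[what]], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
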