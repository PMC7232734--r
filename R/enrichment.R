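#' Read a gene-set collection in GMT format
#'
#' One term per line, tab-separated: term identifier, description, then one
#' or more member genes. Duplicate genes within a term are dropped; a line
#' with no genes, or a duplicated term identifier, is an error reported with
#' its line number.
#'
#' @param path Path to a GMT file.
#' @return Object of class `gene_set_collection`: list with `terms` (named
#'   list of character gene vectors), `descriptions` (named character), and
#'   `source` (the path).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  terms <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i,
           ": expected term, description and >= 1 gene")
    id <- f[1]
    if (!nzchar(id)) stop("malformed GMT line ", i, ": empty term id")
    if (id %in% names(terms))
      stop("malformed GMT line ", i, ": duplicate term id '", id, "'")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop("malformed GMT line ", i, ": term '", id, "' has no genes")
    terms[[id]] <- genes
    descriptions[id] <- f[2]
  }
  structure(list(terms = terms, descriptions = descriptions, source = path),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$terms)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms from %s\n",
              length(x$terms), x$source))
  invisible(x)
}

#' Write a gene-set collection in GMT format
#'
#' @param collection A `gene_set_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$terms), function(id)
    paste(c(id, collection$descriptions[[id]], collection$terms[[id]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment
#'
#' For each term, the upper-tail hypergeometric p-value of the overlap
#' between the query gene set and the term's genes within the universe:
#' `p = P(X >= overlap)` with `X ~ Hypergeometric(universe_size, term_size,
#' query_size)`. Terms are first intersected with the universe; terms with
#' empty intersection are dropped. Fold enrichment is
#' `(overlap / query_size) / (term_size / universe_size)`. Multiple-testing
#' columns over the `m` tested terms: Bonferroni (`min(1, m * p)`) and
#' Benjamini–Hochberg; the `fdr` column is an alias of the
#' Benjamini–Hochberg value. Corrections are computed over all `m` tested
#' terms, but terms with zero overlap are omitted from the returned table
#' (their p-value is 1 by definition).
#'
#' @param query Character vector of genes, a subset of `universe`.
#' @param collection A `gene_set_collection` from [read_gmt()].
#' @param universe Character vector: the background gene universe (for
#'   module enrichment, the tissue's network gene set).
#' @return data.frame sorted by increasing p-value with columns term_id,
#'   description, overlap, query_size, term_size, universe_size,
#'   fold_enrichment, p_value, log10_p, bonferroni, benjamini, fdr.
#' @export
hypergeom_enrich <- function(query, collection, universe) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe)
  if (length(universe) == 0L) stop("'universe' must be non-empty")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  n_univ <- length(universe)
  nq <- length(query)
  term_in_univ <- lapply(collection$terms, intersect, universe)
  keep <- lengths(term_in_univ) > 0L
  term_in_univ <- term_in_univ[keep]
  m <- length(term_in_univ)
  if (m == 0L)
    return(.empty_enrichment())
  overlap <- vapply(term_in_univ, function(g)
    length(intersect(g, query)), integer(1))
  term_size <- lengths(term_in_univ)
  lp <- phyper(overlap - 1, term_size, n_univ - term_size, nq,
               lower.tail = FALSE, log.p = TRUE)
  lp[overlap <= 0] <- 0
  p <- exp(lp)
  fold <- if (nq > 0) (overlap / nq) / (term_size / n_univ) else
    rep(NA_real_, m)
  bh <- p.adjust(p, method = "BH")
  out <- data.frame(term_id = names(term_in_univ),
                    description = unname(collection$descriptions[names(term_in_univ)]),
                    overlap = overlap, query_size = nq,
                    term_size = term_size, universe_size = n_univ,
                    fold_enrichment = fold, p_value = p,
                    log10_p = lp / log(10),
                    bonferroni = pmin(1, p * m), benjamini = bh, fdr = bh,
                    stringsAsFactors = FALSE)
  out <- out[out$overlap > 0, , drop = FALSE]
  out <- out[order(out$log10_p, out$term_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_enrichment <- function() {
  data.frame(term_id = character(), description = character(),
             overlap = integer(), query_size = integer(),
             term_size = integer(), universe_size = integer(),
             fold_enrichment = numeric(), p_value = numeric(),
             log10_p = numeric(), bonferroni = numeric(),
             benjamini = numeric(), fdr = numeric(),
             stringsAsFactors = FALSE)
}

#' Enrichment of every clique member and cross-member summary
#'
#' Applies [hypergeom_enrich()] to each clique member's gene set and
#' summarizes the terms that are significant (Benjamini–Hochberg < `alpha`)
#' in at least a fraction `min_frac` of the members — the "shared function"
#' view of the clique.
#'
#' @param report A `clique_report` from [clique_report()].
#' @param collection A `gene_set_collection`.
#' @param universe Background gene universe (the common network gene set).
#' @param alpha Significance threshold on the BH value (default 0.05).
#' @param min_frac Minimum fraction of members a term must be significant in
#'   to appear in the shared summary (default 0.5).
#' @return Object of class `clique_enrichment`: list with `members` (named
#'   list of per-member enrichment data.frames) and `shared` (data.frame
#'   term_id / description / n_members / frac).
#' @export
enrich_clique <- function(report, collection, universe, alpha = 0.05,
                          min_frac = 0.5) {
  stopifnot(inherits(report, "clique_report"))
  members <- lapply(report$gene_sets, hypergeom_enrich,
                    collection = collection, universe = universe)
  n_mem <- length(members)
  shared <- data.frame(term_id = character(), description = character(),
                       n_members = integer(), frac = numeric(),
                       stringsAsFactors = FALSE)
  if (n_mem > 0) {
    sig_terms <- unlist(lapply(members, function(d)
      d$term_id[d$benjamini < alpha]), use.names = FALSE)
    if (length(sig_terms)) {
      tab <- table(sig_terms)
      keep <- as.integer(tab) / n_mem >= min_frac
      if (any(keep)) {
        ids <- names(tab)[keep]
        shared <- data.frame(term_id = ids,
                             description = unname(collection$descriptions[ids]),
                             n_members = as.integer(tab)[keep],
                             frac = as.integer(tab)[keep] / n_mem,
                             stringsAsFactors = FALSE)
        shared <- shared[order(-shared$n_members, shared$term_id,
                               method = "radix"), , drop = FALSE]
        rownames(shared) <- NULL
      }
    }
  }
  structure(list(members = members, shared = shared, alpha = alpha,
                 min_frac = min_frac),
            class = "clique_enrichment")
}

#' @export
print.clique_enrichment <- function(x, ...) {
  cat(sprintf("clique_enrichment: %d members, %d shared terms (BH < %s in >= %s of members)\n",
              length(x$members), nrow(x$shared), format(x$alpha),
              format(x$min_frac)))
  invisible(x)
}
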