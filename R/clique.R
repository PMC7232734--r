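#' Maximum clique of a module overlap graph
#'
#' Finds the largest set of mutually overlapping modules. Because the graph
#' has no intra-tissue edges, clique members always belong to pairwise
#' distinct tissues. Two modes:
#' \describe{
#'   \item{exact}{Exact maximum clique via igraph's Bron–Kerbosch search
#'     with pivoting ([igraph::largest_cliques]); among equal-size maximum
#'     cliques the lexicographically smallest node-name set is returned, so
#'     the result is deterministic.}
#'   \item{heuristic}{A greedy construction (highest-degree-first) followed
#'     by 1-swap local search; fast on very large graphs but only a lower
#'     bound, and flagged as such in the result.}
#' }
#' The returned members are re-verified against the edge set independently
#' of the search.
#'
#' @param x A `module_overlap_graph` from [build_module_graph()], or an
#'   [igraph::graph] for direct use on arbitrary simple undirected graphs.
#' @param mode `"exact"` (default) or `"heuristic"`.
#' @param ... Passed to methods.
#' @return Object of class `module_clique`: list with `members` (data.frame
#'   tissue / module for graph input; node names otherwise), `size`, `mode`,
#'   and `exact` (logical).
#' @export
max_clique <- function(x, mode = c("exact", "heuristic"), ...) {
  UseMethod("max_clique")
}

#' @rdname max_clique
#' @export
max_clique.module_overlap_graph <- function(x, mode = c("exact", "heuristic"),
                                            ...) {
  mode <- match.arg(mode)
  nodes <- paste(x$nodes$tissue, x$nodes$module, sep = "::")
  if (length(nodes) == 0L) {
    return(structure(list(members = data.frame(tissue = character(),
                                               module = character(),
                                               stringsAsFactors = FALSE),
                          size = 0L, mode = mode, exact = TRUE),
                     class = "module_clique"))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(x$edges) > 0) {
    ea <- paste(x$edges$tissue_a, x$edges$module_a, sep = "::")
    eb <- paste(x$edges$tissue_b, x$edges$module_b, sep = "::")
    g <- igraph::add_edges(g, rbind(ea, eb))
  }
  cl <- max_clique(g, mode = mode)
  parts <- strsplit(cl$members, "::", fixed = TRUE)
  members <- data.frame(tissue = vapply(parts, `[`, character(1), 1L),
                        module = vapply(parts, `[`, character(1), 2L),
                        stringsAsFactors = FALSE)
  structure(list(members = members, size = cl$size, mode = mode,
                 exact = cl$exact),
            class = "module_clique")
}

#' @rdname max_clique
#' @export
max_clique.igraph <- function(x, mode = c("exact", "heuristic"), ...) {
  mode <- match.arg(mode)
  n <- igraph::vcount(x)
  nm <- igraph::V(x)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  if (n == 0L)
    return(list(members = character(), size = 0L, mode = mode, exact = TRUE))
  if (mode == "exact") {
    cls <- igraph::largest_cliques(x)
    sets <- lapply(cls, function(v) sort(nm[as.integer(v)], method = "radix"))
    keys <- vapply(sets, paste, character(1), collapse = "\x01")
    members <- sets[[order(keys, method = "radix")[1L]]]
    exact <- TRUE
  } else {
    members <- .greedy_clique(x, nm)
    exact <- FALSE
  }
  .verify_clique(x, nm, members)
  list(members = members, size = length(members), mode = mode, exact = exact)
}

# greedy highest-degree-first clique plus 1-swap local search; deterministic
.greedy_clique <- function(g, nm) {
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, function(v) sort(as.integer(v)))
  deg <- lengths(adj)
  ord <- order(-deg, nm, method = "radix")
  clique <- integer(0)
  for (v in ord) {
    if (all(clique %in% adj[[v]])) clique <- c(clique, v)
  }
  # 1-swap: try removing one member and adding two non-members
  improved <- TRUE
  n <- length(adj)
  while (improved) {
    improved <- FALSE
    for (drop in clique) {
      base <- setdiff(clique, drop)
      cand <- which(vapply(seq_len(n), function(v)
        all(base %in% adj[[v]]) && !v %in% base, logical(1)))
      add <- integer(0)
      for (v in cand) {
        if (all(add %in% adj[[v]])) add <- c(add, v)
      }
      if (length(base) + length(add) > length(clique)) {
        clique <- c(base, add)
        improved <- TRUE
        break
      }
    }
  }
  sort(nm[clique], method = "radix")
}

# independent verification: every member pair must be an edge
.verify_clique <- function(g, nm, members) {
  idx <- match(members, nm)
  if (length(idx) >= 2L) {
    prs <- utils::combn(idx, 2L)
    for (c in seq_len(ncol(prs)))
      if (!igraph::are_adjacent(g, prs[1, c], prs[2, c]))
        stop("internal error: returned clique is not fully connected")
  }
  invisible(TRUE)
}

#' Enumerate all maximal cliques above a size floor
#'
#' Besides the single maximum clique, lists every maximal clique (a clique
#' not contained in a larger one) with at least `min_size` members, sorted
#' by decreasing size then lexicographically.
#'
#' @param graph A `module_overlap_graph` from [build_module_graph()].
#' @param min_size Smallest clique size to report (default 2).
#' @return data.frame with columns clique_id, size, tissue, module; one row
#'   per clique member.
#' @export
maximal_module_cliques <- function(graph, min_size = 2) {
  stopifnot(inherits(graph, "module_overlap_graph"))
  nodes <- paste(graph$nodes$tissue, graph$nodes$module, sep = "::")
  if (!length(nodes) || !nrow(graph$edges))
    return(data.frame(clique_id = integer(), size = integer(),
                      tissue = character(), module = character(),
                      stringsAsFactors = FALSE))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  ea <- paste(graph$edges$tissue_a, graph$edges$module_a, sep = "::")
  eb <- paste(graph$edges$tissue_b, graph$edges$module_b, sep = "::")
  g <- igraph::add_edges(g, rbind(ea, eb))
  cls <- igraph::max_cliques(g, min = min_size)
  sets <- lapply(cls, function(v)
    sort(nodes[as.integer(v)], method = "radix"))
  keys <- vapply(sets, paste, character(1), collapse = "\x01")
  ord <- order(-lengths(sets), keys, method = "radix")
  sets <- sets[ord]
  out <- do.call(rbind, lapply(seq_along(sets), function(i) {
    parts <- strsplit(sets[[i]], "::", fixed = TRUE)
    data.frame(clique_id = i, size = length(sets[[i]]),
               tissue = vapply(parts, `[`, character(1), 1L),
               module = vapply(parts, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.module_clique <- function(x, ...) {
  cat(sprintf("module_clique: size %d (%s%s)\n", x$size, x$mode,
              if (x$exact) "" else ", heuristic lower bound"))
  if (is.data.frame(x$members) && nrow(x$members))
    print(x$members, row.names = FALSE)
  invisible(x)
}

#' Attach gene sets to the members of a clique
#'
#' One row per clique member with its tissue, module label, module size and
#' member genes, ready for downstream enrichment.
#'
#' @param clique A `module_clique` from [max_clique()].
#' @param partitions List of `module_partition` objects covering the
#'   clique's tissues.
#' @return Object of class `clique_report`: list with `summary` (data.frame
#'   tissue / module / size) and `gene_sets` (named list, names
#'   `"tissue::module"`).
#' @export
clique_report <- function(clique, partitions) {
  stopifnot(inherits(clique, "module_clique"))
  tissues <- vapply(partitions, `[[`, character(1), "tissue")
  members <- clique$members
  gene_sets <- list()
  rows <- list()
  if (nrow(members)) {
    for (i in seq_len(nrow(members))) {
      ti <- members$tissue[i]
      mod <- members$module[i]
      pi <- match(ti, tissues)
      if (is.na(pi))
        stop("no partition supplied for tissue '", ti, "'")
      genes <- module_genes(partitions[[pi]], mod)
      key <- paste(ti, mod, sep = "::")
      gene_sets[[key]] <- sort(genes, method = "radix")
      rows[[i]] <- data.frame(tissue = ti, module = mod,
                              size = length(genes),
                              stringsAsFactors = FALSE)
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tissue = character(), module = character(), size = integer(),
               stringsAsFactors = FALSE)
  structure(list(summary = summary, gene_sets = gene_sets,
                 mode = clique$mode, exact = clique$exact),
            class = "clique_report")
}

#' @export
print.clique_report <- function(x, ...) {
  cat(sprintf("clique_report: %d members\n", nrow(x$summary)))
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a clique report as tab-separated text
#'
#' Columns: tissue, module, size, genes (comma-separated).
#'
#' @param report A `clique_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clique_report <- function(report, path) {
  stopifnot(inherits(report, "clique_report"))
  df <- report$summary
  df$genes <- vapply(seq_len(nrow(df)), function(i)
    paste(report$gene_sets[[paste(df$tissue[i], df$module[i], sep = "::")]],
          collapse = ","), character(1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
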