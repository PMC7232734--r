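#' Module label palette
#'
#' Fixed, documented color-name palette used to label detected modules in
#' decreasing size order; `"grey"` is reserved for unassigned genes and never
#' appears in the palette. Modules beyond the palette get labels
#' `"module_<k>"`.
#'
#' @return Character vector of module color names.
#' @export
module_colors <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta",
    "sienna3", "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3",
    "lightsteelblue1", "lightcyan1", "ivory", "floralwhite", "darkseagreen4",
    "thistle2", "salmon4", "palevioletred3", "navajowhite2", "maroon")
}

#' Average-linkage hierarchical clustering of a dissimilarity matrix
#'
#' UPGMA clustering of the topological-overlap dissimilarity `D = 1 - Omega`.
#'
#' @param D Square symmetric nonnegative matrix with zero diagonal; row
#'   names identify the genes.
#' @return An [stats::hclust] tree.
#' @export
hclust_average <- function(D) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D))
    stop("'D' must be a square numeric matrix")
  if (nrow(D) < 2L) stop("'D' must have at least 2 rows")
  if (anyNA(D)) stop("'D' contains missing values")
  if (min(D) < 0) stop("'D' must be nonnegative")
  if (max(abs(diag(D))) > 1e-8) stop("'D' must have a zero diagonal")
  if (max(abs(D - t(D))) > 1e-8) stop("'D' must be symmetric")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- sprintf("g%d", seq_len(nrow(D)))
  hc <- hclust(as.dist(D), method = "average")
  # UPGMA merge heights are monotone in exact arithmetic; averaging can leave
  # ~1e-16 inversions that cutree() rejects, so clamp them
  if (is.unsorted(hc$height)) {
    if (any(diff(hc$height) < -1e-8 * max(hc$height)))
      stop("internal error: non-monotone merge heights")
    hc$height <- cummax(hc$height)
  }
  hc
}

#' Cut a dendrogram at a fixed height
#'
#' The static cut: clusters are the connected components formed by merges at
#' height <= `height`; clusters smaller than `min_module_size` are relabeled
#' `"grey"`, survivors are sorted by decreasing size and named from
#' [module_colors()].
#'
#' @param hc An [stats::hclust] tree from [hclust_average()].
#' @param height Cut height (>= 0).
#' @param min_module_size Minimum genes per retained module.
#' @param tissue Tissue identifier for the resulting partition.
#' @return A `module_partition`.
#' @export
static_cut <- function(hc, height, min_module_size = 30, tissue = "tissue") {
  stopifnot(inherits(hc, "hclust"))
  if (height < 0) stop("'height' must be >= 0")
  cl <- cutree(hc, h = height)
  mods <- split(names(cl), cl)
  mods <- mods[lengths(mods) >= min_module_size]
  .make_partition(unname(mods), hc$labels, tissue, min_module_size,
                  method = "static")
}

#' Dynamic (tree-shape-based) branch cut
#'
#' Detects modules from the shape of the dendrogram rather than a single
#' fixed height, in two stages:
#'
#' 1. Merges above a ceiling `cut_frac * max(height)` are ignored, so loosely
#'    attached background genes (which only join near the top of the tree)
#'    fall out as unassigned rather than forming spurious clusters.
#' 2. Each remaining component is recursively split at internal merges whose
#'    height gap to the taller child exceeds a threshold controlled by
#'    `deep_split`: a gap of at least `g * cut_height` with
#'    `g = (0.25, 0.20, 0.15, 0.10, 0.05)[deep_split + 1]` marks the two
#'    branches as separate modules. Higher `deep_split` therefore splits more
#'    aggressively into smaller modules. Branches smaller than
#'    `min_module_size` are never modules; their genes become `"grey"`.
#'
#' A tree whose merge heights are all (numerically) equal carries no shape
#' information; by contract it yields a single module when the gene count
#' meets `min_module_size`.
#'
#' @param hc An [stats::hclust] tree from [hclust_average()].
#' @param min_module_size Minimum genes per module (default 30).
#' @param deep_split Split sensitivity, integer 0-4 (default 2).
#' @param cut_frac Merge-height ceiling as a fraction of the tree height
#'   (default 0.99).
#' @param tissue Tissue identifier for the resulting partition.
#' @return A `module_partition`.
#' @export
dynamic_cut <- function(hc, min_module_size = 30, deep_split = 2,
                        cut_frac = 0.99, tissue = "tissue") {
  stopifnot(inherits(hc, "hclust"))
  if (!deep_split %in% 0:4) stop("'deep_split' must be an integer in 0..4")
  if (cut_frac <= 0 || cut_frac > 1) stop("'cut_frac' must be in (0, 1]")
  n <- length(hc$labels)
  hmax <- max(hc$height)
  hmin <- min(hc$height)

  # degenerate tree: no shape information
  if (hmax <= 0 || (hmax - hmin) <= 1e-10 * hmax) {
    mods <- if (n >= min_module_size) list(hc$labels) else list()
    return(.make_partition(mods, hc$labels, tissue, min_module_size,
                           method = "dynamic"))
  }

  cut_height <- cut_frac * hmax
  gap_frac <- c(0.25, 0.20, 0.15, 0.10, 0.05)[deep_split + 1L]
  g <- gap_frac * cut_height

  # leaf sets of every internal node
  members <- vector("list", n - 1L)
  for (j in seq_len(n - 1L)) {
    ch <- hc$merge[j, ]
    members[[j]] <- c(if (ch[1] < 0) -ch[1] else members[[ch[1]]],
                      if (ch[2] < 0) -ch[2] else members[[ch[2]]])
  }
  node_h <- function(ch) if (ch < 0) 0 else hc$height[ch]

  split_rec <- function(j) {
    # returns a list of leaf-index vectors (modules) under node j; leaves not
    # covered by a returned module are left unassigned by the caller
    if (length(members[[j]]) < min_module_size) return(list())
    ch <- hc$merge[j, ]
    gap <- hc$height[j] - max(node_h(ch[1]), node_h(ch[2]))
    if (gap >= g) {
      res <- list()
      for (c in ch) {
        if (c < 0) next                       # singleton branch -> grey
        sub <- split_rec(c)
        res <- c(res, sub)
      }
      if (length(res)) return(res)
      # both branches below min_module_size: keep the node as one module
    }
    list(members[[j]])
  }

  cl <- cutree(hc, h = cut_height)
  mods <- list()
  for (cid in unique(cl)) {
    idx <- which(cl == cid)
    if (length(idx) < min_module_size) next
    if (length(idx) == n && hmax <= cut_height) {
      top <- n - 1L
    } else {
      # top merge node spanning exactly this component
      cand <- which(vapply(members, function(mm)
        length(mm) == length(idx) && all(cl[mm] == cid), logical(1)))
      if (!length(cand)) next                 # should not happen
      top <- cand[which.max(hc$height[cand])]
    }
    mods <- c(mods, lapply(split_rec(top), function(ix) hc$labels[ix]))
  }
  mods <- lapply(mods, function(m) if (is.character(m)) m else hc$labels[m])
  .make_partition(mods, hc$labels, tissue, min_module_size,
                  method = "dynamic")
}

# order modules by decreasing size (ties: smallest member gene id), assign
# palette labels, and build the partition object
.make_partition <- function(mods, all_genes, tissue, min_module_size,
                            method) {
  assignment <- rep("grey", length(all_genes))
  names(assignment) <- all_genes
  if (length(mods)) {
    first_gene <- vapply(mods, function(m) min(sort(m, method = "radix")),
                         character(1))
    ord <- order(-lengths(mods), first_gene, method = "radix")
    mods <- mods[ord]
    pal <- module_colors()
    labels <- c(pal, sprintf("module_%d", seq_len(max(0, length(mods) - length(pal)))))
    for (i in seq_along(mods)) assignment[mods[[i]]] <- labels[i]
  }
  structure(list(tissue = tissue, assignment = assignment,
                 min_module_size = min_module_size, method = method),
            class = "module_partition")
}

#' Sizes of the modules of a partition
#'
#' @param partition A `module_partition`.
#' @param include_grey Include the unassigned class? Default `FALSE`.
#' @return Named integer vector of module sizes, decreasing.
#' @export
module_sizes <- function(partition, include_grey = FALSE) {
  stopifnot(inherits(partition, "module_partition"))
  tab <- table(partition$assignment)
  if (!include_grey) tab <- tab[names(tab) != "grey"]
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  out <- as.integer(tab)[ord]
  names(out) <- names(tab)[ord]
  out
}

#' Member genes of one module
#'
#' @param partition A `module_partition`.
#' @param label Module label (may be `"grey"`).
#' @return Character vector of gene identifiers.
#' @export
module_genes <- function(partition, label) {
  stopifnot(inherits(partition, "module_partition"))
  names(partition$assignment)[partition$assignment == label]
}

#' @export
print.module_partition <- function(x, ...) {
  sz <- module_sizes(x)
  cat(sprintf("module_partition: tissue '%s', %d genes, %d modules (%s cut), %d grey\n",
              x$tissue, length(x$assignment), length(sz), x$method,
              sum(x$assignment == "grey")))
  if (length(sz)) print(sz)
  invisible(x)
}

#' Write module assignments as tab-separated text
#'
#' Columns: gene_id, tissue, module_label; rows in canonical gene order.
#'
#' @param partition A `module_partition`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "module_partition"))
  g <- sort(names(partition$assignment), method = "radix")
  df <- data.frame(gene_id = g, tissue = partition$tissue,
                   module_label = unname(partition$assignment[g]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect modules of a coexpression network
#'
#' Convenience wrapper: average-linkage clustering of the network's
#' dissimilarity followed by [dynamic_cut()].
#'
#' @param network A `coexpression_network` from [build_network()].
#' @param min_module_size,deep_split,cut_frac Passed to [dynamic_cut()].
#' @return A `module_partition`.
#' @export
detect_modules <- function(network, min_module_size = 30, deep_split = 2,
                           cut_frac = 0.99) {
  stopifnot(inherits(network, "coexpression_network"))
  D <- network$D
  rownames(D) <- colnames(D) <- network$gene_ids
  hc <- hclust_average(D)
  dynamic_cut(hc, min_module_size = min_module_size,
              deep_split = deep_split, cut_frac = cut_frac,
              tissue = network$tissue)
}
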