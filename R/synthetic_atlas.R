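#' Describe a planted coexpression module
#'
#' Member genes of a planted module load on a shared latent "eigengene" with
#' loading `loading` in each tissue where the module is active, giving an
#' expected within-module Pearson correlation of `loading^2`. A module active
#' in every tissue emulates the ubiquitous (immune-like) modules seen across
#' tissue panels; a module active in one tissue emulates a tissue-specific
#' module.
#'
#' @param module_id Unique identifier string.
#' @param size Number of member genes (>= 2).
#' @param loading Factor loading in (0, 1).
#' @param tissues Character vector of tissue identifiers in which the module
#'   is active (non-empty).
#' @return An object of class `planted_module`.
#' @export
planted_module <- function(module_id, size, loading, tissues) {
  if (length(module_id) != 1L || !nzchar(module_id))
    stop("invalid planted module: 'module_id' must be a single non-empty string")
  if (length(size) != 1L || size < 2 || size != round(size))
    stop("invalid planted module '", module_id, "': size must be an integer >= 2")
  if (length(loading) != 1L || !is.finite(loading) ||
      loading <= 0 || loading >= 1)
    stop("invalid planted module '", module_id,
         "': loading must lie strictly in (0, 1)")
  if (length(tissues) < 1L || anyDuplicated(tissues))
    stop("invalid planted module '", module_id,
         "': tissues must be a non-empty set")
  structure(list(module_id = module_id, size = as.integer(size),
                 loading = loading, tissues = as.character(tissues)),
            class = "planted_module")
}

#' Specify a synthetic multi-tissue expression atlas
#'
#' Defines the study conditions for the generator: a common gene universe
#' shared by all tissues, planted modules occupying disjoint gene blocks,
#' and i.i.d. Gaussian background for everything else.
#'
#' Tissue identifiers are `"T01"`, `"T02"`, ... and module member blocks are
#' assigned deterministically in module order starting at the first gene, so
#' the same spec always describes the same ground truth.
#'
#' @param n_tissues Number of tissues (>= 1).
#' @param n_genes Size of the common gene universe.
#' @param n_samples_per_tissue Samples per tissue (>= 3).
#' @param planted_modules List of [planted_module()] objects; their sizes must
#'   sum to at most `n_genes` (blocks are pairwise disjoint by construction).
#' @param noise_sd Standard deviation of background genes (>= 0).
#' @param seed Integer seed controlling all randomness of the generator.
#' @return An object of class `atlas_spec`.
#' @export
atlas_spec <- function(n_tissues, n_genes, n_samples_per_tissue,
                       planted_modules = list(), noise_sd = 1, seed = 1L) {
  if (n_tissues < 1L) stop("invalid atlas spec: n_tissues must be >= 1")
  if (n_samples_per_tissue < 3L)
    stop("invalid atlas spec: n_samples_per_tissue must be >= 3")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("invalid atlas spec: noise_sd must be nonnegative")
  if (!is.list(planted_modules) ||
      !all(vapply(planted_modules, inherits, logical(1), "planted_module")))
    stop("invalid atlas spec: planted_modules must be a list of planted_module objects")
  tissue_ids <- sprintf("T%02d", seq_len(n_tissues))
  ids <- vapply(planted_modules, `[[`, character(1), "module_id")
  if (anyDuplicated(ids))
    stop("invalid atlas spec: duplicate module_id among planted modules")
  for (pm in planted_modules) {
    bad <- setdiff(pm$tissues, tissue_ids)
    if (length(bad))
      stop("invalid atlas spec: module '", pm$module_id,
           "' names unknown tissue(s): ", paste(bad, collapse = ", "))
  }
  total <- sum(vapply(planted_modules, `[[`, integer(1), "size"))
  if (total > n_genes)
    stop("invalid atlas spec: planted module sizes sum to ", total,
         " which exceeds n_genes = ", n_genes)
  structure(list(n_tissues = as.integer(n_tissues),
                 n_genes = as.integer(n_genes),
                 n_samples_per_tissue = as.integer(n_samples_per_tissue),
                 planted_modules = planted_modules,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 tissue_ids = tissue_ids),
            class = "atlas_spec")
}

#' Demonstration atlas: one ubiquitous module plus tissue-specific modules
#'
#' Four tissues over 600 common genes and 100 samples each; a 50-gene module
#' with loading 0.9 active in every tissue (the ubiquitous, immune-like
#' module), one 30-gene module with loading 0.9 specific to each tissue, and
#' uncorrelated background genes. These are the package's reference study
#' conditions for end-to-end recovery: the ubiquitous module should be found
#' in each tissue and its four detected counterparts should form the largest
#' clique of the module overlap graph.
#'
#' @param seed Integer seed.
#' @param n_tissues,n_genes,n_samples_per_tissue Override the defaults.
#' @return An `atlas_spec`.
#' @export
demo_atlas_spec <- function(seed = 1L, n_tissues = 4L, n_genes = 600L,
                            n_samples_per_tissue = 100L) {
  tissues <- sprintf("T%02d", seq_len(n_tissues))
  mods <- c(
    list(planted_module("M_shared", 50L, 0.9, tissues)),
    lapply(tissues, function(t)
      planted_module(paste0("M_", t), 30L, 0.9, t))
  )
  atlas_spec(n_tissues, n_genes, n_samples_per_tissue,
             planted_modules = mods, noise_sd = 1, seed = seed)
}

#' Generate a synthetic multi-tissue atlas with planted modules
#'
#' For each tissue and each planted module active there, a latent standard
#' normal eigengene `e` is drawn over the tissue's samples and each member
#' gene's profile is `loading * e + sqrt(1 - loading^2) * eps` with `eps`
#' i.i.d. standard normal, so two member genes have expected Pearson
#' correlation `loading^2`. Eigengenes are drawn independently per tissue:
#' what is shared across tissues is the coexpression structure (the member
#' block), not the expression values. Background genes — and member genes of
#' modules inactive in a tissue — are i.i.d. normal with standard deviation
#' `noise_sd`. Output is deterministic given `spec$seed`.
#'
#' @param spec An [atlas_spec()].
#' @return A list of class `atlas` with elements:
#'   \describe{
#'     \item{tissues}{Named list of [expression_matrix()] objects.}
#'     \item{truth}{data.frame with columns `tissue`, `gene`, `module`
#'       covering every (tissue, gene) pair; `module` is the planted module id
#'       or `"background"`.}
#'     \item{spec}{The input spec.}
#'   }
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  ns <- spec$n_samples_per_tissue
  genes <- sprintf("G%06d", seq_len(ng))

  # disjoint member blocks, assigned in module order from the first gene
  members <- list()
  at <- 1L
  for (pm in spec$planted_modules) {
    members[[pm$module_id]] <- genes[at:(at + pm$size - 1L)]
    at <- at + pm$size
  }

  tissues <- vector("list", spec$n_tissues)
  names(tissues) <- spec$tissue_ids
  truth <- vector("list", spec$n_tissues)
  for (ti in seq_len(spec$n_tissues)) {
    tid <- spec$tissue_ids[ti]
    vals <- matrix(rnorm(ng * ns, sd = spec$noise_sd), nrow = ng, ncol = ns,
                   dimnames = list(genes,
                                   sprintf("%s_S%03d", tid, seq_len(ns))))
    assign_t <- rep("background", ng)
    names(assign_t) <- genes
    for (pm in spec$planted_modules) {
      if (!tid %in% pm$tissues) next
      mg <- members[[pm$module_id]]
      e <- rnorm(ns)
      eps <- matrix(rnorm(length(mg) * ns), nrow = length(mg))
      vals[mg, ] <- pm$loading * matrix(e, nrow = length(mg), ncol = ns,
                                        byrow = TRUE) +
        sqrt(1 - pm$loading^2) * eps
      assign_t[mg] <- pm$module_id
    }
    tissues[[tid]] <- expression_matrix(vals, tid)
    truth[[ti]] <- data.frame(tissue = tid, gene = genes,
                              module = unname(assign_t),
                              stringsAsFactors = FALSE)
  }
  structure(list(tissues = tissues,
                 truth = do.call(rbind, truth),
                 spec = spec),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("synthetic atlas: %d tissues, %d genes, %d samples/tissue, %d planted modules\n",
              x$spec$n_tissues, x$spec$n_genes, x$spec$n_samples_per_tissue,
              length(x$spec$planted_modules)))
  invisible(x)
}

#' Write an atlas to a directory as tab-separated text
#'
#' One expression file per tissue (`<tissue>.tsv`, see [write_expression()])
#' plus `truth.tsv` with columns tissue, gene, module.
#'
#' @param atlas An `atlas` from [generate_atlas()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in atlas$tissues)
    write_expression(m, file.path(dir, paste0(m$tissue, ".tsv")))
  write.table(atlas$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
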