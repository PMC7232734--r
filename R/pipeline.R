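#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Exactly one of
#' `input_dir` (a directory of per-tissue `.tsv` expression files) or
#' `atlas_spec` (an [atlas_spec()] to simulate) must be given.
#'
#' @param output_dir Directory where all artifacts are written.
#' @param input_dir Directory with per-tissue expression files (optional).
#' @param atlas_spec An [atlas_spec()] to simulate instead (optional).
#' @param power Soft power applied to every tissue (default 6).
#' @param strict_power If `TRUE`, pick each tissue's power by the strict
#'   scale-free criterion instead of the fixed common power.
#' @param min_module_size Minimum module size (default 30).
#' @param deep_split Dynamic-cut sensitivity, 0-4 (default 2).
#' @param alpha Edge significance threshold (default 0.05).
#' @param gmt_path Optional GMT file; enables the enrichment stage.
#' @param seed Integer seed for all randomness (default 1).
#' @param clique_mode `"exact"` or `"heuristic"`.
#' @param sweep_powers Candidate powers for the reported sweep (default
#'   1:20); `NULL` disables the sweep.
#' @param cut_frac Dynamic-cut merge-height ceiling fraction (default 0.99).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, input_dir = NULL, atlas_spec = NULL,
                            power = 6, strict_power = FALSE,
                            min_module_size = 30, deep_split = 2,
                            alpha = 0.05, gmt_path = NULL, seed = 1L,
                            clique_mode = c("exact", "heuristic"),
                            sweep_powers = 1:20, cut_frac = 0.99) {
  clique_mode <- match.arg(clique_mode)
  if (is.null(input_dir) && is.null(atlas_spec))
    stop("invalid config: one of 'input_dir' or 'atlas_spec' must be given")
  if (!is.null(input_dir) && !is.null(atlas_spec))
    stop("invalid config: give only one of 'input_dir' or 'atlas_spec'")
  if (!is.null(atlas_spec) && !inherits(atlas_spec, "atlas_spec"))
    stop("invalid config: 'atlas_spec' must be an atlas_spec object")
  if (power < 1) stop("invalid config: 'power' must be >= 1")
  if (alpha <= 0 || alpha >= 1)
    stop("invalid config: 'alpha' must be in (0, 1)")
  structure(list(output_dir = output_dir, input_dir = input_dir,
                 atlas_spec = atlas_spec, power = power,
                 strict_power = strict_power,
                 min_module_size = min_module_size, deep_split = deep_split,
                 alpha = alpha, gmt_path = gmt_path, seed = as.integer(seed),
                 clique_mode = clique_mode, sweep_powers = sweep_powers,
                 cut_frac = cut_frac),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]. An
#' `atlas_spec` block has keys `n_tissues`, `n_genes`,
#' `n_samples_per_tissue`, `noise_sd`, `seed`, and `modules` (a list of
#' `{module_id, size, loading, tissues}` entries; `tissues: all` expands to
#' every tissue).
#'
#' @param path Path to the YAML file.
#' @param overrides Named list of values overriding the file (e.g. from
#'   command-line flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  spec <- NULL
  if (!is.null(cfg$atlas_spec)) {
    a <- cfg$atlas_spec
    tissues_all <- sprintf("T%02d", seq_len(a$n_tissues))
    mods <- lapply(a$modules, function(m) {
      tt <- if (identical(m$tissues, "all")) tissues_all else
        as.character(unlist(m$tissues))
      planted_module(m$module_id, m$size, m$loading, tt)
    })
    spec <- atlas_spec(a$n_tissues, a$n_genes, a$n_samples_per_tissue,
                       planted_modules = mods,
                       noise_sd = if (is.null(a$noise_sd)) 1 else a$noise_sd,
                       seed = if (is.null(a$seed)) cfg$seed %||% 1L else a$seed)
  }
  args <- cfg[intersect(names(cfg),
                        c("output_dir", "input_dir", "power", "strict_power",
                          "min_module_size", "deep_split", "alpha",
                          "gmt_path", "seed", "clique_mode", "sweep_powers",
                          "cut_frac"))]
  args$atlas_spec <- spec
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the cross-tissue coexpression pipeline end to end
#'
#' Stages: load or simulate the per-tissue expression matrices; restrict to
#' the common gene universe and rank-normalize; per tissue, sweep soft
#' powers, build the network at the chosen power and detect modules by the
#' dynamic cut; test all inter-tissue module pairs for overlap and build the
#' module overlap graph; extract the maximum clique; optionally run
#' hypergeometric enrichment of the clique members against a GMT
#' collection. Every artifact is written under `config$output_dir` as
#' tab-separated text, and a JSON manifest records per-stage summaries. The
#' run is deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (a list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(
    package = "coexatlas",
    version = as.character(utils::packageVersion("coexatlas")),
    config = .echo_config(config),
    stages = list(), outputs = list(), status = "RUNNING")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$status <<- "FAILED"
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  set.seed(config$seed)

  # --- input -----------------------------------------------------------
  mats <- stage("input", {
    if (!is.null(config$atlas_spec)) {
      spec <- config$atlas_spec
      spec$seed <- config$seed
      atlas <- generate_atlas(spec)
      write_atlas(atlas, file.path(out, "atlas"))
      manifest$outputs$atlas <- file.path(out, "atlas")
      manifest$stages$input <- list(source = "simulated",
                                     n_tissues = length(atlas$tissues))
      atlas$tissues
    } else {
      files <- sort(list.files(config$input_dir, pattern = "\\.tsv$",
                               full.names = TRUE), method = "radix")
      if (!length(files)) stop("no .tsv expression files in ",
                               config$input_dir)
      manifest$stages$input <- list(source = config$input_dir,
                                     n_tissues = length(files))
      lapply(files, read_expression)
    }
  })

  # --- preprocess ------------------------------------------------------
  mats <- stage("preprocess", {
    mm <- intersect_genes(mats)
    mm <- lapply(mm, normalize_matrix)
    manifest$stages$preprocess <- list(
      n_common_genes = length(gene_ids(mm[[1]])),
      samples_per_tissue = vapply(mm, function(m) ncol(m$values),
                                  integer(1)))
    mm
  })
  universe <- gene_ids(mats[[1]])

  # --- networks + modules ---------------------------------------------
  partitions <- stage("network_modules", {
    parts <- vector("list", length(mats))
    sweeps <- list()
    powers_used <- numeric(length(mats))
    for (i in seq_along(mats)) {
      m <- mats[[i]]
      beta <- config$power
      if (!is.null(config$sweep_powers)) {
        sw <- power_sweep(m, powers = config$sweep_powers,
                          mode = if (config$strict_power) "strict" else "fixed",
                          fixed_power = config$power)
        sweeps[[m$tissue]] <- sw$table
        beta <- sw$chosen_power
        write.table(sw$table,
                    file.path(out, paste0("power_sweep_", m$tissue, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      } else if (config$strict_power) {
        sw <- power_sweep(m, mode = "strict", fixed_power = config$power)
        beta <- sw$chosen_power
      }
      powers_used[i] <- beta
      net <- build_network(m, beta = beta)
      parts[[i]] <- detect_modules(net,
                                   min_module_size = config$min_module_size,
                                   deep_split = config$deep_split,
                                   cut_frac = config$cut_frac)
      write_partition(parts[[i]],
                      file.path(out, paste0("modules_", m$tissue, ".tsv")))
    }
    manifest$stages$network_modules <- list(
      powers = powers_used,
      module_counts = vapply(parts, function(p)
        length(module_sizes(p)), integer(1)),
      grey_counts = vapply(parts, function(p)
        sum(p$assignment == "grey"), integer(1)))
    manifest$outputs$modules <- file.path(
      out, paste0("modules_", vapply(mats, `[[`, character(1), "tissue"),
                  ".tsv"))
    parts
  })

  # --- module overlap graph -------------------------------------------
  graph <- stage("compare", {
    g <- build_module_graph(partitions, universe = universe,
                            alpha = config$alpha)
    write_overlap(g, file.path(out, "overlap_results.tsv"), "results")
    write_overlap(g, file.path(out, "overlap_edges.tsv"), "edges")
    ts <- tissue_similarity(g)
    write.table(ts, file.path(out, "tissue_similarity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages$compare <- list(n_nodes = nrow(g$nodes),
                                     n_tested = nrow(g$results),
                                     n_edges = nrow(g$edges))
    manifest$outputs$overlap <- file.path(
      out, c("overlap_results.tsv", "overlap_edges.tsv",
             "tissue_similarity.tsv"))
    g
  })

  # --- maximum clique --------------------------------------------------
  report <- stage("clique", {
    cl <- max_clique(graph, mode = config$clique_mode)
    rep <- clique_report(cl, partitions)
    write_clique_report(rep, file.path(out, "clique_report.tsv"))
    manifest$stages$clique <- list(size = cl$size, mode = cl$mode,
                                    exact = cl$exact)
    manifest$outputs$clique <- file.path(out, "clique_report.tsv")
    rep
  })

  # --- enrichment (optional) ------------------------------------------
  if (!is.null(config$gmt_path)) {
    stage("enrichment", {
      coll <- read_gmt(config$gmt_path)
      enr <- enrich_clique(report, coll, universe, alpha = config$alpha)
      for (key in names(enr$members)) {
        fn <- file.path(out, paste0("enrichment_",
                                    gsub("::", "_", key, fixed = TRUE),
                                    ".tsv"))
        write.table(enr$members[[key]], fn, sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
      write.table(enr$shared, file.path(out, "enrichment_shared.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$enrichment <- list(
        n_terms = length(coll),
        n_members = length(enr$members),
        n_shared_terms = nrow(enr$shared))
      manifest$outputs$enrichment <- file.path(out, "enrichment_shared.tsv")
      invisible(NULL)
    })
  }

  manifest$status <- "OK"
  manifest$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# config echo for the manifest: plain values only
.echo_config <- function(config) {
  e <- unclass(config)
  if (!is.null(e$atlas_spec)) {
    s <- e$atlas_spec
    e$atlas_spec <- list(
      n_tissues = s$n_tissues, n_genes = s$n_genes,
      n_samples_per_tissue = s$n_samples_per_tissue,
      noise_sd = s$noise_sd, seed = s$seed,
      modules = lapply(s$planted_modules, function(pm)
        list(module_id = pm$module_id, size = pm$size,
             loading = pm$loading, tissues = pm$tissues)))
  }
  e
}
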