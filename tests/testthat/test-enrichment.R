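write_fixture_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("GMT parsing reads terms and rejects malformed lines", {
  path <- write_fixture_gmt(c(
    "TERM1\tfirst term\tg1\tg2\tg3",
    "TERM2\tsecond term\tg2\tg4"))
  coll <- read_gmt(path)
  expect_equal(length(coll), 2)
  expect_equal(coll$terms$TERM1, c("g1", "g2", "g3"))
  expect_equal(unname(coll$descriptions["TERM2"]), "second term")

  sizes <- c(3, 2, 5, 1, 4)
  big <- write_fixture_gmt(vapply(seq_along(sizes), function(i)
    paste(c(sprintf("T%d", i), "d",
            sprintf("t%d_g%d", i, seq_len(sizes[i]))), collapse = "\t"),
    character(1)))
  coll2 <- read_gmt(big)
  expect_equal(unname(lengths(coll2$terms)), sizes)

  expect_error(read_gmt(write_fixture_gmt(c("T1\tdesc\tg1", "T2\tdesc"))),
               "line 2")
  expect_error(read_gmt(write_fixture_gmt("T1\tdesc\t")), "no genes|line 1")
  expect_error(read_gmt(write_fixture_gmt(c("T1\td\tg1", "T1\td\tg2"))),
               "duplicate term")
  expect_error(read_gmt("/nonexistent/x.gmt"), "not found")
  # duplicate genes within a term are deduplicated
  dup <- read_gmt(write_fixture_gmt("T1\td\tg1\tg1\tg2"))
  expect_equal(dup$terms$T1, c("g1", "g2"))
})

test_that("GMT collections round-trip through write_gmt", {
  path <- write_fixture_gmt("TERM1\tdesc one\tg1\tg2")
  coll <- read_gmt(path)
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, out)
  expect_equal(read_gmt(out)$terms, coll$terms)
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  universe <- sprintf("g%02d", 1:50)
  coll <- structure(list(
    terms = list(TERM = universe[1:10]),
    descriptions = c(TERM = "a term"), source = "fixture"),
    class = "gene_set_collection")
  # query of 5 hitting 4 of the 10 term genes
  query <- c(universe[1:4], universe[20])
  res <- hypergeom_enrich(query, coll, universe)
  expect_equal(res$overlap, 4)
  oracle <- sum(choose(10, 4:5) * choose(40, 5 - (4:5))) / choose(50, 5)
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  expect_equal(res$fold_enrichment, (4 / 5) / (10 / 50), tolerance = 1e-12)
})

test_that("fold enrichment is 1 at the null expectation and in the degenerate universe", {
  universe <- sprintf("g%03d", 1:100)
  coll <- structure(list(
    terms = list(TERM = universe[1:20]),
    descriptions = c(TERM = "t"), source = "fixture"),
    class = "gene_set_collection")
  query <- c(universe[1:2], universe[50:57])   # 10 genes, overlap 2
  res <- hypergeom_enrich(query, coll, universe)
  expect_equal(res$fold_enrichment, 1, tolerance = 1e-12)

  # query = term = universe: overlap everything, fold 1, p 1
  u2 <- universe[1:20]
  res2 <- hypergeom_enrich(u2, coll, u2)
  expect_equal(res2$overlap, 20)
  expect_equal(res2$fold_enrichment, 1)
  expect_equal(res2$p_value, 1)

  expect_error(hypergeom_enrich(c("zz"), coll, universe), "outside")
})

test_that("p-values agree with the oracle across margins up to 50", {
  set.seed(8)
  universe <- sprintf("g%02d", 1:50)
  for (i in 1:20) {
    ts <- sample(1:30, 1)
    qs <- sample(1:30, 1)
    term_genes <- sample(universe, ts)
    query <- sample(universe, qs)
    coll <- structure(list(terms = list(X = term_genes),
                           descriptions = c(X = "x"), source = "f"),
                      class = "gene_set_collection")
    res <- hypergeom_enrich(query, coll, universe)
    k <- length(intersect(term_genes, query))
    if (k == 0) {
      expect_equal(nrow(res), 0)
    } else {
      expect_equal(res$p_value,
                   naive_hyper_upper(k, ts - k, qs - k, 50 - ts - qs + k),
                   tolerance = 1e-10)
    }
  }
})

test_that("correction columns respect their orderings", {
  set.seed(9)
  universe <- sprintf("g%03d", 1:200)
  terms <- lapply(1:12, function(i) sample(universe, sample(10:40, 1)))
  names(terms) <- sprintf("T%02d", 1:12)
  coll <- structure(list(terms = terms,
                         descriptions = setNames(sprintf("d%d", 1:12),
                                                 names(terms)),
                         source = "f"),
                    class = "gene_set_collection")
  query <- sample(universe, 30)
  res <- hypergeom_enrich(query, coll, universe)
  expect_true(all(diff(res$p_value) >= -1e-15))       # sorted ascending
  expect_true(all(res$bonferroni >= res$p_value - 1e-15))
  expect_true(all(res$bonferroni >= res$benjamini - 1e-15))
  expect_identical(res$fdr, res$benjamini)
  expect_true(all(res$benjamini >= res$p_value - 1e-15))
  expect_true(all(res$benjamini <= 1 & res$bonferroni <= 1))
  # BH is monotone in p-rank
  expect_true(all(diff(res$benjamini) >= -1e-15))
})

test_that("clique enrichment flags the planted term for every member", {
  atlas <- generate_atlas(demo_atlas_spec(seed = 5, n_genes = 300,
                                          n_samples_per_tissue = 80))
  mats <- lapply(intersect_genes(atlas$tissues), normalize_matrix)
  parts <- lapply(mats, function(m)
    detect_modules(build_network(m, 6), min_module_size = 20))
  g <- build_module_graph(parts)
  rep <- clique_report(max_clique(g), parts)
  universe <- gene_ids(mats[[1]])
  shared_genes <- atlas$truth$gene[atlas$truth$tissue == "T01" &
                                   atlas$truth$module == "M_shared"]
  set.seed(6)
  coll <- structure(list(
    terms = c(list(SHARED = shared_genes),
              lapply(setNames(1:5, sprintf("RAND%d", 1:5)), function(i)
                sample(universe, 40))),
    descriptions = setNames(c("planted shared module", sprintf("random %d", 1:5)),
                            c("SHARED", sprintf("RAND%d", 1:5))),
    source = "fixture"), class = "gene_set_collection")
  enr <- enrich_clique(rep, coll, universe)
  expect_equal(length(enr$members), 4)
  for (tab in enr$members) {
    expect_equal(tab$term_id[1], "SHARED")   # top hit by p for every member
    expect_lt(tab$benjamini[1], 0.05)
  }
  expect_true("SHARED" %in% enr$shared$term_id)

  # a member whose gene set hits no term yields an empty table
  fake_rep <- structure(list(
    summary = data.frame(tissue = "T09", module = "blue", size = 3),
    gene_sets = list("T09::blue" = universe[1:3]),
    mode = "exact", exact = TRUE), class = "clique_report")
  coll2 <- structure(list(terms = list(X = universe[200:220]),
                          descriptions = c(X = "x"), source = "f"),
                     class = "gene_set_collection")
  enr2 <- enrich_clique(fake_rep, coll2, universe)
  expect_equal(nrow(enr2$members[["T09::blue"]]), 0)
})
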