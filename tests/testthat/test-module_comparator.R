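# build a module_partition directly from a named assignment vector
mk_partition <- function(assignment, tissue, min_size = 2) {
  structure(list(tissue = tissue, assignment = assignment,
                 min_module_size = min_size, method = "fixture"),
            class = "module_partition")
}

test_that("overlap tables are plain set arithmetic over the universe", {
  u <- sprintf("g%d", 1:10)
  expect_equal(unname(overlap_table(u, u, u)), c(10, 0, 0, 0))
  expect_equal(unname(overlap_table(u[1:3], u[4:6], u)), c(0, 3, 3, 4))
  expect_equal(unname(overlap_table(c("g1", "g2", "g3"),
                                    c("g2", "g3", "g4"), u)),
               c(2, 1, 1, 6))
  expect_error(overlap_table(c("g1", "zz"), u[1:2], u), "outside")
})

test_that("fisher_p is the exact one-sided hypergeometric tail", {
  # zero overlap: P(X >= 0) = 1 whatever the margins
  expect_equal(fisher_p(c(0, 5, 7, 3)), 1)
  expect_equal(fisher_p(c(0, 0, 0, 12)), 1)
  # hand-derived: margins 4/4 in universe 8, overlap 3
  expect_equal(fisher_p(c(3, 1, 1, 3)), 17 / 70, tolerance = 1e-12)
  expect_error(fisher_p(c(-1, 1, 1, 1)), "nonnegative")
  expect_error(fisher_p(c(1.5, 1, 1, 1)), "integer")
})

test_that("fisher_p agrees with fisher.test and the naive sum on random tables", {
  set.seed(5)
  for (i in 1:25) {
    tab <- as.integer(rmultinom(1, sample(10:40, 1), rep(0.25, 4)))
    p <- fisher_p(tab)
    expect_equal(p, naive_hyper_upper(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(tab, 2), alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("fisher_p is monotone in the overlap at fixed margins", {
  n <- 100; sa <- 30; sb <- 40
  ps <- vapply(0:30, function(k)
    fisher_p(c(k, sa - k, sb - k, n - sa - sb + k)), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("the log-space path survives astronomically small p-values", {
  lp <- fisher_p(c(500, 0, 0, 500), log10 = TRUE)
  expect_true(is.finite(lp))
  expect_lt(lp, -250)
  # log and naive paths agree where the naive path does not underflow
  tab <- c(40, 10, 10, 140)
  expect_equal(fisher_p(tab, log10 = TRUE),
               log10(naive_hyper_upper(40, 10, 10, 140)), tolerance = 1e-9)
})

test_that("identical half-universe partitions give one overwhelming edge", {
  u <- sprintf("g%03d", 1:100)
  asn <- setNames(rep(c("turquoise", "grey"), each = 50), u)
  g <- build_module_graph(list(mk_partition(asn, "T01"),
                               mk_partition(asn, "T02")))
  expect_equal(nrow(g$results), 1)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$p, fisher_p(c(50, 0, 0, 50)), tolerance = 1e-12)
  expect_equal(g$edges$n11, 50)
})

test_that("a single tissue yields nodes but no inter-tissue edges", {
  u <- sprintf("g%03d", 1:60)
  asn <- setNames(rep(c("turquoise", "blue", "grey"), each = 20), u)
  g <- build_module_graph(list(mk_partition(asn, "T01")))
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$results), 0)
  expect_equal(nrow(g$edges), 0)
})

test_that("grey is never tested and every inter-tissue pair appears once", {
  u <- sprintf("g%03d", 1:90)
  a1 <- setNames(rep(c("turquoise", "blue", "grey"), each = 30), u)
  a2 <- setNames(rep(c("turquoise", "grey", "blue"), each = 30), u)
  a3 <- setNames(rep(c("grey", "turquoise", "blue"), each = 30), u)
  g <- build_module_graph(list(mk_partition(a1, "T01"),
                               mk_partition(a2, "T02"),
                               mk_partition(a3, "T03")))
  expect_equal(nrow(g$results), 3 * 4)   # 3 tissue pairs x 2x2 modules
  expect_false(any(g$results$module_a == "grey" |
                   g$results$module_b == "grey"))
  expect_false(any(g$results$tissue_a == g$results$tissue_b))
  key <- with(g$results, paste(tissue_a, module_a, tissue_b, module_b))
  expect_false(anyDuplicated(key) > 0)
  # tables always sum to the universe size
  expect_true(all(rowSums(g$results[, c("n11", "n10", "n01", "n00")]) == 90))
})

test_that("partitions over different universes are rejected", {
  a1 <- setNames(rep("turquoise", 10), sprintf("g%d", 1:10))
  a2 <- setNames(rep("turquoise", 10), sprintf("h%d", 1:10))
  expect_error(build_module_graph(list(mk_partition(a1, "T01"),
                                       mk_partition(a2, "T02"))),
               "universe")
})

test_that("tissue similarity ranks a pair sharing a planted module first", {
  # tissues T01 and T02 share a module that T03 lacks
  tissues <- sprintf("T%02d", 1:3)
  mods <- list(planted_module("M_shared", 40, 0.9, c("T01", "T02")),
               planted_module("M_a", 30, 0.9, "T01"),
               planted_module("M_b", 30, 0.9, "T02"),
               planted_module("M_c", 30, 0.9, "T03"))
  spec <- atlas_spec(3, 400, 80, planted_modules = mods, seed = 77)
  atlas <- generate_atlas(spec)
  mats <- lapply(intersect_genes(atlas$tissues), normalize_matrix)
  parts <- lapply(mats, function(m)
    detect_modules(build_network(m, 6), min_module_size = 20))
  g <- build_module_graph(parts)
  ts <- tissue_similarity(g)
  expect_equal(ts$tissue_a[1], "T01")
  expect_equal(ts$tissue_b[1], "T02")
  others <- ts$min_log10_p[!(ts$tissue_a == "T01" & ts$tissue_b == "T02")]
  expect_true(all(ts$min_log10_p[1] < others))
})

test_that("overlap tables write as tab-separated text", {
  u <- sprintf("g%03d", 1:100)
  asn <- setNames(rep(c("turquoise", "grey"), each = 50), u)
  g <- build_module_graph(list(mk_partition(asn, "T01"),
                               mk_partition(asn, "T02")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_overlap(g, path, "results")
  df <- read.delim(path)
  expect_equal(nrow(df), 1)
  expect_equal(df$n11, 50)
})
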