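toy_expr <- function() {
  vals <- matrix(c(1.0, 2.0, 4.0, 3.0,
                   2.0, 1.5, 3.5, 5.0,
                   9.0, 7.0, 2.0, 1.0),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("s1", "s2", "s3", "s4")))
  expression_matrix(vals, "T01")
}

test_that("similarity is absolute Pearson correlation", {
  m <- toy_expr()
  S <- similarity_matrix(m)
  # long-hand Pearson for each pair
  pearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  v <- m$values
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(S[i, j], abs(pearson(v[i, ], v[j, ])), tolerance = 1e-12)
  expect_equal(diag(S), c(g1 = 1, g2 = 1, g3 = 1))
  expect_equal(S, t(S))

  # duplicated row and negated row both give similarity 1
  v2 <- rbind(v, g4 = v[1, ], g5 = -v[1, ])
  S2 <- similarity_matrix(expression_matrix(v2, "T01"))
  expect_equal(S2["g1", "g4"], 1, tolerance = 1e-12)
  expect_equal(S2["g1", "g5"], 1, tolerance = 1e-12)
})

test_that("similarity rejects degenerate input", {
  v <- matrix(c(1, 1, 1, 2, 3, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  expect_error(similarity_matrix(expression_matrix(v, "t")), "gA")
  expect_error(similarity_matrix(expression_matrix(v[, 1:2, drop = FALSE], "t")),
               "3 samples")
})

test_that("power adjacency is an elementwise power with unit diagonal", {
  S <- rand_sym01(5, 1)
  expect_equal(adjacency(S, 1), {d <- S; diag(d) <- 1; d})
  A <- adjacency(S, 6)
  expect_equal(A[1, 2], S[1, 2]^6, tolerance = 1e-15)
  expect_equal(unname(diag(A)), rep(1, 5))
  S[1, 2] <- S[2, 1] <- 0.8
  expect_equal(adjacency(S, 6)[1, 2], 0.262144, tolerance = 1e-15)
  expect_error(adjacency(S, 0.5), "beta")
})

test_that("TOM matches hand evaluation on a 3-node network", {
  mk3 <- function(a12, a13, a23) {
    A <- diag(3)
    A[1, 2] <- A[2, 1] <- a12
    A[1, 3] <- A[3, 1] <- a13
    A[2, 3] <- A[3, 2] <- a23
    A
  }
  # complete graph saturates TOM; empty graph zeroes it
  expect_equal(tom(mk3(1, 1, 1)), matrix(1, 3, 3))
  expect_equal(tom(mk3(0, 0, 0)), diag(3))
  # hand evaluation: w12 = (0.4*0.2 + 0.5)/(min(0.9, 0.7) + 1 - 0.5)
  Om <- tom(mk3(0.5, 0.4, 0.2))
  expect_equal(Om[1, 2], 0.58 / 1.2, tolerance = 1e-12)
  expect_equal(Om[1, 3], (0.5 * 0.2 + 0.4) / (min(0.9, 0.6) + 1 - 0.4),
               tolerance = 1e-12)
  expect_equal(Om[2, 3], (0.5 * 0.4 + 0.2) / (min(0.7, 0.6) + 1 - 0.2),
               tolerance = 1e-12)
})

test_that("TOM equals the naive triple-loop oracle and stays in [0, 1]", {
  for (seed in 1:5) {
    A <- rand_sym01(30, seed)
    Om <- tom(A)
    expect_lt(max(abs(Om - naive_tom(A))), 1e-12)
    expect_true(all(Om >= 0 & Om <= 1))
    expect_equal(Om, t(Om))
    expect_equal(unname(diag(Om)), rep(1, 30))
  }
  expect_error(tom(matrix(runif(9), 3)), "symmetric|\\[0, 1\\]")
})

test_that("an exact power-law degree histogram yields |signed R^2| ~ 1", {
  # connectivities at integers 1..6 with frequencies proportional to k^-2;
  # 10 equal-width bins over [1, 6] isolate each integer in its own bin
  k <- rep(1:6, times = 3600 / (1:6)^2)
  sf <- coexatlas:::sf_fit_from_connectivity(k, n_bins = 10)
  expect_equal(sf$flag, "ok")
  expect_lt(sf$signed_r2, 0)              # decreasing p(k)
  expect_gt(abs(sf$signed_r2), 0.99)
  expect_equal(sf$mean_connectivity, mean(k))
})

test_that("a regular network is flagged degenerate, not an error", {
  A <- matrix(0.4, 6, 6)
  diag(A) <- 1
  sf <- scale_free_fit(A)
  expect_equal(sf$flag, "degenerate")
  expect_true(is.na(sf$signed_r2))
  expect_equal(sf$mean_connectivity, 5 * 0.4)
})

test_that("mean connectivity is nonincreasing in the soft power", {
  S <- rand_sym01(40, 9)
  ks <- vapply(1:20, function(b) mean(connectivity(adjacency(S, b))),
               numeric(1))
  expect_true(all(diff(ks) <= 1e-12))
})

test_that("power sweep reports diagnostics and fixed mode always chooses 6", {
  a <- one_tissue_fixture(seed = 21, sizes = c(50, 40, 30), n_bg = 200)
  m <- normalize_matrix(a$tissues$T01)
  sw <- power_sweep(m, powers = c(1, 2, 4, 6, 9, 12))
  expect_equal(nrow(sw$table), 6)
  expect_equal(sw$chosen_power, 6)
  expect_true(all(diff(sw$table$mean_connectivity) <= 1e-12))
  # soft-thresholding suppresses background noise: fit improves from 1 to 6
  r2 <- sw$table$signed_r2
  expect_gt(abs(r2[sw$table$power == 6]), abs(r2[sw$table$power == 1]))

  sw1 <- power_sweep(m, powers = 6)
  expect_equal(nrow(sw1$table), 1)
  expect_equal(sw1$chosen_power, 6)
})

test_that("strict mode picks the smallest power meeting the R^2 criterion", {
  a <- one_tissue_fixture(seed = 22, sizes = c(50, 40, 30), n_bg = 200)
  m <- normalize_matrix(a$tissues$T01)
  sw <- power_sweep(m, powers = 1:12, mode = "strict", r2_threshold = 0.8)
  tab <- sw$table
  qualifying <- tab$power[!is.na(tab$signed_r2) & abs(tab$signed_r2) >= 0.8]
  if (length(qualifying)) {
    expect_true(sw$criterion_met)
    expect_equal(sw$chosen_power, min(qualifying))
  } else {
    expect_false(sw$criterion_met)
  }
})

test_that("build_network assembles consistent S, A, Omega, D", {
  a <- one_tissue_fixture(seed = 23, sizes = c(20), n_bg = 30,
                          n_samples = 40)
  net <- build_network(normalize_matrix(a$tissues$T01), beta = 6)
  expect_equal(net$A, adjacency(net$S, 6), tolerance = 1e-15)
  expect_equal(net$D, 1 - net$Omega, tolerance = 1e-15)
  expect_equal(unname(diag(net$D)), rep(0, 50))
  expect_equal(net$gene_ids, rownames(net$S))
})
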