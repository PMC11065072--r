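test_that("overlap p equals the hypergeometric tail by direct summation", {
  uni <- sprintf("g%02d", 1:20)
  mend <- c("g01", "g02", "g03")
  canc <- c("g01", "g02", "g04", "g05")
  p <- gene_overlap_test(mend, canc, uni)
  expect_equal(p, hyper_enum_p(2, 3, 4, 20), tolerance = 1e-12)
  # random fixtures
  set.seed(17)
  for (i in 1:20) {
    N <- sample(15:40, 1)
    u <- sprintf("x%03d", seq_len(N))
    a <- sample(u, sample(2:6, 1))
    b <- sample(u, sample(2:8, 1))
    k <- length(intersect(a, b))
    expect_equal(gene_overlap_test(a, b, u),
                 hyper_enum_p(k, length(a), length(b), N),
                 tolerance = 1e-12)
    # symmetry in the two sets
    expect_equal(gene_overlap_test(a, b, u), gene_overlap_test(b, a, u),
                 tolerance = 1e-12)
  }
})

test_that("overlap p boundary cases and universe validation", {
  uni <- sprintf("g%02d", 1:20)
  expect_equal(gene_overlap_test(c("g01", "g02"), c("g03", "g04"), uni), 1)
  expect_equal(gene_overlap_test(uni, c("g01", "g02"), uni), 1)
  expect_error(gene_overlap_test(c("g01", "zz"), c("g02"), uni), "zz")
})

test_that("co-expression p is exact for small backgrounds", {
  # two Mendelian genes holding the two largest correlations among 12
  # comparison genes: minimum achievable p = 1 / choose(12, 2) = 1/66
  set.seed(5)
  tis <- 10
  base <- matrix(rnorm(10 * tis), 10, tis,
                 dimnames = list(sprintf("bg%02d", 1:10), NULL))
  x <- rnorm(tis)
  expr <- rbind(base, CG = x,
                MA = x + rnorm(tis, sd = 1e-4),
                MB = x + rnorm(tis, sd = 1e-4))
  colnames(expr) <- sprintf("t%02d", seq_len(tis))
  p <- coexpression_test("CG", c("MA", "MB"), expr)
  expect_equal(p, 1 / 66, tolerance = 1e-12)
})

test_that("co-expression p is invariant to monotone value transforms", {
  set.seed(6)
  expr <- exp(matrix(rnorm(15 * 8), 15, 8,
                     dimnames = list(sprintf("g%02d", 1:15), NULL)))
  p1 <- coexpression_test("g01", c("g02", "g03"), expr)
  p2 <- coexpression_test("g01", c("g02", "g03"), expr^3)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("degenerate co-expression inputs are handled", {
  set.seed(7)
  expr <- exp(matrix(rnorm(6 * 8), 6, 8,
                     dimnames = list(sprintf("g%d", 1:6), NULL)))
  expect_error(coexpression_test("zz", "g1", expr), "not in expression")
  expect_error(coexpression_test("g1", "zz", expr), "no Mendelian gene")
  expect_error(coexpression_test("g1", sprintf("g%d", 2:6), expr),
               "every background gene")
  # constant gene dropped from the background with a message
  expr2 <- rbind(expr, gflat = rep(2, 8))
  expect_message(coexpression_test("g1", "g2", expr2), "constant-expression")
})

test_that("the either-metric rule drives the similarity call", {
  set.seed(8)
  n <- 60; tis <- 12
  genes <- sprintf("g%03d", 1:n)
  expr <- exp(matrix(rnorm(n * tis), n, tis, dimnames = list(genes, NULL)))
  # overlap-driven: identical sets, uncorrelated expression
  s1 <- similarity_call(genes[1:6], c(genes[1:6], genes[40:45]), expr)
  expect_lt(s1$overlap_p, 0.05)
  expect_true(s1$similar)
  # coexpression-driven: disjoint sets, planted correlation
  x <- rnorm(tis)
  expr2 <- expr
  expr2["g010", ] <- exp(x)
  for (g in genes[2:6]) expr2[g, ] <- exp(x + rnorm(tis, sd = 0.1))
  s2 <- similarity_call(genes[2:6], c("g010", genes[50:54]), expr2)
  expect_gt(s2$overlap_p, 0.05)
  expect_lt(s2$coexpr_min_adj_p, 0.05)
  expect_true(s2$similar)
  # neither metric: disjoint, uncorrelated
  s3 <- similarity_call(genes[1:5], genes[30:36], expr)
  expect_false(s3$similar)
  expect_error(similarity_call(genes[1:5], character(), expr), "empty cancer")
})

test_that("missing expression data degrades the call to overlap only", {
  set.seed(9)
  genes <- sprintf("g%03d", 1:30)
  expr <- exp(matrix(rnorm(30 * 8), 30, 8, dimnames = list(genes, NULL)))
  s <- similarity_call(c("absent1", "absent2"), genes[1:5], expr,
                       universe = c(genes, "absent1", "absent2"))
  expect_true(is.na(s$coexpr_min_adj_p))
  expect_identical(s$n_coexpr_tested, 0L)
  expect_identical(s$similar, s$overlap_p < 0.05)
})

test_that("BH adjustment dominates the raw minimum within a call", {
  set.seed(10)
  ex <- generate_expression(mini_cfg(seed = 10, module_correlation = 0.5))
  raw <- vapply(intersect(ex$cancer_sets[[1]], rownames(ex$expr)),
                function(g) coexpression_test(g, ex$mendelian_set, ex$expr),
                numeric(1))
  adj <- stats::p.adjust(raw, "BH")
  expect_true(all(adj >= raw - 1e-12))
  expect_true(all(diff(adj[order(raw)]) >= -1e-12))  # order-preserving
  sc <- similarity_call(ex$mendelian_set, ex$cancer_sets[[1]], ex$expr)
  expect_equal(sc$coexpr_min_adj_p, min(adj), tolerance = 1e-12)
})

test_that("similarity_table covers every Mendelian-cancer pair", {
  cfg <- mini_cfg(seed = 12)
  w <- generate_world(cfg)
  ex <- generate_expression(cfg)
  # restrict Mendelian gene map to genes with expression to keep it fast
  tab <- similarity_table(w$bundle, ex$cancer_sets[1:2], ex$expr)
  expect_identical(nrow(tab), nrow(w$bundle$mendelian) * 2L)
  expect_true(all(tab$overlap_p >= 0 & tab$overlap_p <= 1))
  expect_identical(tab$similar,
                   tab$overlap_p < 0.05 |
                     (!is.na(tab$coexpr_min_adj_p) &
                        tab$coexpr_min_adj_p < 0.05))
})
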