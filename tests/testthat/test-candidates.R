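test_that("candidate generation matches the brute-force join oracle", {
  b <- tiny_bundle()
  cs <- candidate_sets(b)
  expect_equal(as.data.frame(cs), brute_candidates(b), ignore_attr = TRUE)

  # and on a batch of random synthetic worlds
  for (s in 1:5) {
    w <- generate_world(mini_cfg(seed = 100 + s))
    got <- as.data.frame(candidate_sets(w$bundle))
    want <- brute_candidates(w$bundle)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("per-disease candidates carry valid provenance", {
  b <- tiny_bundle()
  c1 <- candidate_drugs("C1", b)
  expect_setequal(c1$drugs, c("D1", "D2"))
  # every provenance gene belongs to both the cited Mendelian disease and
  # the drug's target set
  for (i in seq_len(nrow(c1$provenance))) {
    r <- c1$provenance[i, ]
    expect_true(r$gene %in% b$mendelian_genes$gene[
      b$mendelian_genes$mendelian_id == r$mendelian_id])
    expect_true(r$gene %in% b$drug_targets$gene[
      b$drug_targets$drug_id == r$drug_id])
  }
  expect_identical(candidate_drugs("C3", b)$drugs, character(0))
  expect_error(candidate_drugs("C9", b), "unknown complex disease")
})

test_that("pair table is the full cross product with per-drug constants", {
  b <- tiny_bundle()
  pt <- build_pair_table(b)
  expect_identical(nrow(pt), 3L * 3L)  # D4 targets no Mendelian gene
  expect_false("D4" %in% pt$drug_id)
  nt <- tapply(pt$n_targets, pt$drug_id, function(v) length(unique(v)))
  expect_true(all(nt == 1))
  expect_identical(unname(pt$n_targets[pt$drug_id == "D1"][1]), 2L)
  # candidate flag agrees with candidate_sets
  cs <- candidate_sets(b)
  ck <- unique(paste(cs$drug_id, cs$complex_id))
  expect_identical(pt$is_candidate,
                   as.integer(paste(pt$drug_id, pt$complex_id) %in% ck))
})

test_that("outcome definitions select the intended pairs", {
  b <- tiny_bundle()
  key <- function(pt) paste(pt$drug_id, pt$complex_id)[pt$outcome == 1]
  pt <- build_pair_table(b, "investigated_or_indicated")
  expect_setequal(key(pt), c("D1 C1", "D2 C2", "D2 C1", "D3 C1"))
  pt <- build_pair_table(b, "investigated_or_indicated",
                         include_unknown = FALSE)
  expect_setequal(key(pt), c("D1 C1", "D2 C2", "D3 C1"))
  pt <- build_pair_table(b, "investigated_only")
  expect_setequal(key(pt), c("D1 C1", "D2 C1"))
  pt <- build_pair_table(b, "indicated_only")
  expect_setequal(key(pt), c("D2 C2", "D3 C1"))
  pt <- build_pair_table(b, "phase_k", phase = "PHASE_II")
  expect_setequal(key(pt), "D1 C1")
  pt <- build_pair_table(b, "phase_k", phase = "INDICATED")
  expect_setequal(key(pt), c("D2 C2", "D3 C1"))
  expect_error(build_pair_table(b, "phase_k"), "phase")
})

test_that("empty evidence gives an all-zero outcome cross product", {
  b <- suppressMessages(comorbid_bundle(
    mendelian = data.frame(id = "M1", name = "m"),
    mendelian_genes = data.frame(mendelian_id = "M1", gene = "GA"),
    complex = data.frame(id = c("C1", "C2", "C3"), name = c("a", "b", "c"),
                         category = rep("immune", 3)),
    comorbidity = data.frame(mendelian_id = "M1", complex_id = "C1"),
    drug_targets = data.frame(drug_id = c("D1", "D2"), gene = "GA")))
  pt <- build_pair_table(b)
  expect_identical(nrow(pt), 6L)
  expect_true(all(pt$outcome == 0))
})

test_that("candidate sets grow with targets and shrink with comorbidities", {
  w <- generate_world(mini_cfg(seed = 42))
  b <- w$bundle
  n_cand <- function(bb) nrow(unique(as.data.frame(
    candidate_sets(bb))[, c("drug_id", "complex_id")]))
  base <- n_cand(b)
  # adding a gene to a drug's target set can only grow candidate sets
  b_add <- b
  g <- b$mendelian_genes$gene[1]
  d <- setdiff(unique(b$drug_targets$drug_id),
               b$drug_targets$drug_id[b$drug_targets$gene == g])[1]
  b_add$drug_targets <- rbind(b_add$drug_targets,
                              data.frame(drug_id = d, gene = g))
  expect_gte(n_cand(b_add), base)
  # removing a comorbidity pair can only shrink them
  b_rm <- b
  b_rm$comorbidity <- b_rm$comorbidity[-1, , drop = FALSE]
  expect_lte(n_cand(b_rm), base)
})

test_that("pair table construction is pure and ignores evidence for the flag", {
  b <- tiny_bundle()
  expect_identical(build_pair_table(b), build_pair_table(b))
  b_noev <- b
  b_noev$evidence <- b$evidence[0, ]
  b_noev$indicated <- b$indicated[0, ]
  expect_identical(build_pair_table(b)$is_candidate,
                   build_pair_table(b_noev)$is_candidate)
})

test_that("empty drug universe raises the dedicated error", {
  b <- suppressWarnings(suppressMessages(comorbid_bundle(
    mendelian = data.frame(id = "M1", name = "m"),
    mendelian_genes = data.frame(mendelian_id = "M1", gene = "GA"),
    complex = data.frame(id = "C1", name = "c", category = "immune"),
    comorbidity = data.frame(mendelian_id = "M1", complex_id = "C1"),
    drug_targets = data.frame(drug_id = "D1", gene = "GZ"))))
  expect_error(build_pair_table(b), "no druggable Mendelian genes")
})
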