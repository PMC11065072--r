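# Hand-built miniature bundle: 3 Mendelian diseases, 3 complex diseases,
# 4 drugs (one of which targets no Mendelian gene and so sits outside the
# evaluation universe).
tiny_bundle <- function() {
  suppressMessages(comorbid_bundle(
    mendelian = data.frame(id = c("M1", "M2", "M3"),
                           name = c("alpha", "beta", "gamma")),
    mendelian_genes = data.frame(
      mendelian_id = c("M1", "M1", "M2", "M3"),
      gene = c("GA", "GB", "GC", "GD")),
    complex = data.frame(id = c("C1", "C2", "C3"),
                         name = c("one", "two", "three"),
                         category = c("immune", "neoplasms", "neurological")),
    comorbidity = data.frame(mendelian_id = c("M1", "M2", "M2"),
                             complex_id = c("C1", "C1", "C2")),
    drug_targets = data.frame(
      drug_id = c("D1", "D1", "D2", "D3", "D4"),
      gene = c("GA", "GX", "GC", "GD", "GZ")),
    evidence = data.frame(drug_id = c("D1", "D2", "D2"),
                          complex_id = c("C1", "C2", "C1"),
                          phase = c("Phase 2", "Phase 4", "")),
    indicated = data.frame(drug_id = "D3", complex_id = "C1")))
}

# miniature synthetic scale used across tests: small enough for fast
# permutation loops, non-degenerate candidate rate
mini_cfg <- function(seed, beta_candidate = log(2), ...) {
  args <- list(n_mendelian = 10L, n_complex = 12L, n_genes = 80L,
               n_drugs = 30L, n_cancers = 3L, n_tissues = 12L,
               genes_per_mendelian = 3, targets_per_drug_prob = 0.5,
               comorbidity_density = 0.18,
               beta_candidate = beta_candidate, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(synthetic_config, args)
}

# --- independent enumeration oracles -----------------------------------

# exact one-sided (greater) rank-sum p by exhaustive enumeration of all
# ways the x-group ranks can fall among the combined sample; mid-ranks for
# ties so the statistic matches the mid-rank convention
ranksum_enum_p <- function(x, y) {
  all_v <- c(x, y)
  r <- rank(all_v)
  n <- length(all_v)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)])
  sets <- utils::combn(n, m)
  w_all <- apply(sets, 2, function(ix) sum(r[ix]))
  mean(w_all >= w_obs)
}

# hypergeometric upper tail by direct summation of choose() terms
hyper_enum_p <- function(k, size_a, size_b, n_universe) {
  ks <- k:min(size_a, size_b)
  sum(choose(size_a, ks) * choose(n_universe - size_a, size_b - ks)) /
    choose(n_universe, size_b)
}

# brute-force candidate sets: triple loop over (mendelian, gene, drug)
brute_candidates <- function(bundle) {
  out <- NULL
  for (i in seq_len(nrow(bundle$comorbidity))) {
    m <- bundle$comorbidity$mendelian_id[i]
    cx <- bundle$comorbidity$complex_id[i]
    genes <- bundle$mendelian_genes$gene[
      bundle$mendelian_genes$mendelian_id == m]
    for (g in genes) {
      drugs <- bundle$drug_targets$drug_id[bundle$drug_targets$gene == g]
      for (d in drugs) {
        out <- rbind(out, data.frame(drug_id = d, complex_id = cx,
                                     mendelian_id = m, gene = g))
      }
    }
  }
  if (is.null(out)) return(out)
  out <- unique(out)
  out <- out[order(out$drug_id, out$complex_id, out$mendelian_id, out$gene), ]
  rownames(out) <- NULL
  out
}

# closed-form 2x2 cross-product odds ratio fixture as a pair table
counts_to_pairs <- function(a, b, c, d) {
  data.frame(
    is_candidate = rep(c(1, 1, 0, 0), c(a, b, c, d)),
    outcome = rep(c(1, 0, 1, 0), c(a, b, c, d)))
}
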