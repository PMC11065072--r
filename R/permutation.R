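#' @title Degree-preserving permutation nulls
#' @description
#' Two rewiring schemes build the null model for the enrichment analyses.
#' The comorbidity scheme redraws which complex diseases each Mendelian
#' disease is comorbid with, holding every intrinsic characteristic of the
#' Mendelian disease fixed (causal genes, number of comorbidities). The
#' drug-target scheme redraws which drugs target each gene, holding the
#' number of drugs per gene fixed. Both sample uniformly without replacement
#' from the respective universe, so the permuted relation preserves the
#' Mendelian-side (resp. gene-side) degree sequence exactly.
#' @name permutation-nulls
NULL

# Deterministic, order-independent per-replicate seeds from one master seed.
.replicate_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Permute the comorbidity relation
#'
#' For each Mendelian disease with `k` comorbid complex diseases, draws a
#' uniform random `k`-subset of the complex disease universe. Per-Mendelian
#' comorbidity counts are preserved exactly; a disease comorbid with the
#' whole universe is returned unchanged.
#'
#' @param comorbidity data.frame `mendelian_id`, `complex_id`.
#' @param complex_ids character vector: the complex disease universe.
#' @return data.frame with the same columns and per-Mendelian row counts.
#' @export
permute_comorbidity <- function(comorbidity, complex_ids) {
  ks <- table(comorbidity$mendelian_id)
  if (any(ks > length(complex_ids)))
    stop("a Mendelian disease has more comorbidities than the complex universe",
         call. = FALSE)
  m_ids <- names(ks)
  new_c <- lapply(as.integer(ks), function(k)
    complex_ids[sample.int(length(complex_ids), k)])
  data.frame(mendelian_id = rep(m_ids, as.integer(ks)),
             complex_id = unlist(new_c, use.names = FALSE))
}

#' Permute the drug-target relation gene-wise
#'
#' For each gene (optionally restricted to `genes`), the set of drugs
#' targeting it is replaced by a uniform random subset of the drug universe
#' of the same size, preserving the per-gene drug count exactly. Links of
#' genes outside `genes` are kept as observed.
#'
#' @param drug_targets data.frame `drug_id`, `gene`.
#' @param drug_ids character vector: the drug universe to sample from.
#' @param genes genes to rewire (default: all genes in the map).
#' @return data.frame `drug_id`, `gene` with per-gene counts preserved.
#' @export
permute_drug_targets <- function(drug_targets, drug_ids,
                                 genes = unique(drug_targets$gene)) {
  keep <- drug_targets[!drug_targets$gene %in% genes, , drop = FALSE]
  rew <- drug_targets[drug_targets$gene %in% genes, , drop = FALSE]
  if (!nrow(rew)) return(drug_targets)
  ds <- table(rew$gene)
  if (any(ds > length(drug_ids)))
    stop("a gene is targeted by more drugs than the drug universe",
         call. = FALSE)
  new_d <- lapply(as.integer(ds), function(d)
    drug_ids[sample.int(length(drug_ids), d)])
  out <- rbind(keep,
               data.frame(drug_id = unlist(new_d, use.names = FALSE),
                          gene = rep(names(ds), as.integer(ds))))
  rownames(out) <- NULL
  out
}

#' Empirical permutation p-value for an odds ratio
#'
#' Runs `analysis` once per replicate (each with its own deterministic seed
#' derived from `seed`, so replicates are order-independent) and counts how
#' often the permuted odds ratio is at least the observed one:
#' `p = #\{OR_perm >= OR_obs\} / n_valid`. Ties count as exceedances and no
#' +1 correction is applied, so `p = 0` is possible and is printed as
#' `< 1/n_perm`. Replicates whose fit fails (separation, empty class) return
#' `NA` and are excluded from the denominator with their count recorded.
#'
#' @param observed_or the observed odds ratio.
#' @param analysis `function(replicate_seed)` returning a permuted odds
#'   ratio (or `NA` on failure).
#' @param n_perm number of permutations (default 1000).
#' @param seed master seed.
#' @return object of class `permutation_result`: `observed_or`,
#'   `permuted_ors`, `p_perm`, `n_perm`, `n_failed`, `significant`
#'   (`p_perm < 0.05`), `seed`.
#' @export
permutation_pvalue <- function(observed_or, analysis, n_perm = 1000L,
                               seed = 1L) {
  stopifnot(n_perm >= 1)
  seeds <- .replicate_seeds(seed, n_perm)
  ors <- vapply(seeds, function(s) as.numeric(analysis(s)), numeric(1))
  failed <- !is.finite(ors)
  n_valid <- sum(!failed)
  if (any(failed))
    message(sprintf("%d of %d permutation replicate(s) failed and were excluded",
                    sum(failed), n_perm))
  if (!n_valid) stop("all permutation replicates failed", call. = FALSE)
  p <- sum(ors[!failed] >= observed_or) / n_valid
  structure(list(observed_or = observed_or, permuted_ors = ors,
                 p_perm = p, n_perm = n_perm, n_failed = sum(failed),
                 significant = p < 0.05, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  pstr <- if (x$p_perm == 0) sprintf("< %.3g", 1 / (x$n_perm - x$n_failed))
          else sprintf("= %.3g", x$p_perm)
  cat(sprintf("permutation test: observed OR %.4g, p_perm %s (%d permutations%s)\n",
              x$observed_or, pstr, x$n_perm,
              if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}

#' Permutation test of the global enrichment
#'
#' Recomputes the full candidate-generation + enrichment analysis under one
#' of the two rewiring schemes. Under both schemes the pair-table rows, the
#' outcome flags and the `n_targets` covariate are held at their observed
#' values (they are intrinsic to the drugs and the clinical record); only
#' the candidate flag is recomputed from the rewired relation.
#'
#' @param bundle a `comorbid_bundle`.
#' @param scheme `"comorbidity"` (rewire Mendelian-complex comorbidity) or
#'   `"drug_target"` (rewire gene-drug targeting, Mendelian causal genes
#'   only).
#' @param outcome_def,phase,include_unknown passed to [build_pair_table()].
#' @param adjust,weights passed to [fit_enrichment()].
#' @param n_perm,seed permutation controls.
#' @return a `permutation_result`, with the observed `enrichment_result`
#'   attached as `$observed_fit`.
#' @export
permutation_test <- function(bundle, scheme = c("comorbidity", "drug_target"),
                             outcome_def = "investigated_or_indicated",
                             phase = NULL, include_unknown = TRUE,
                             adjust = c("category", "n_targets"),
                             weights = "none", n_perm = 1000L, seed = 1L) {
  scheme <- match.arg(scheme)
  pt <- build_pair_table(bundle, outcome_def = outcome_def, phase = phase,
                         include_unknown = include_unknown)
  obs <- fit_enrichment(pt, adjust = adjust, weights = weights)

  # fixed parts of the refit
  y <- as.numeric(pt$outcome)
  des <- .enrich_design(pt, "is_candidate", adjust)
  x <- des$x
  ci <- match("is_candidate", colnames(x))
  complex_ids <- bundle$complex$id
  drugs <- unique(pt$drug_id)
  key <- paste(pt$drug_id, pt$complex_id, sep = "\r")
  w <- NULL
  if (weights == "balanced") {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    w <- ifelse(y == 1, length(y) / (2 * n1), length(y) / (2 * n0))
  }
  mendelian_genes <- bundle$mendelian_genes
  drug_universe_all <- sort(unique(bundle$drug_targets$drug_id))

  refit_or <- function(cand_prov) {
    ck <- unique(paste(cand_prov$drug_id, cand_prov$complex_id, sep = "\r"))
    flag <- as.numeric(key %in% ck)
    if (length(unique(flag)) < 2) return(NA_real_)
    x[, ci] <- flag
    ft <- tryCatch(.logit_fit(y, x, w), error = function(e) NULL)
    if (is.null(ft) || ft$separated || is.na(ft$estimate["is_candidate"]))
      return(NA_real_)
    exp(unname(ft$estimate["is_candidate"]))
  }

  analysis <- function(s) {
    set.seed(s)
    if (scheme == "comorbidity") {
      com <- permute_comorbidity(bundle$comorbidity, complex_ids)
      prov <- merge(com, mendelian_genes, by = "mendelian_id")
      prov <- merge(prov, bundle$drug_targets, by = "gene")
    } else {
      dt <- permute_drug_targets(bundle$drug_targets, drug_universe_all,
                                 genes = unique(mendelian_genes$gene))
      prov <- merge(bundle$comorbidity, mendelian_genes, by = "mendelian_id")
      prov <- merge(prov, dt, by = "gene")
    }
    refit_or(prov)
  }
  res <- permutation_pvalue(obs$odds_ratio, analysis, n_perm = n_perm,
                            seed = seed)
  res$observed_fit <- obs
  res$scheme <- scheme
  res
}
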