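#' @title Prioritizing druggable Mendelian diseases and genes
#' @description
#' Each Mendelian disease (or each Mendelian causal gene) is tested
#' individually: are the drugs targeting that unit enriched among drugs
#' currently investigated or indicated for its comorbid complex diseases?
#' Each unit's test is gated by a drug-target rewiring permutation, and the
#' significant units' drug counts are compared with the rest by a one-sided
#' rank-sum test.
#' @name druggability
NULL

# unit -> (genes, comorbid complex diseases, drugs targeting the unit)
.unit_info <- function(unit_id, level, bundle) {
  if (level == "disease") {
    genes <- bundle$mendelian_genes$gene[
      bundle$mendelian_genes$mendelian_id == unit_id]
    comorbid <- bundle$comorbidity$complex_id[
      bundle$comorbidity$mendelian_id == unit_id]
  } else {
    genes <- unit_id
    carriers <- bundle$mendelian_genes$mendelian_id[
      bundle$mendelian_genes$gene == unit_id]
    comorbid <- bundle$comorbidity$complex_id[
      bundle$comorbidity$mendelian_id %in% carriers]
  }
  drugs <- unique(bundle$drug_targets$drug_id[
    bundle$drug_targets$gene %in% genes])
  list(genes = unique(genes), comorbid = unique(comorbid), drugs = drugs)
}

#' Per-unit enrichment with drug-target permutation gate
#'
#' Restricts the candidate flag to one unit — a Mendelian disease or a single
#' causal gene — over the full drug-by-disease pair table: a pair is a
#' candidate iff the drug targets one of the unit's causal genes and the
#' complex disease is comorbid with the unit (for a gene, comorbid with any
#' Mendelian disease carrying that gene). The enrichment fit keeps the
#' `n_targets` and `category` covariates of the global model. The
#' permutation null rewires which drugs target each of the unit's genes,
#' preserving per-gene drug counts.
#'
#' @param unit_id Mendelian disease id (`level = "disease"`) or gene symbol
#'   (`level = "gene"`).
#' @param bundle a `comorbid_bundle`.
#' @param level `"disease"` or `"gene"`.
#' @param pairs optional precomputed pair table (its `is_candidate` column
#'   is ignored); pass it when looping over units.
#' @param outcome_def passed to [build_pair_table()] if `pairs` is missing.
#' @param adjust covariates for the fit.
#' @param n_perm,seed permutation controls.
#' @return list of class `unit_result`: `unit_id`, `level`, `n_drugs`,
#'   `enrichment` (an `enrichment_result`), `perm` (a
#'   `permutation_result`), `significant` (`p_perm < 0.05`).
#' @export
per_unit_enrichment <- function(unit_id, bundle, level = c("disease", "gene"),
                                pairs = NULL,
                                outcome_def = "investigated_or_indicated",
                                adjust = c("category", "n_targets"),
                                n_perm = 1000L, seed = 1L) {
  level <- match.arg(level)
  info <- .unit_info(unit_id, level, bundle)
  if (!length(info$drugs))
    stop(sprintf("unit '%s' is targeted by no drug", unit_id), call. = FALSE)
  if (!length(info$comorbid)) {
    warning(sprintf("unit '%s' has no comorbid complex disease; skipped",
                    unit_id), call. = FALSE)
    return(NULL)
  }
  if (is.null(pairs))
    pairs <- build_pair_table(bundle, outcome_def = outcome_def)
  y <- as.numeric(pairs$outcome)
  flag_for <- function(drugs) {
    as.numeric(pairs$drug_id %in% drugs &
                 pairs$complex_id %in% info$comorbid)
  }
  p2 <- pairs
  p2$is_candidate <- flag_for(info$drugs)
  if (length(unique(p2$is_candidate)) < 2)
    stop(sprintf("unit '%s': candidate flag has a single level", unit_id),
         call. = FALSE)
  obs <- fit_enrichment(p2, adjust = adjust)

  des <- .enrich_design(p2, "is_candidate", adjust)
  x <- des$x
  ci <- match("is_candidate", colnames(x))
  universe <- sort(unique(bundle$drug_targets$drug_id))
  unit_links <- bundle$drug_targets[bundle$drug_targets$gene %in% info$genes, ]
  analysis <- function(s) {
    set.seed(s)
    dt <- permute_drug_targets(unit_links, universe, genes = info$genes)
    flag <- flag_for(unique(dt$drug_id))
    if (length(unique(flag)) < 2) return(NA_real_)
    x[, ci] <- flag
    ft <- tryCatch(.logit_fit(y, x), error = function(e) NULL)
    if (is.null(ft) || ft$separated || is.na(ft$estimate["is_candidate"]))
      return(NA_real_)
    exp(unname(ft$estimate["is_candidate"]))
  }
  perm <- permutation_pvalue(obs$odds_ratio, analysis, n_perm = n_perm,
                             seed = seed)
  structure(list(unit_id = unit_id, level = level,
                 n_drugs = length(info$drugs), enrichment = obs,
                 perm = perm, significant = perm$p_perm < 0.05),
            class = "unit_result")
}

#' Prioritize all drug-targeted units
#'
#' Runs [per_unit_enrichment()] for every Mendelian disease (or gene)
#' targeted by at least one drug, and returns a tidy summary table.
#'
#' @param bundle a `comorbid_bundle`.
#' @param level `"disease"` or `"gene"`.
#' @param outcome_def,adjust,n_perm,seed as in [per_unit_enrichment()].
#' @return data.frame with one row per testable unit: `unit_id`, `n_drugs`,
#'   `odds_ratio`, `p_value`, `p_perm`, `significant`.
#' @export
prioritize_units <- function(bundle, level = c("disease", "gene"),
                             outcome_def = "investigated_or_indicated",
                             adjust = c("category", "n_targets"),
                             n_perm = 1000L, seed = 1L) {
  level <- match.arg(level)
  units <- if (level == "disease") bundle$mendelian$id else
    unique(bundle$mendelian_genes$gene)
  targeted <- vapply(units, function(u)
    length(.unit_info(u, level, bundle)$drugs) > 0, logical(1))
  units <- units[targeted]
  pairs <- build_pair_table(bundle, outcome_def = outcome_def)
  rows <- lapply(seq_along(units), function(i) {
    u <- units[i]
    r <- tryCatch(suppressMessages(
      per_unit_enrichment(u, bundle, level = level, pairs = pairs,
                          outcome_def = outcome_def, adjust = adjust,
                          n_perm = n_perm, seed = seed + i)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(r)) return(NULL)
    data.frame(unit_id = u, n_drugs = r$n_drugs,
               odds_ratio = r$enrichment$odds_ratio,
               p_value = r$enrichment$p_value,
               p_perm = r$perm$p_perm, significant = r$significant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# One-sided (greater) rank-sum p. Exhaustive enumeration of the mid-rank
# statistic over all group assignments for small samples (ties allowed);
# normal approximation with tie-corrected variance beyond that.
.ranksum_greater <- function(x, y, exact_max_n = 12L) {
  n <- length(x) + length(y)
  m <- length(x)
  if (n <= exact_max_n) {
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(m)])
    sets <- utils::combn(n, m)
    w_all <- colSums(matrix(r[sets], nrow = m))
    mean(w_all >= w_obs - 1e-9)
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                         correct = FALSE)$p.value)
  }
}

#' One-sided rank-sum comparison of drug counts
#'
#' Tests whether significant units are targeted by more drugs than the
#' remaining units (Wilcoxon rank-sum, alternative "greater"). For 12 or
#' fewer total observations the p-value is exact, by exhaustive enumeration
#' of the mid-rank statistic over all group assignments (so ties are handled
#' exactly as well); larger samples use the normal approximation with
#' tie-corrected variance.
#'
#' @param significant_counts drug counts of the significant units.
#' @param other_counts drug counts of the remaining units.
#' @return one-sided p-value.
#' @export
compare_drug_counts <- function(significant_counts, other_counts) {
  if (!length(significant_counts) || !length(other_counts))
    stop("both groups must be non-empty", call. = FALSE)
  .ranksum_greater(significant_counts, other_counts)
}

#' Permutation gate for the druggability comparison
#'
#' Asks whether "significant units are targeted by more drugs" could be a
#' power artifact of drug counts alone: per replicate, all Mendelian-gene
#' drug-target links are rewired at once (per-gene counts preserved), every
#' unit's enrichment is refit on the rewired world, the significant set is
#' recomputed, and the one-sided rank-sum p comparing drug counts is
#' recorded. The empirical gate p is the fraction of replicates whose
#' rank-sum p is at least as small as observed.
#'
#' Within replicates (and for the observed statistic of this gate) unit
#' significance is the analytic Wald p < 0.05 of the unit fit — nesting a
#' full inner permutation inside each outer replicate is quadratic in
#' `n_perm` and the gate only needs a consistent selection rule on both
#' sides of the comparison.
#'
#' @param bundle a `comorbid_bundle`.
#' @param level `"disease"` or `"gene"`.
#' @param outcome_def,adjust model options as in [per_unit_enrichment()].
#' @param n_perm,seed permutation controls.
#' @return list of class `druggability_gate`: `observed_p` (rank-sum p on
#'   the observed world), `permuted_ps`, `p_perm`, `n_failed`.
#' @export
druggability_permutation_gate <- function(bundle, level = c("disease", "gene"),
                                          outcome_def = "investigated_or_indicated",
                                          adjust = c("category", "n_targets"),
                                          n_perm = 200L, seed = 1L) {
  level <- match.arg(level)
  units <- if (level == "disease") bundle$mendelian$id else
    unique(bundle$mendelian_genes$gene)
  infos <- lapply(units, .unit_info, level = level, bundle = bundle)
  names(infos) <- units
  usable <- vapply(infos, function(z)
    length(z$drugs) > 0 && length(z$comorbid) > 0, logical(1))
  units <- units[usable]; infos <- infos[usable]
  if (length(units) < 3)
    stop("too few testable units for the druggability gate", call. = FALSE)

  pairs <- build_pair_table(bundle, outcome_def = outcome_def)
  y <- as.numeric(pairs$outcome)
  des <- .enrich_design(pairs, "is_candidate", adjust)
  x <- des$x
  ci <- match("is_candidate", colnames(x))
  universe <- sort(unique(bundle$drug_targets$drug_id))
  mend_genes <- unique(bundle$mendelian_genes$gene)

  # analytic unit p under a given drug-target relation
  unit_stats <- function(drug_targets) {
    by_gene <- split(drug_targets$drug_id, drug_targets$gene)
    res <- vapply(units, function(u) {
      gs <- infos[[u]]$genes
      drugs <- unique(unlist(by_gene[gs], use.names = FALSE))
      if (!length(drugs)) return(c(NA_real_, 0))
      flag <- as.numeric(pairs$drug_id %in% drugs &
                           pairs$complex_id %in% infos[[u]]$comorbid)
      if (length(unique(flag)) < 2) return(c(NA_real_, length(drugs)))
      x[, ci] <- flag
      ft <- tryCatch(.logit_fit(y, x), error = function(e) NULL)
      est <- if (is.null(ft)) NA_real_ else unname(ft$estimate["is_candidate"])
      se <- if (is.null(ft)) NA_real_ else ft$stderr[ci]
      p <- if (is.na(est) || is.na(se) || ft$separated) NA_real_ else
        2 * stats::pnorm(-abs(est / se))
      # one-sided gate: enrichment means positive coefficient
      p1 <- if (is.na(p)) NA_real_ else if (est > 0) p / 2 else 1 - p / 2
      c(p1, length(drugs))
    }, numeric(2))
    list(p = res[1, ], n_drugs = res[2, ])
  }
  # replicates without a usable significant/non-significant split carry the
  # least extreme statistic (p = 1): an empty significant set is no evidence
  # that significant units have higher drug counts
  ranksum_p <- function(st, unusable = 1) {
    sig <- !is.na(st$p) & st$p < 0.05
    if (!any(sig) || all(sig[!is.na(st$p)])) return(unusable)
    compare_drug_counts(st$n_drugs[sig], st$n_drugs[!sig & !is.na(st$p)])
  }

  obs_stats <- unit_stats(bundle$drug_targets)
  observed_p <- ranksum_p(obs_stats, unusable = NA_real_)
  if (is.na(observed_p))
    stop("observed world has no usable significant/non-significant split",
         call. = FALSE)
  seeds <- .replicate_seeds(seed, n_perm)
  perm_ps <- vapply(seeds, function(s) {
    set.seed(s)
    dt <- permute_drug_targets(bundle$drug_targets, universe,
                               genes = mend_genes)
    ranksum_p(unit_stats(dt))
  }, numeric(1))
  failed <- is.na(perm_ps)
  n_valid <- sum(!failed)
  if (!n_valid) stop("all gate replicates failed", call. = FALSE)
  p_perm <- sum(perm_ps[!failed] <= observed_p) / n_valid
  structure(list(observed_p = observed_p, permuted_ps = perm_ps,
                 p_perm = p_perm, n_perm = n_perm, n_failed = sum(failed),
                 significant = p_perm < 0.05, seed = seed),
            class = "druggability_gate")
}
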