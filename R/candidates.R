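#' Drugs targeting at least one Mendelian causal gene
#'
#' This is the drug universe of the evaluation: every drug whose target set
#' intersects the union of Mendelian causal genes. Optionally restricted to
#' the causal genes of a subset of Mendelian diseases.
#'
#' @param bundle a `comorbid_bundle`.
#' @param mendelian_ids optional subset of Mendelian disease ids.
#' @return sorted character vector of drug ids.
#' @export
drug_universe <- function(bundle, mendelian_ids = NULL) {
  genes <- if (is.null(mendelian_ids)) bundle$mendelian_genes$gene else
    bundle$mendelian_genes$gene[bundle$mendelian_genes$mendelian_id %in%
                                  mendelian_ids]
  dt <- bundle$drug_targets
  sort(unique(dt$drug_id[dt$gene %in% genes]))
}

#' Candidate drugs with provenance for every complex disease
#'
#' A drug is a candidate for a complex disease when the disease is comorbid
#' with some Mendelian disease whose causal gene the drug targets. The result
#' records every supporting (Mendelian disease, gene) pair, so each candidate
#' link carries at least one provenance triple by construction.
#'
#' @param bundle a `comorbid_bundle`.
#' @return data.frame with class `candidate_set` and columns `drug_id`,
#'   `complex_id`, `mendelian_id`, `gene` (long format; one row per
#'   provenance triple).
#' @export
candidate_sets <- function(bundle) {
  prov <- merge(bundle$comorbidity, bundle$mendelian_genes,
                by = "mendelian_id")
  prov <- merge(prov, bundle$drug_targets, by = "gene")
  prov <- unique(prov[, c("drug_id", "complex_id", "mendelian_id", "gene")])
  prov <- prov[order(prov$drug_id, prov$complex_id, prov$mendelian_id,
                     prov$gene), ]
  rownames(prov) <- NULL
  class(prov) <- c("candidate_set", "data.frame")
  prov
}

#' Candidate drugs for one complex disease
#'
#' @param complex_id a registered complex disease id.
#' @param bundle a `comorbid_bundle`.
#' @return list with `drugs` (character vector, possibly empty) and
#'   `provenance` (data.frame `drug_id`, `mendelian_id`, `gene`).
#' @export
candidate_drugs <- function(complex_id, bundle) {
  if (!complex_id %in% bundle$complex$id)
    stop("unknown complex disease id: ", complex_id, call. = FALSE)
  cs <- candidate_sets(bundle)
  prov <- cs[cs$complex_id == complex_id,
             c("drug_id", "mendelian_id", "gene"), drop = FALSE]
  rownames(prov) <- NULL
  list(drugs = sort(unique(prov$drug_id)), provenance = prov)
}

# internal fast path: per-Mendelian drug sets from a gene->drugs relation
.drugs_by_mendelian <- function(mendelian_genes, drug_targets, mendelian_ids) {
  by_gene <- split(drug_targets$drug_id, drug_targets$gene)
  genes_by_m <- split(mendelian_genes$gene, mendelian_genes$mendelian_id)
  out <- lapply(mendelian_ids, function(m) {
    g <- genes_by_m[[m]]
    if (is.null(g)) character() else unique(unlist(by_gene[g], use.names = FALSE))
  })
  names(out) <- mendelian_ids
  out
}

#' Build the drug-by-disease pair table
#'
#' Emits the full cross product of the drug universe and the complex disease
#' registry: one row per (drug, complex disease) pair with the candidate
#' flag, the outcome flag, the disease category, the drug's total number of
#' known gene targets, and the pair's most advanced clinical phase (`NA` when
#' no evidence exists).
#'
#' Outcome definitions:
#' \describe{
#'   \item{`investigated_or_indicated`}{any clinical trial at any phase
#'     (including unknown phase, unless `include_unknown = FALSE`) or an
#'     indication.}
#'   \item{`investigated_only`}{trial evidence whose most advanced phase is
#'     Phase I-III (or unknown, unless excluded) and no indication.}
#'   \item{`indicated_only`}{an indication (incl. Phase IV trials).}
#'   \item{`phase_k`}{most advanced evidence is exactly `phase`.}
#' }
#'
#' @param bundle a `comorbid_bundle`.
#' @param outcome_def one of the four definitions above.
#' @param phase required when `outcome_def = "phase_k"`: one of
#'   [PHASE_LEVELS].
#' @param include_unknown count unknown-phase trials as investigation
#'   (default TRUE; trials with no phase information are still trials).
#' @param candidates optional precomputed [candidate_sets()] result.
#' @return data.frame of class `pair_table` with columns `drug_id`,
#'   `complex_id`, `is_candidate`, `outcome`, `category`, `n_targets`,
#'   `phase`.
#' @export
build_pair_table <- function(bundle,
                             outcome_def = c("investigated_or_indicated",
                                             "investigated_only",
                                             "indicated_only", "phase_k"),
                             phase = NULL, include_unknown = TRUE,
                             candidates = NULL) {
  outcome_def <- match.arg(outcome_def)
  drugs <- drug_universe(bundle)
  if (!length(drugs))
    stop("no druggable Mendelian genes: drug universe is empty",
         call. = FALSE)
  complex_ids <- bundle$complex$id
  pairs <- expand.grid(drug_id = drugs, complex_id = complex_ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  if (is.null(candidates)) candidates <- candidate_sets(bundle)
  key <- function(d, c) paste(d, c, sep = "\r")
  cand_keys <- unique(key(candidates$drug_id, candidates$complex_id))
  pairs$is_candidate <- as.integer(key(pairs$drug_id, pairs$complex_id)
                                   %in% cand_keys)

  nt <- n_targets_per_drug(bundle)
  pairs$n_targets <- as.integer(nt[pairs$drug_id])
  cat_map <- stats::setNames(bundle$complex$category, bundle$complex$id)
  pairs$category <- unname(cat_map[pairs$complex_id])

  ev <- bundle$evidence
  phase_map <- stats::setNames(ev$phase, key(ev$drug_id, ev$complex_id))
  pairs$phase <- unname(phase_map[key(pairs$drug_id, pairs$complex_id)])
  ind_keys <- key(bundle$indicated$drug_id, bundle$indicated$complex_id)
  is_ind <- key(pairs$drug_id, pairs$complex_id) %in% ind_keys
  has_trial <- !is.na(pairs$phase) &
    (include_unknown | pairs$phase != "UNKNOWN")
  trial_not_p4 <- has_trial & pairs$phase != "INDICATED"

  pairs$outcome <- as.integer(switch(outcome_def,
    investigated_or_indicated = has_trial | is_ind,
    investigated_only = trial_not_p4 & !is_ind,
    indicated_only = is_ind,
    phase_k = {
      if (is.null(phase) || !phase %in% PHASE_LEVELS)
        stop("outcome_def 'phase_k' needs `phase` in PHASE_LEVELS",
             call. = FALSE)
      if (phase == "INDICATED") is_ind else !is.na(pairs$phase) &
        pairs$phase == phase & !is_ind
    }))
  pairs <- pairs[, c("drug_id", "complex_id", "is_candidate", "outcome",
                     "category", "n_targets", "phase")]
  class(pairs) <- c("pair_table", "data.frame")
  pairs
}
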