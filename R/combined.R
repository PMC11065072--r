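#' @title Combining comorbidity with genetic similarity
#' @description
#' For cancers with driver-gene lists, every (drug, cancer) pair is labeled
#' by its support: comorbidity support means some Mendelian disease whose
#' causal gene the drug targets is comorbid with the cancer; similarity
#' support means such a provenance disease is genetically similar to the
#' cancer. Enrichment of clinical outcomes on similarity support is then fit
#' within the comorbid and non-comorbid subsets.
#' @name combined-evidence
NULL

#' Stratify drug-cancer pairs by comorbidity and similarity support
#'
#' The drug universe is every drug targeting a causal gene of the Mendelian
#' diseases under study. In `mode = "strict"` (default) a pair counts as
#' supported by both only when a single provenance Mendelian disease is
#' simultaneously comorbid with and similar to the cancer — the rationale
#' being shared etiology of one disease pair; `mode = "any"` lets two
#' different provenance diseases contribute the two support types.
#'
#' @param bundle a `comorbid_bundle`.
#' @param cancer_ids complex disease ids treated as cancers (must have
#'   similarity calls).
#' @param similarity data.frame `mendelian_id`, `cancer_id`, `similar`
#'   (see [similarity_table()]); pairs missing from the table count as not
#'   similar.
#' @param mode `"strict"` or `"any"` (see above).
#' @return data.frame of class `support_strata`: `drug_id`, `cancer_id`,
#'   `comorbid` (0/1), `similar` (0/1), `both` (0/1, per `mode`), `label`
#'   in `{comorbid_and_similar, comorbid_only, similar_only, neither}`.
#' @export
stratify_drug_cancer_pairs <- function(bundle, cancer_ids, similarity,
                                       mode = c("strict", "any")) {
  mode <- match.arg(mode)
  stopifnot(all(cancer_ids %in% bundle$complex$id))
  drugs <- drug_universe(bundle)
  # provenance: which Mendelian diseases back each drug
  prov <- merge(bundle$drug_targets, bundle$mendelian_genes, by = "gene")
  prov <- unique(prov[, c("drug_id", "mendelian_id")])
  prov_by_drug <- split(prov$mendelian_id, prov$drug_id)

  com_key <- paste(bundle$comorbidity$mendelian_id,
                   bundle$comorbidity$complex_id, sep = "\r")
  sim <- similarity[similarity$similar %in% c(TRUE, 1), , drop = FALSE]
  sim_key <- paste(sim$mendelian_id, sim$cancer_id, sep = "\r")

  grid <- expand.grid(drug_id = drugs, cancer_id = cancer_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  comorbid <- integer(n); similar <- integer(n); both <- integer(n)
  for (i in seq_len(n)) {
    ms <- prov_by_drug[[grid$drug_id[i]]]
    if (is.null(ms)) next
    k <- paste(ms, grid$cancer_id[i], sep = "\r")
    is_com <- k %in% com_key
    is_sim <- k %in% sim_key
    comorbid[i] <- as.integer(any(is_com))
    similar[i] <- as.integer(any(is_sim))
    both[i] <- as.integer(if (mode == "strict") any(is_com & is_sim)
                          else any(is_com) && any(is_sim))
  }
  grid$comorbid <- comorbid
  grid$similar <- similar
  grid$both <- both
  grid$label <- ifelse(both == 1L, "comorbid_and_similar",
                ifelse(comorbid == 1L, "comorbid_only",
                ifelse(similar == 1L, "similar_only", "neither")))
  class(grid) <- c("support_strata", "data.frame")
  grid
}

#' Enrichment of outcomes on a support flag within a subset
#'
#' Fits the enrichment model for `contrast` (e.g. similarity support) on the
#' drug-cancer pairs selected by `conditioning`, adjusted for `n_targets`
#' (the disease category is constant — neoplasms — and is dropped).
#'
#' @param pairs a `pair_table` built on the same bundle (its cancer rows are
#'   used; `is_candidate` is ignored).
#' @param strata a `support_strata` table.
#' @param contrast which support flag to test: `"similar"`, `"comorbid"` or
#'   `"both"`.
#' @param conditioning `"all"`, `"comorbid"` (only comorbidity-supported
#'   pairs) or `"noncomorbid"`.
#' @param adjust covariates (default `n_targets`).
#' @return an `enrichment_result` for the contrast flag.
#' @export
fit_per_stratum <- function(pairs, strata, contrast = c("similar", "comorbid",
                                                        "both"),
                            conditioning = c("all", "comorbid", "noncomorbid"),
                            adjust = "n_targets") {
  contrast <- match.arg(contrast)
  conditioning <- match.arg(conditioning)
  df <- merge(strata,
              pairs[, c("drug_id", "complex_id", "outcome", "n_targets")],
              by.x = c("drug_id", "cancer_id"),
              by.y = c("drug_id", "complex_id"))
  df <- switch(conditioning,
               all = df,
               comorbid = df[df$comorbid == 1L, , drop = FALSE],
               noncomorbid = df[df$comorbid == 0L, , drop = FALSE])
  if (!nrow(df))
    stop(sprintf("conditioning subset '%s' is empty", conditioning),
         call. = FALSE)
  if (length(unique(df[[contrast]])) < 2)
    stop(sprintf("contrast '%s' has a single level within subset '%s'",
                 contrast, conditioning), call. = FALSE)
  fit_enrichment(df, adjust = setdiff(adjust, "category"), term = contrast)
}
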