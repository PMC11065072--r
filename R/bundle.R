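#' Assemble and validate an input bundle
#'
#' The bundle is the package's central container: disease registries, the
#' comorbidity relation, the drug-target map and clinical evidence, all as
#' plain data frames so they round-trip through TSV unchanged.
#'
#' @param mendelian data.frame with columns `id`, `name` — one row per
#'   Mendelian disease. Chromosomal-abnormality syndromes without an obvious
#'   causal gene are assumed pre-filtered upstream; a disease with zero causal
#'   genes only triggers a warning.
#' @param mendelian_genes data.frame `mendelian_id`, `gene` — OMIM-style
#'   causal gene map (long format, one gene per row).
#' @param complex data.frame `id`, `name`, `category`; `category` must be one
#'   of the six values in [DISEASE_CATEGORIES].
#' @param comorbidity data.frame `mendelian_id`, `complex_id` — the clinically
#'   associated (comorbid) pairs.
#' @param drug_targets data.frame `drug_id`, `gene` — drug to gene-target map
#'   (long format). Every drug must have at least one target.
#' @param evidence data.frame `drug_id`, `complex_id`, `phase` with raw or
#'   grouped phase labels; duplicates collapse to the most advanced phase.
#' @param indicated data.frame `drug_id`, `complex_id` — indication flags
#'   (RxNORM may_treat/may_prevent, repoDB approved, and the like). Phase IV
#'   evidence is merged in automatically.
#' @return an object of class `comorbid_bundle` (a named list of the seven
#'   validated tables).
#' @seealso [read_bundle()], [write_bundle()], [generate_world()]
#' @export
comorbid_bundle <- function(mendelian, mendelian_genes, complex, comorbidity,
                            drug_targets, evidence = NULL, indicated = NULL) {
  if (is.null(evidence))
    evidence <- data.frame(drug_id = character(), complex_id = character(),
                           phase = character())
  if (is.null(indicated))
    indicated <- data.frame(drug_id = character(), complex_id = character())
  b <- list(mendelian = as.data.frame(mendelian),
            mendelian_genes = as.data.frame(mendelian_genes),
            complex = as.data.frame(complex),
            comorbidity = as.data.frame(comorbidity),
            drug_targets = as.data.frame(drug_targets),
            evidence = as.data.frame(evidence),
            indicated = as.data.frame(indicated))
  validate_bundle(b)
}

.need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("table '%s' is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df[cols]
}

.dedupe <- function(df, what) {
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sprintf("%d duplicate row(s) in '%s' removed", sum(dup), what),
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

.check_ids <- function(ids, registry, what, file = what) {
  bad <- setdiff(unique(ids), registry)
  if (length(bad)) {
    lines <- which(ids %in% bad)[seq_len(min(5, sum(ids %in% bad)))]
    stop(sprintf("unresolvable id(s) in '%s' (e.g. line %s): %s", file,
                 paste(lines, collapse = ","),
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
}

#' Validate a bundle in place
#'
#' Checks every cross-reference, deduplicates relations (with a warning),
#' collapses duplicate clinical evidence to the most advanced phase per
#' (drug, disease) pair, and folds Phase IV evidence into the indication set.
#'
#' @param b a list with the seven bundle tables (see [comorbid_bundle()]).
#' @return the validated `comorbid_bundle`.
#' @export
validate_bundle <- function(b) {
  b$mendelian <- .dedupe(.need_cols(b$mendelian, c("id", "name"),
                                    "mendelian_diseases"), "mendelian_diseases")
  b$complex <- .dedupe(.need_cols(b$complex, c("id", "name", "category"),
                                  "complex_diseases"), "complex_diseases")
  b$mendelian_genes <- .dedupe(.need_cols(b$mendelian_genes,
                                          c("mendelian_id", "gene"),
                                          "mendelian_genes"), "mendelian_genes")
  b$comorbidity <- .dedupe(.need_cols(b$comorbidity,
                                      c("mendelian_id", "complex_id"),
                                      "comorbidity"), "comorbidity")
  b$drug_targets <- .dedupe(.need_cols(b$drug_targets, c("drug_id", "gene"),
                                       "drug_targets"), "drug_targets")
  b$evidence <- .need_cols(b$evidence, c("drug_id", "complex_id", "phase"),
                           "clinical_evidence")
  b$indicated <- .dedupe(.need_cols(b$indicated, c("drug_id", "complex_id"),
                                    "indications"), "indications")

  if (anyDuplicated(b$mendelian$id))
    stop("duplicate Mendelian disease ids in registry", call. = FALSE)
  if (anyDuplicated(b$complex$id))
    stop("duplicate complex disease ids in registry", call. = FALSE)
  bad_cat <- setdiff(unique(b$complex$category), DISEASE_CATEGORIES)
  if (length(bad_cat))
    stop("unknown disease category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)

  .check_ids(b$mendelian_genes$mendelian_id, b$mendelian$id, "mendelian_genes")
  .check_ids(b$comorbidity$mendelian_id, b$mendelian$id, "comorbidity")
  .check_ids(b$comorbidity$complex_id, b$complex$id, "comorbidity")
  .check_ids(b$evidence$complex_id, b$complex$id, "clinical_evidence")
  .check_ids(b$indicated$complex_id, b$complex$id, "indications")

  no_gene <- setdiff(b$mendelian$id, b$mendelian_genes$mendelian_id)
  if (length(no_gene))
    warning("Mendelian disease(s) with no causal gene: ",
            paste(no_gene, collapse = ", "), call. = FALSE)

  # group + collapse clinical evidence to the most advanced phase per pair
  if (nrow(b$evidence)) {
    ev <- b$evidence
    ev$phase <- group_phase(ev$phase)
    key <- paste(ev$drug_id, ev$complex_id, sep = "\r")
    ord <- order(key, -phase_rank(ev$phase))
    ev <- ev[ord, , drop = FALSE]
    ev <- ev[!duplicated(key[ord]), , drop = FALSE]
    rownames(ev) <- NULL
    b$evidence <- ev
    # Phase IV trials are post-approval: fold into the indication set
    p4 <- ev[ev$phase == "INDICATED", c("drug_id", "complex_id")]
    if (nrow(p4)) {
      ind <- unique(rbind(b$indicated, p4))
      rownames(ind) <- NULL
      b$indicated <- ind
    }
  }
  structure(b, class = "comorbid_bundle")
}

#' @export
print.comorbid_bundle <- function(x, ...) {
  cat("comorbid_bundle\n")
  cat(sprintf("  %d Mendelian diseases (%d causal gene links, %d unique genes)\n",
              nrow(x$mendelian), nrow(x$mendelian_genes),
              length(unique(x$mendelian_genes$gene))))
  cat(sprintf("  %d complex diseases in %d categories\n", nrow(x$complex),
              length(unique(x$complex$category))))
  cat(sprintf("  %d comorbid pairs\n", nrow(x$comorbidity)))
  cat(sprintf("  %d drugs, %d drug-target links\n",
              length(unique(x$drug_targets$drug_id)), nrow(x$drug_targets)))
  cat(sprintf("  %d clinical evidence records, %d indicated pairs\n",
              nrow(x$evidence), nrow(x$indicated)))
  invisible(x)
}

#' Number of known gene targets per drug
#'
#' @param bundle a `comorbid_bundle`.
#' @return named integer vector over all drugs in the target map.
#' @export
n_targets_per_drug <- function(bundle) {
  tab <- table(bundle$drug_targets$drug_id)
  stats::setNames(as.integer(tab), names(tab))
}
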