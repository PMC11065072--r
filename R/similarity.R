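#' @title Mendelian-cancer genetic similarity
#' @description
#' Two complementary metrics decide whether a Mendelian disease and a cancer
#' share genetic etiology. The gene overlap metric tests the intersection of
#' the Mendelian causal genes with the cancer's driver genes against a gene
#' universe (one-sided hypergeometric, i.e. Fisher's exact enrichment test).
#' The co-expression metric asks, for each cancer driver gene, whether the
#' Mendelian causal genes rank higher than all remaining genes in their
#' expression correlation with that driver across tissues (one-sided
#' rank-sum), with Benjamini-Hochberg adjustment across the cancer's driver
#' genes. A pair is called genetically similar if either metric is
#' significant at 0.05.
#' @name genetic-similarity
NULL

#' One-sided gene-set overlap test
#'
#' Exact hypergeometric upper-tail probability of observing at least the
#' realized intersection between two gene sets drawn from a common universe
#' (identical to the one-sided Fisher's exact test for enrichment).
#'
#' @param mendelian_genes,cancer_genes character vectors of gene symbols;
#'   both must be subsets of `universe`.
#' @param universe the background gene universe.
#' @return p-value: `P(X >= |intersection|)`.
#' @export
gene_overlap_test <- function(mendelian_genes, cancer_genes, universe) {
  mendelian_genes <- unique(mendelian_genes)
  cancer_genes <- unique(cancer_genes)
  universe <- unique(universe)
  for (nm in c("mendelian_genes", "cancer_genes")) {
    s <- get(nm)
    bad <- setdiff(s, universe)
    if (length(bad))
      stop(sprintf("%s not in universe: %s", nm,
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
  }
  k <- length(intersect(mendelian_genes, cancer_genes))
  stats::phyper(k - 1, length(mendelian_genes),
                length(universe) - length(mendelian_genes),
                length(cancer_genes), lower.tail = FALSE)
}

# correlations of one gene's tissue profile against all other rows
.cor_with_gene <- function(gene, expr, method) {
  v <- expr[gene, ]
  others <- expr[setdiff(rownames(expr), gene), , drop = FALSE]
  sds <- apply(others, 1, stats::sd)
  dropped <- rownames(others)[sds == 0]
  if (length(dropped)) {
    message(sprintf("%d constant-expression gene(s) dropped from the background",
                    length(dropped)))
    others <- others[sds > 0, , drop = FALSE]
  }
  if (stats::sd(v) == 0)
    stop(sprintf("gene '%s' has constant expression; no correlation defined",
                 gene), call. = FALSE)
  drop(stats::cor(v, t(others), method = method))
}

#' Co-expression test of a cancer gene against a Mendelian gene set
#'
#' Correlates the cancer gene's expression profile across tissues with every
#' other gene in the matrix, then tests (one-sided rank-sum, "greater")
#' whether the Mendelian set's correlations stochastically dominate the
#' correlations of all remaining genes. The cancer gene itself is excluded
#' from both groups; constant-expression genes are dropped from the
#' comparison with a message.
#'
#' @param cancer_gene a gene symbol present in `expr`.
#' @param mendelian_genes gene symbols; those present in `expr` are used.
#' @param expr expression matrix (genes x tissues), see
#'   [as_expression_matrix()].
#' @param method correlation type: `"spearman"` (default; robust to the
#'   right-skew of expression summaries) or `"pearson"`.
#' @param log1p_values log1p-transform values first (only sensible with
#'   Pearson).
#' @return raw one-sided p-value.
#' @export
coexpression_test <- function(cancer_gene, mendelian_genes, expr,
                              method = c("spearman", "pearson"),
                              log1p_values = FALSE) {
  method <- match.arg(method)
  if (!cancer_gene %in% rownames(expr))
    stop(sprintf("cancer gene '%s' not in expression matrix", cancer_gene),
         call. = FALSE)
  if (log1p_values) expr <- log1p(expr)
  mend <- setdiff(intersect(unique(mendelian_genes), rownames(expr)),
                  cancer_gene)
  if (!length(mend))
    stop("no Mendelian gene with expression data", call. = FALSE)
  cors <- .cor_with_gene(cancer_gene, expr, method)
  in_set <- names(cors) %in% mend
  if (all(in_set))
    stop("Mendelian set covers every background gene; comparison undefined",
         call. = FALSE)
  .ranksum_greater(cors[in_set], cors[!in_set])
}

#' Genetic similarity call for one Mendelian-cancer pair
#'
#' Combines the overlap and co-expression metrics. The co-expression test is
#' run once per driver gene of the cancer (drivers absent from the
#' expression matrix are skipped) and the resulting p-values are
#' Benjamini-Hochberg adjusted across the tested drivers; the pair's
#' co-expression summary is the minimum adjusted p. When no Mendelian gene
#' has expression data the co-expression metric is absent (`NA`) and the
#' call rests on the overlap metric alone.
#'
#' @param mendelian_genes causal genes of the Mendelian disease.
#' @param cancer_genes driver genes of the cancer (non-empty).
#' @param expr expression matrix, or `NULL` to skip co-expression.
#' @param universe background universe for the overlap test (default: the
#'   genes of the expression matrix).
#' @param alpha significance level for both metrics.
#' @param method correlation type for [coexpression_test()].
#' @return list of class `similarity_call`: `overlap_p`,
#'   `coexpr_min_adj_p` (`NA` when absent), `similar` (either metric
#'   < `alpha`), `n_coexpr_tested`.
#' @export
similarity_call <- function(mendelian_genes, cancer_genes, expr = NULL,
                            universe = NULL, alpha = 0.05,
                            method = "spearman") {
  if (!length(cancer_genes)) stop("empty cancer driver gene set",
                                  call. = FALSE)
  if (is.null(universe)) {
    if (is.null(expr))
      stop("need either an expression matrix or an explicit universe",
           call. = FALSE)
    universe <- rownames(expr)
  }
  overlap_p <- gene_overlap_test(intersect(unique(mendelian_genes), universe),
                                 intersect(unique(cancer_genes), universe),
                                 universe)
  coexpr_min <- NA_real_
  n_tested <- 0L
  if (!is.null(expr)) {
    mend_in <- intersect(unique(mendelian_genes), rownames(expr))
    drivers_in <- intersect(unique(cancer_genes), rownames(expr))
    if (length(mend_in) && length(drivers_in)) {
      raw <- vapply(drivers_in, function(g)
        tryCatch(suppressMessages(
          coexpression_test(g, mend_in, expr, method = method)),
          error = function(e) NA_real_), numeric(1))
      raw <- raw[!is.na(raw)]
      n_tested <- length(raw)
      if (n_tested) coexpr_min <- min(stats::p.adjust(raw, method = "BH"))
    }
  }
  similar <- (overlap_p < alpha) ||
    (!is.na(coexpr_min) && coexpr_min < alpha)
  structure(list(overlap_p = overlap_p, coexpr_min_adj_p = coexpr_min,
                 similar = similar, n_coexpr_tested = n_tested,
                 alpha = alpha),
            class = "similarity_call")
}

#' @export
print.similarity_call <- function(x, ...) {
  cat(sprintf("similarity call: overlap p = %.3g, min BH co-expression p = %s -> %s\n",
              x$overlap_p,
              if (is.na(x$coexpr_min_adj_p)) "absent"
              else sprintf("%.3g", x$coexpr_min_adj_p),
              if (x$similar) "SIMILAR" else "not similar"))
  invisible(x)
}

#' Similarity calls for all Mendelian-cancer pairs
#'
#' @param bundle a `comorbid_bundle` (source of the Mendelian causal genes).
#' @param cancer_sets named list of driver gene sets (see
#'   [read_driver_genes()]).
#' @param expr expression matrix or `NULL`.
#' @param universe,alpha,method passed to [similarity_call()].
#' @return data.frame: `mendelian_id`, `cancer_id`, `overlap_p`,
#'   `coexpr_min_adj_p`, `similar`.
#' @export
similarity_table <- function(bundle, cancer_sets, expr = NULL,
                             universe = NULL, alpha = 0.05,
                             method = "spearman") {
  genes_by_m <- split(bundle$mendelian_genes$gene,
                      bundle$mendelian_genes$mendelian_id)
  rows <- list()
  for (m in names(genes_by_m)) for (cn in names(cancer_sets)) {
    sc <- similarity_call(genes_by_m[[m]], cancer_sets[[cn]], expr = expr,
                          universe = universe, alpha = alpha,
                          method = method)
    rows[[length(rows) + 1L]] <- data.frame(
      mendelian_id = m, cancer_id = cn, overlap_p = sc$overlap_p,
      coexpr_min_adj_p = sc$coexpr_min_adj_p, similar = sc$similar)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
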