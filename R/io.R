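#' @title TSV interchange for input bundles
#' @description
#' All pipeline inputs are plain TSV files with fixed headers, one table per
#' file. Identifiers are opaque strings (DrugBank/OMIM-style ids accepted but
#' not required).
#'
#' | file | columns |
#' |---|---|
#' | `mendelian_diseases.tsv` | `id`, `name` |
#' | `mendelian_genes.tsv`    | `mendelian_id`, `gene` |
#' | `complex_diseases.tsv`   | `id`, `name`, `category` |
#' | `comorbidity.tsv`        | `mendelian_id`, `complex_id` |
#' | `drug_targets.tsv`       | `drug_id`, `gene` |
#' | `clinical_evidence.tsv`  | `drug_id`, `complex_id`, `phase` |
#' | `indications.tsv`        | `drug_id`, `complex_id` |
#'
#' @name bundle-io
NULL

BUNDLE_FILES <- c(mendelian = "mendelian_diseases.tsv",
                  mendelian_genes = "mendelian_genes.tsv",
                  complex = "complex_diseases.tsv",
                  comorbidity = "comorbidity.tsv",
                  drug_targets = "drug_targets.tsv",
                  evidence = "clinical_evidence.tsv",
                  indicated = "indications.tsv")

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = TRUE,
                    na.strings = NULL, quote = "")
}

#' Read an input bundle from a directory of TSV files
#'
#' Reads the seven tables (see [bundle-io] for the schemas), validates all
#' cross-references and reports per-table record counts via `message()`.
#' The evidence and indication tables are optional; all others must exist.
#'
#' @param dir directory containing the TSV files.
#' @param quiet suppress the per-table record count messages.
#' @return a validated [comorbid_bundle()].
#' @export
read_bundle <- function(dir, quiet = FALSE) {
  paths <- file.path(dir, BUNDLE_FILES)
  names(paths) <- names(BUNDLE_FILES)
  required <- setdiff(names(paths), c("evidence", "indicated"))
  miss <- required[!file.exists(paths[required])]
  if (length(miss))
    stop("missing input file(s): ",
         paste(BUNDLE_FILES[miss], collapse = ", "), call. = FALSE)
  tabs <- lapply(names(paths), function(nm) {
    p <- paths[[nm]]
    if (!file.exists(p)) return(NULL)
    df <- .read_tsv(p)
    if (!quiet) message(sprintf("read %s: %d records", BUNDLE_FILES[[nm]],
                                nrow(df)))
    df
  })
  names(tabs) <- names(paths)
  comorbid_bundle(mendelian = tabs$mendelian,
                  mendelian_genes = tabs$mendelian_genes,
                  complex = tabs$complex,
                  comorbidity = tabs$comorbidity,
                  drug_targets = tabs$drug_targets,
                  evidence = tabs$evidence,
                  indicated = tabs$indicated)
}

#' Write an input bundle to a directory of TSV files
#'
#' Inverse of [read_bundle()]: `read_bundle(write_bundle(b, d))` returns a
#' bundle identical to `b`.
#'
#' @param bundle a `comorbid_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "comorbid_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(BUNDLE_FILES)) {
    utils::write.table(bundle[[nm]], file.path(dir, BUNDLE_FILES[[nm]]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a gene-by-tissue expression matrix
#'
#' Accepts the long three-column layout of tissue expression summaries
#' (`gene`, `tissue`, `value`, header required, extra columns ignored).
#' Genes lacking a value for every tissue are dropped at load with a message,
#' mirroring the upstream handling of incomplete tissue coverage.
#'
#' @param path TSV file in long format.
#' @param min_tissues minimum number of tissues required (co-expression over
#'   fewer than 3 tissues is meaningless).
#' @return numeric matrix, genes in rows, tissues in columns.
#' @export
read_expression <- function(path, min_tissues = 3L) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "")
  need <- c("gene", "tissue", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("expression table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$value <- as.numeric(df$value)
  genes <- unique(df$gene)
  tissues <- unique(df$tissue)
  m <- matrix(NA_real_, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  m[cbind(match(df$gene, genes), match(df$tissue, tissues))] <- df$value
  as_expression_matrix(m, min_tissues = min_tissues)
}

#' Coerce a matrix to a complete expression matrix
#'
#' Drops genes with any missing tissue value (with a message) and checks the
#' tissue count.
#'
#' @param m numeric matrix, genes in rows, tissues in columns.
#' @param min_tissues minimum tissue count.
#' @return the filtered matrix.
#' @export
as_expression_matrix <- function(m, min_tissues = 3L) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < min_tissues)
    stop(sprintf("expression matrix has %d tissues; at least %d required",
                 ncol(m), min_tissues), call. = FALSE)
  incomplete <- rowSums(is.na(m)) > 0
  if (any(incomplete)) {
    message(sprintf("dropping %d gene(s) without full tissue coverage",
                    sum(incomplete)))
    m <- m[!incomplete, , drop = FALSE]
  }
  if (any(m < 0, na.rm = TRUE))
    stop("expression values must be non-negative", call. = FALSE)
  m
}

#' Read cancer driver gene lists
#'
#' Two-column TSV (`cancer_id`, `gene`); returns a named list of character
#' vectors, one per cancer. Every cancer must have at least one driver gene.
#'
#' @param path TSV file path.
#' @return named list of driver gene sets.
#' @export
read_driver_genes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  miss <- setdiff(c("cancer_id", "gene"), names(df))
  if (length(miss))
    stop("driver gene table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  split(df$gene, df$cancer_id)
}
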