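#' Assemble an expression study
#'
#' Bundles the pipeline's raw input: a gene-by-sample matrix of non-negative
#' integer read counts, per-gene lengths in base pairs, and a sample sheet
#' mapping each sample (column) to an organ and replicate.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). No negative entries.
#' @param gene_length named numeric vector of gene lengths in bp, one entry
#'   per row of `counts`; all lengths must be positive.
#' @param design data.frame with columns `sample_id`, `organ`, `replicate`;
#'   every column of `counts` must appear in `sample_id`.
#' @return An object of class `expression_study`: a list with elements
#'   `counts`, `gene_length`, `design`.
#' @export
expression_study <- function(counts, gene_length, design) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must be a matrix with gene rownames and sample colnames", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]), call. = FALSE)
  }
  if (any(counts != round(counts)))
    stop("counts must be integers", call. = FALSE)
  gene_length <- gene_length[rownames(counts)]
  if (anyNA(gene_length))
    stop("gene_length missing for some genes in counts", call. = FALSE)
  if (any(gene_length <= 0))
    stop(sprintf("non-positive length for gene '%s'",
                 rownames(counts)[which(gene_length <= 0)[1L]]), call. = FALSE)
  req <- c("sample_id", "organ", "replicate")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    stop("design must be a data.frame with sample_id, organ, replicate", call. = FALSE)
  missing_s <- setdiff(colnames(counts), design$sample_id)
  if (length(missing_s))
    stop(sprintf("samples absent from design: %s", paste(missing_s, collapse = ", ")),
         call. = FALSE)
  design <- design[match(colnames(counts), design$sample_id), req, drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, gene_length = gene_length, design = design),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples (%d organs)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$design$organ))))
  invisible(x)
}

#' Organ label for each sample, in column order
#' @param study an `expression_study`
#' @return character vector of organ labels, one per sample.
#' @export
organ_labels <- function(study) study$design$organ
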