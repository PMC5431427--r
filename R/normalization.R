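#' TMM scaling factors
#'
#' Trimmed mean of M-values between-sample normalization for count data.
#' The reference sample is the one whose upper quartile of `count/libsize`
#' (over its nonzero genes) is closest to the mean upper quartile. For every
#' sample, over genes nonzero in both sample and reference,
#' `M = log2((y/N)/(y_r/N_r))` and `A = (1/2) log2((y/N)(y_r/N_r))` are
#' computed; the most extreme 30% of M and 5% of A are trimmed from each
#' tail, and the factor is `2^` the weighted mean of the surviving M with
#' inverse asymptotic-variance weights
#' `1 / ((N - y)/(N y) + (N_r - y_r)/(N_r y_r))`. Factors are rescaled to
#' geometric mean 1.
#'
#' @param counts gene x sample count matrix with at least two samples; every
#'   sample must have a positive total count.
#' @param trim_m,trim_a trim fractions applied to each tail of the M and A
#'   distributions (published defaults 0.30 and 0.05).
#' @return named numeric vector of scaling factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  assert_numeric_matrix(counts, "counts")
  if (ncol(counts) < 2L) stop("tmm_factors needs at least 2 samples", call. = FALSE)
  libsize <- colSums(counts)
  if (any(libsize <= 0))
    stop(sprintf("degenerate input: sample '%s' has zero total counts",
                 colnames(counts)[which(libsize <= 0)[1L]]), call. = FALSE)
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    y <- counts[, j]
    stats::quantile(y[y > 0] / libsize[j], 0.75, names = FALSE)
  }, 1)
  ref <- which.min(abs(uq - mean(uq)))
  yr <- counts[, ref]
  Nr <- libsize[ref]

  one_factor <- function(j) {
    y <- counts[, j]
    N <- libsize[j]
    keep <- y > 0 & yr > 0
    if (!any(keep)) return(1)
    yk <- y[keep]; yrk <- yr[keep]
    M <- log2((yk / N) / (yrk / Nr))
    A <- 0.5 * log2((yk / N) * (yrk / Nr))
    w <- 1 / ((N - yk) / (N * yk) + (Nr - yrk) / (Nr * yrk))
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    kept <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(kept)) return(1)
    2^(sum(w[kept] * M[kept]) / sum(w[kept]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, 1)
  f <- f / geometric_mean(f)
  stats::setNames(f, colnames(counts))
}

#' FPKM matrix
#'
#' Fragments per kilobase of feature per million mapped fragments:
#' `fpkm = 1e9 * count / (effective_libsize * length_bp)`.
#'
#' @param counts gene x sample count matrix.
#' @param gene_length positive lengths in bp, one per gene.
#' @param effective_libsize positive per-sample library sizes (typically raw
#'   library size times TMM factor).
#' @return numeric matrix of the same shape as `counts`.
#' @export
fpkm_matrix <- function(counts, gene_length, effective_libsize) {
  assert_numeric_matrix(counts, "counts")
  if (any(gene_length <= 0))
    stop(sprintf("zero or negative length for gene '%s'",
                 rownames(counts)[which(gene_length <= 0)[1L]]), call. = FALSE)
  if (any(effective_libsize <= 0))
    stop("effective_libsize must be positive", call. = FALSE)
  sweep(counts / gene_length, 2, effective_libsize, `/`) * 1e9
}

#' log2 counts per million
#'
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)`; the prior keeps
#' every value finite.
#'
#' @param counts gene x sample count matrix.
#' @param effective_libsize positive per-sample library sizes.
#' @param prior positive pseudo-count (default 0.5).
#' @return numeric matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, effective_libsize, prior = 0.5) {
  assert_numeric_matrix(counts, "counts")
  if (!is.numeric(prior) || length(prior) != 1L || prior <= 0)
    stop("prior must be a single positive value", call. = FALSE)
  log2(sweep(counts + prior, 2, effective_libsize + 2 * prior, `/`) * 1e6)
}

#' Median-center the rows of a matrix
#'
#' Subtracts each row's median, so every output row has median zero. Used
#' for cluster expression profiles on the log2 FPKM scale.
#'
#' @param mat numeric matrix with at least one column.
#' @return matrix of the same shape with row medians 0.
#' @export
median_center <- function(mat) {
  assert_numeric_matrix(mat, "matrix")
  if (ncol(mat) < 1L) stop("median_center needs at least one column", call. = FALSE)
  mat - apply(mat, 1, stats::median)
}

#' Normalize an expression study
#'
#' Runs the normalization stage: TMM factors, effective library sizes, FPKM
#' on TMM-effective library sizes, log2-CPM, and per-gene median-centered
#' log2(FPKM + 1).
#'
#' @param study an [expression_study()].
#' @param prior pseudo-count for [log_cpm()].
#' @return Object of class `normalized_expression`: list with `tmm_factor`,
#'   `effective_libsize`, `fpkm`, `log_cpm`, `log_fpkm` (log2(FPKM + 1)) and
#'   `centered` (median-centered `log_fpkm`).
#' @export
normalize_study <- function(study, prior = 0.5) {
  stopifnot(inherits(study, "expression_study"))
  tmm <- tmm_factors(study$counts)
  eff <- colSums(study$counts) * tmm
  fpkm <- fpkm_matrix(study$counts, study$gene_length, eff)
  lf <- log2(fpkm + 1)
  structure(list(
    tmm_factor = tmm,
    effective_libsize = eff,
    fpkm = fpkm,
    log_cpm = log_cpm(study$counts, eff, prior),
    log_fpkm = lf,
    centered = median_center(lf)
  ), class = "normalized_expression")
}
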