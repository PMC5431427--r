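#' Presence/absence calls per gene and organ
#'
#' For each organ the maximum FPKM over that organ's replicates decides the
#' call: `>= 1` is `expressed`, exactly `0` is `absent`, and anything in
#' `(0, 1)` is `indeterminate` (neither rule fires).
#'
#' @param fpkm gene x sample FPKM matrix.
#' @param design design data.frame (`sample_id`, `organ`); every organ must
#'   have at least one sample.
#' @return data.frame of class `presence_call`: `gene_id`, `organ`,
#'   `max_fpkm`, `status`.
#' @export
presence_call <- function(fpkm, design) {
  assert_numeric_matrix(fpkm, "fpkm")
  organs <- unique(design$organ)
  labels <- design$organ[match(colnames(fpkm), design$sample_id)]
  if (anyNA(labels)) stop("design error: samples missing from design", call. = FALSE)
  empty <- setdiff(organs, labels)
  if (length(empty))
    stop(sprintf("design error: organ '%s' has no samples", empty[1L]), call. = FALSE)
  res <- lapply(organs, function(o) {
    mx <- apply(fpkm[, labels == o, drop = FALSE], 1, max)
    data.frame(gene_id = rownames(fpkm), organ = o, max_fpkm = mx,
               status = ifelse(mx >= 1, "expressed",
                               ifelse(mx == 0, "absent", "indeterminate")),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  attr(out, "organs") <- organs
  class(out) <- c("presence_call", class(out))
  out
}

presence_matrix <- function(presence, status = "expressed") {
  organs <- attr(presence, "organs") %||% unique(presence$organ)
  genes <- unique(presence$gene_id)
  m <- matrix(FALSE, length(genes), length(organs), dimnames = list(genes, organs))
  m[cbind(match(presence$gene_id, genes), match(presence$organ, organs))] <-
    presence$status == status
  m
}

#' Venn partition of expressed genes over organs
#'
#' Every gene expressed in at least one organ is counted in exactly one of
#' the `2^K - 1` regions given by its set of expressing organs; genes
#' expressed nowhere are excluded.
#'
#' @param presence a [presence_call()].
#' @return data.frame with `region` (organ names joined by `+`), `bitmask`
#'   (bit i set = organ i expressed, organs in first-appearance order) and
#'   `count`, covering all `2^K - 1` regions.
#' @export
venn_partition <- function(presence) {
  expr <- presence_matrix(presence, "expressed")
  organs <- colnames(expr)
  K <- length(organs)
  bits <- as.integer(expr %*% 2^(seq_len(K) - 1))
  masks <- seq_len(2^K - 1)
  region_name <- vapply(masks, function(m)
    paste(organs[bitwAnd(m, 2^(seq_len(K) - 1)) > 0], collapse = "+"), "")
  counts <- vapply(masks, function(m) sum(bits == m), 1L)
  data.frame(region = region_name, bitmask = masks, count = counts,
             stringsAsFactors = FALSE)
}

#' Organ-exclusive gene sets
#'
#' A gene is exclusive to organ `o` when it is expressed in `o` and called
#' `absent` (max FPKM exactly 0) in every other organ; an `indeterminate`
#' call elsewhere blocks exclusivity.
#'
#' @param presence a [presence_call()].
#' @return named list, organ -> character vector of exclusive gene ids.
#' @export
exclusive_sets <- function(presence) {
  expr <- presence_matrix(presence, "expressed")
  abs_ <- presence_matrix(presence, "absent")
  organs <- colnames(expr)
  out <- lapply(seq_along(organs), function(k) {
    rownames(expr)[expr[, k] & rowSums(abs_[, -k, drop = FALSE]) == length(organs) - 1L]
  })
  stats::setNames(out, organs)
}

#' Hierarchical clustering of samples
#'
#' Complete-linkage agglomerative clustering of the matrix columns under
#' Euclidean distance.
#'
#' @param mat gene x sample numeric matrix (e.g. TMM-normalized log
#'   expression); no NA/NaN allowed.
#' @return an object of class `hclust`.
#' @export
sample_dendrogram <- function(mat) {
  if (anyNA(mat)) stop("matrix contains NA/NaN values", call. = FALSE)
  if (ncol(mat) < 2L) stop("need at least 2 samples", call. = FALSE)
  stats::hclust(stats::dist(t(mat), method = "euclidean"), method = "complete")
}

#' Cluster genes into expression-profile groups
#'
#' Complete-linkage Euclidean clustering of gene rows (typically the
#' median-centered log2 FPKM matrix), cut into `k` clusters. Each cluster's
#' profile is the per-sample median over its member genes.
#'
#' @param centered gene x sample matrix (median-centered log2 FPKM).
#' @param k number of clusters (default 6).
#' @return list of class `cluster_profiles`: `assignment` (named cluster id
#'   per gene), `profiles` (cluster x sample median matrix), `sizes`, and the
#'   `hclust` tree.
#' @export
gene_clusters <- function(centered, k = 6) {
  if (anyNA(centered)) stop("matrix contains NA/NaN values", call. = FALSE)
  if (nrow(centered) < 2L) stop("need at least 2 genes", call. = FALSE)
  hc <- stats::hclust(stats::dist(centered, method = "euclidean"), method = "complete")
  assignment <- stats::cutree(hc, k = min(k, nrow(centered)))
  profiles <- do.call(rbind, lapply(sort(unique(assignment)), function(cl)
    apply(centered[assignment == cl, , drop = FALSE], 2, stats::median)))
  rownames(profiles) <- sort(unique(assignment))
  structure(list(assignment = assignment, profiles = profiles,
                 sizes = as.integer(table(assignment)), tree = hc),
            class = "cluster_profiles")
}

#' Serialize an hclust tree to Newick
#'
#' @param hc an `hclust` object.
#' @return single Newick string (with branch lengths).
#' @export
as_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Squared Pearson correlation between two expression vectors
#'
#' The concordance statistic used to compare qPCR and RNA-seq profiles.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return R-squared (scalar in `[0, 1]`).
#' @export
expression_concordance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  stats::cor(x, y)^2
}
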