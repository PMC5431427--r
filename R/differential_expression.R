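#' One-way ANOVA F statistic across organs
#'
#' `F = (SS_between / (g - 1)) / (SS_within / (n - g))`. By convention
#' `F = 0` when both sums of squares are zero (a constant gene) and
#' `F = Inf` when the within-group sum of squares is zero but the
#' between-group sum is positive.
#'
#' @param x numeric vector of (log-scale) expression values, one per sample.
#' @param labels group label per sample; at least two groups, each with at
#'   least two replicates.
#' @return the F statistic (scalar).
#' @export
organ_f_statistic <- function(x, labels) {
  drop(f_statistics(matrix(x, nrow = 1), labels))
}

#' Row-wise F statistics for an expression matrix
#'
#' @param mat gene x sample numeric matrix.
#' @param labels organ label per column.
#' @return named numeric vector of per-gene F statistics.
#' @export
f_statistics <- function(mat, labels) {
  assert_numeric_matrix(mat, "expression matrix")
  labels <- as.character(labels)
  if (length(labels) != ncol(mat))
    stop("labels must have one entry per sample", call. = FALSE)
  sizes <- table(labels)
  g <- length(sizes)
  n <- length(labels)
  if (g < 2L) stop("degenerate design: need at least 2 organs", call. = FALSE)
  if (any(sizes < 2L))
    stop(sprintf("degenerate design: organ '%s' has a single replicate",
                 names(sizes)[which(sizes < 2L)[1L]]), call. = FALSE)
  gm <- rowMeans(mat)
  group_sum <- t(rowsum(t(mat), labels))          # gene x group sums
  ns <- as.numeric(sizes[colnames(group_sum)])
  group_mean <- sweep(group_sum, 2, ns, `/`)
  ss_between <- rowSums(sweep((group_mean - gm)^2, 2, ns, `*`))
  ss_total <- rowSums((mat - gm)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  f <- (ss_between / (g - 1)) / (ss_within / (n - g))
  f[ss_between <= 1e-12 & ss_within <= 1e-12] <- 0
  f[ss_within <= 1e-12 & ss_between > 1e-12] <- Inf
  stats::setNames(f, rownames(mat))
}

#' Permutation p-values for the organ F test
#'
#' Shuffles organ labels over samples `n_perm` times (the same shuffles are
#' reused for every gene) and reports the add-one permutation p-value
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` per gene.
#'
#' @param mat gene x sample matrix of log-scale expression.
#' @param labels organ label per column.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the shuffle stream.
#' @return named numeric vector of p-values in `(0, 1]`.
#' @export
permutation_pvalues <- function(mat, labels, n_perm = 1000, seed = 1) {
  n_perm <- assert_count(n_perm, "n_perm", 99L)
  obs <- f_statistics(mat, labels)
  set.seed(seed)
  exceed <- integer(nrow(mat))
  for (b in seq_len(n_perm)) {
    fp <- f_statistics(mat, sample(labels))
    exceed <- exceed + (fp >= obs)
  }
  stats::setNames((1 + exceed) / (1 + n_perm), rownames(mat))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and
#' mapped back to the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Maximum absolute pairwise log2 fold change across organs
#'
#' For each gene, the largest absolute difference of organ-mean log
#' expression over all organ pairs (equal to the range of organ means).
#'
#' @param mat gene x sample matrix of log2-scale expression.
#' @param labels organ label per column.
#' @return named numeric vector, one value per gene.
#' @export
max_abs_log2fc <- function(mat, labels) {
  labels <- as.character(labels)
  group_sum <- t(rowsum(t(mat), labels))
  ns <- as.numeric(table(labels)[colnames(group_sum)])
  group_mean <- sweep(group_sum, 2, ns, `/`)
  stats::setNames(apply(group_mean, 1, max) - apply(group_mean, 1, min),
                  rownames(mat))
}

#' Differential expression across organs
#'
#' Computes per-gene F statistics on log2-CPM, p-values (permutation null by
#' default, asymptotic F distribution optionally), BH q-values, maximum
#' pairwise |log2 fold change| of organ means, and the DE flag
#' `q < alpha AND max_abs_log2fc > lfc` (both inequalities strict).
#'
#' @param norm a `normalized_expression` (or a log2 expression matrix).
#' @param design the study design data.frame (`sample_id`, `organ`).
#' @param alpha FDR threshold (default 0.05).
#' @param lfc log2 fold-change threshold (default 1.5).
#' @param n_perm permutations for the null (default 1000).
#' @param seed permutation seed.
#' @param asymptotic if TRUE use the F distribution instead of permutations.
#' @return data.frame of class `de_table`: `gene_id`, `f_stat`, `p_value`,
#'   `q_value`, `max_abs_log2fc`, `is_de`.
#' @export
de_table <- function(norm, design, alpha = 0.05, lfc = 1.5,
                     n_perm = 1000, seed = 1, asymptotic = FALSE) {
  mat <- if (inherits(norm, "normalized_expression")) norm$log_cpm else norm
  labels <- design$organ[match(colnames(mat), design$sample_id)]
  f <- f_statistics(mat, labels)
  if (asymptotic) {
    sizes <- table(labels)
    p <- stats::pf(f, length(sizes) - 1, ncol(mat) - length(sizes), lower.tail = FALSE)
    p[f == 0] <- 1
  } else {
    p <- permutation_pvalues(mat, labels, n_perm = n_perm, seed = seed)
  }
  q <- bh_fdr(p)
  fc <- max_abs_log2fc(mat, labels)
  out <- data.frame(gene_id = rownames(mat), f_stat = f, p_value = p,
                    q_value = q, max_abs_log2fc = fc,
                    is_de = q < alpha & fc > lfc,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_table", class(out))
  out
}

#' Genes called differentially expressed
#'
#' Strict thresholds, as printed in the source criteria: `q < alpha` and
#' `max_abs_log2fc > lfc`.
#'
#' @param tab a [de_table()].
#' @param alpha FDR threshold.
#' @param lfc log2 fold-change threshold.
#' @return character vector of DE gene ids.
#' @export
de_call <- function(tab, alpha = 0.05, lfc = 1.5) {
  tab$gene_id[tab$q_value < alpha & tab$max_abs_log2fc > lfc]
}
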