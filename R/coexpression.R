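#' Network-stage configuration
#'
#' Parameters of the signed weighted co-expression network and module
#' detection, with the defaults used throughout: soft threshold `beta = 20`,
#' `max_block_size = 11000`, `min_module_size = 30`, `deep_split = 2`,
#' `merge_cut_height = 0.2`.
#'
#' @param beta positive integer soft-threshold exponent.
#' @param max_block_size largest gene count handled in one block; larger
#'   inputs are rejected (blockwise decomposition is out of scope).
#' @param min_module_size smallest admissible module (>= 2).
#' @param deep_split integer 0-4 controlling the static cut height
#'   `(0.99 - 0.02 * deep_split) * h_max`.
#' @param merge_cut_height eigengene-dissimilarity threshold below which
#'   modules are merged, in (0, 1).
#' @return validated list of class `network_config`.
#' @export
network_config <- function(beta = 20, max_block_size = 11000,
                           min_module_size = 30, deep_split = 2,
                           merge_cut_height = 0.2) {
  beta <- assert_count(beta, "beta", 1L)
  max_block_size <- assert_count(max_block_size, "max_block_size", 2L)
  min_module_size <- assert_count(min_module_size, "min_module_size", 2L)
  deep_split <- assert_count(deep_split, "deep_split", 0L)
  if (deep_split > 4L) config_error("deep_split", "must be in 0..4")
  if (!is.numeric(merge_cut_height) || length(merge_cut_height) != 1L ||
      merge_cut_height <= 0 || merge_cut_height >= 1)
    config_error("merge_cut_height", "must lie in (0, 1)")
  structure(list(beta = beta, max_block_size = max_block_size,
                 min_module_size = min_module_size, deep_split = deep_split,
                 merge_cut_height = merge_cut_height),
            class = "network_config")
}

#' Pearson correlation matrix over genes
#'
#' @param expr gene x sample matrix (>= 3 samples).
#' @param drop_zero_var if TRUE (default), zero-variance genes are dropped
#'   with a warning; if FALSE their presence is an error.
#' @return gene x gene correlation matrix.
#' @export
pearson_matrix <- function(expr, drop_zero_var = TRUE) {
  assert_numeric_matrix(expr, "expression matrix")
  if (ncol(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    bad <- rownames(expr)[v == 0]
    if (!drop_zero_var)
      stop(sprintf("zero-variance genes: %s", paste(bad, collapse = ", ")), call. = FALSE)
    warning(sprintf("dropping %d zero-variance gene(s)", length(bad)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  stats::cor(t(expr))
}

#' Signed soft-threshold adjacency
#'
#' `a = ((1 + cor) / 2)^beta`, mapping correlation -1 to adjacency 0 and +1
#' to 1 so that anti-correlated genes are not connected.
#'
#' @param cor correlation matrix with entries in `[-1, 1]`.
#' @param beta soft-threshold exponent (default 20).
#' @return adjacency matrix in `[0, 1]`.
#' @export
signed_adjacency <- function(cor, beta = 20) {
  if (any(cor < -1 - 1e-12 | cor > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  ((1 + cor) / 2)^beta
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, with
#' `L_ij = sum_{u != i,j} a_iu a_uj` and connectivity `k_i = sum_{u != i}
#' a_iu`; `TOM_ii = 1`. Self-adjacency is excluded throughout.
#'
#' @param adjacency symmetric matrix with entries in `[0, 1]`.
#' @return symmetric TOM matrix with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  assert_symmetric(adjacency, "adjacency")
  if (any(adjacency < 0 | adjacency > 1))
    stop("adjacency values must lie in [0, 1]", call. = FALSE)
  A <- adjacency
  diag(A) <- 0
  L <- A %*% A                       # diag(A)=0 removes the u=i and u=j terms
  k <- rowSums(A)
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Build the signed co-expression network
#'
#' Correlation, signed adjacency, connectivity, TOM and TOM dissimilarity in
#' one container.
#'
#' @param expr gene x sample matrix (log2 TMM-normalized FPKM is the
#'   pipeline's convention).
#' @param config a [network_config()].
#' @return list of class `coexpression_network`: `genes`, `cor`,
#'   `adjacency`, `connectivity`, `tom`, `diss_tom`, `config`.
#' @export
build_network <- function(expr, config = network_config()) {
  cor <- pearson_matrix(expr)
  adj <- signed_adjacency(cor, config$beta)
  tom <- tom_similarity(adj)
  A <- adj; diag(A) <- 0
  structure(list(genes = rownames(cor), cor = cor, adjacency = adj,
                 connectivity = rowSums(A), tom = tom, diss_tom = 1 - tom,
                 config = config),
            class = "coexpression_network")
}

#' Detect co-expression modules on the TOM dendrogram
#'
#' Average-linkage clustering of TOM dissimilarity, cut statically at height
#' `(0.99 - 0.02 * deep_split) * h_max` where `h_max` is the final merge
#' height. Branches with at least `min_module_size` genes become modules,
#' labeled 1..M by decreasing size; all other genes get label 0.
#'
#' @param diss_tom symmetric TOM dissimilarity matrix (`1 - TOM`).
#' @param config a [network_config()].
#' @return list of class `module_partition`: `module_of_gene` (named integer,
#'   0 = unassigned), `module_sizes` (named by module id), `tree` (hclust),
#'   `cut_height`.
#' @export
detect_modules <- function(diss_tom, config = network_config()) {
  assert_symmetric(diss_tom, "diss_tom")
  n <- nrow(diss_tom)
  if (n > config$max_block_size)
    stop(sprintf(
      "block-size error: %d genes exceed max_block_size = %d (blockwise decomposition is not supported)",
      n, config$max_block_size), call. = FALSE)
  hc <- stats::hclust(stats::as.dist(diss_tom), method = "average")
  h_max <- max(hc$height)
  cut_h <- (0.99 - 0.02 * config$deep_split) * h_max
  raw <- stats::cutree(hc, h = cut_h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= config$min_module_size]
  labels <- ifelse(as.character(raw) %in% keep, raw, 0L)
  labels <- relabel_by_size(as.integer(labels))
  names(labels) <- rownames(diss_tom)
  module_partition(labels, tree = hc, cut_height = cut_h)
}

module_partition <- function(labels, tree = NULL, cut_height = NULL,
                             eigengenes = NULL) {
  sizes <- table(labels[labels > 0L])
  structure(list(module_of_gene = labels,
                 module_sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 eigengenes = eigengenes,
                 tree = tree, cut_height = cut_height),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d genes, %d modules (sizes %s), %d unassigned\n",
              length(x$module_of_gene), length(x$module_sizes),
              paste(x$module_sizes, collapse = ", "),
              sum(x$module_of_gene == 0L)))
  invisible(x)
}

#' Module eigengenes
#'
#' Each module's eigengene is the first principal component of its member
#' expression profiles: member genes are z-scored across samples, the first
#' right singular vector of the member x sample matrix is scaled to unit
#' variance, and its sign is chosen so that it correlates non-negatively
#' with the mean member profile. A single-gene module returns that gene's
#' z-scored profile with a warning.
#'
#' @param expr gene x sample expression matrix covering all labeled genes.
#' @param labels named integer module labels (0 = unassigned, ignored).
#' @return module x sample matrix of eigengenes (rownames = module ids),
#'   each row with unit variance.
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- sort(unique(labels[labels > 0L]))
  if (!length(mods)) stop("no modules to summarize", call. = FALSE)
  eg <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(as.character(mods), colnames(expr)))
  for (i in seq_along(mods)) {
    members <- names(labels)[labels == mods[i]]
    X <- expr[members, , drop = FALSE]
    X <- t(scale(t(X)))
    X[!is.finite(X)] <- 0                       # constant member profiles
    if (nrow(X) == 1L) {
      warning(sprintf("module %s has a single gene; returning its z-scored profile", mods[i]))
      e <- drop(X)
    } else {
      sv <- svd(X, nu = 0, nv = 1)
      e <- drop(sv$v[, 1])
    }
    s <- stats::sd(e)
    if (s > 0) e <- e / s
    ref <- colMeans(X)
    if (stats::sd(ref) > 0 && stats::cor(e, ref) < 0) e <- -e
    eg[i, ] <- e
  }
  eg
}

#' Merge modules with similar eigengenes
#'
#' Iteratively clusters module eigengenes by `1 - cor` dissimilarity under
#' average linkage, merges every group of modules joined below
#' `merge_cut_height`, recomputes eigengenes, and repeats until a fixed
#' point. Final labels are renumbered by decreasing module size.
#'
#' @param expr gene x sample expression matrix.
#' @param labels named integer module labels (0 = unassigned).
#' @param merge_cut_height dissimilarity threshold (default 0.2).
#' @return `module_partition` with merged labels and final `eigengenes`.
#' @export
merge_modules <- function(expr, labels, merge_cut_height = 0.2) {
  labels <- labels[!is.na(labels)]
  repeat {
    mods <- sort(unique(labels[labels > 0L]))
    if (length(mods) < 2L) break
    eg <- module_eigengenes(expr, labels)
    d <- 1 - stats::cor(t(eg))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(hc, h = merge_cut_height)
    if (length(unique(grp)) == length(mods)) break
    map <- stats::setNames(grp, rownames(eg))
    labels[labels > 0L] <- as.integer(map[as.character(labels[labels > 0L])])
  }
  labels <- relabel_by_size(labels)
  eg <- if (any(labels > 0L)) module_eigengenes(expr, labels) else NULL
  module_partition(labels, eigengenes = eg)
}
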