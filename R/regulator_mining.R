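#' Mining-stage configuration
#'
#' @param per_gene_k per-gene strongest edges to retain (default 4).
#' @param global_quantile fraction of globally strongest edges to retain
#'   (default 0.01, i.e. the top 1% of all unordered pairs).
#' @param top_tf_k length of each pathway gene's TF list (default 10).
#' @param min_list_count minimum number of lists a TF must appear in to be
#'   retained (default 2).
#' @return validated list of class `mining_config`.
#' @export
mining_config <- function(per_gene_k = 4, global_quantile = 0.01,
                          top_tf_k = 10, min_list_count = 2) {
  per_gene_k <- assert_count(per_gene_k, "per_gene_k", 1L)
  top_tf_k <- assert_count(top_tf_k, "top_tf_k", 1L)
  min_list_count <- assert_count(min_list_count, "min_list_count", 1L)
  if (!is.numeric(global_quantile) || length(global_quantile) != 1L ||
      global_quantile <= 0 || global_quantile > 1)
    config_error("global_quantile", "must lie in (0, 1]")
  structure(list(per_gene_k = per_gene_k, global_quantile = global_quantile,
                 top_tf_k = top_tf_k, min_list_count = min_list_count),
            class = "mining_config")
}

#' Sparsify a TOM network for export
#'
#' Keeps, for every gene, its `per_gene_k` highest-TOM partners, plus the
#' globally largest `ceiling(global_quantile * n(n-1)/2)` unordered pairs.
#' Ties are broken by smaller row then smaller column index so the edge list
#' is deterministic; each unordered pair appears once.
#'
#' @param tom symmetric TOM matrix.
#' @param per_gene_k neighbors kept per gene (must be < number of genes).
#' @param global_quantile global fraction of pairs kept.
#' @return data.frame of class `sparse_network` with columns `gene_i`,
#'   `gene_j` (lexicographically `gene_i < gene_j` by matrix order) and
#'   `tom`, sorted by decreasing weight then indices.
#' @export
sparsify <- function(tom, per_gene_k = 4, global_quantile = 0.01) {
  assert_symmetric(tom, "tom")
  n <- nrow(tom)
  if (per_gene_k >= n)
    stop(sprintf("parameter error: per_gene_k = %d but only %d genes", per_gene_k, n),
         call. = FALSE)
  genes <- rownames(tom) %||% as.character(seq_len(n))
  W <- tom
  diag(W) <- -Inf

  # per-gene top-k partners (ties -> smaller partner index first)
  sel_i <- integer(0); sel_j <- integer(0)
  for (i in seq_len(n)) {
    ord <- order(-W[i, ], seq_len(n))[seq_len(per_gene_k)]
    sel_i <- c(sel_i, rep.int(i, per_gene_k)); sel_j <- c(sel_j, ord)
  }
  a <- pmin(sel_i, sel_j); b <- pmax(sel_i, sel_j)
  per_gene_keys <- unique(a * (n + 1) + b)

  # global top quantile over all off-diagonal unordered pairs
  iu <- which(upper.tri(W))
  m_top <- as.integer(ceiling(global_quantile * n * (n - 1) / 2))
  ri <- ((iu - 1L) %% n) + 1L
  ci <- ((iu - 1L) %/% n) + 1L
  ord <- order(-W[iu], ri, ci)[seq_len(min(m_top, length(iu)))]
  global_keys <- ri[ord] * (n + 1) + ci[ord]

  keys <- sort(unique(c(per_gene_keys, global_keys)))
  ii <- keys %/% (n + 1); jj <- keys %% (n + 1)
  out <- data.frame(gene_i = genes[ii], gene_j = genes[jj],
                    tom = tom[cbind(ii, jj)], stringsAsFactors = FALSE)
  out <- out[order(-out$tom, ii, jj), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sparse_network", class(out))
  out
}

#' Read a TF family assignment rules table
#'
#' Tab-delimited with header `family`, `required`, `forbidden`; the domain
#' columns hold semicolon-separated PFAM accessions (forbidden may be
#' empty). Rules are applied in table order by [classify_tfs()].
#'
#' @param path path to the rules TSV.
#' @return data.frame with columns `family`, `required`, `forbidden`.
#' @export
read_tf_rules <- function(path) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("family", "required", "forbidden")
  if (!all(req %in% names(rules)))
    stop(sprintf("malformed rules table '%s': header must contain %s",
                 path, paste(req, collapse = ", ")), call. = FALSE)
  bad <- which(rules$family == "" | rules$required == "")
  if (length(bad))
    stop(sprintf("malformed rules row at line %d: empty family or required domains",
                 bad[1L] + 1L), call. = FALSE)
  rules[req]
}

#' The TF family rules shipped with the package
#'
#' A small configurable subset of the Plant Transcription Factor Database
#' style assignment rules (MYB, bHLH, NAC, TIFY, YABBY, TCP, HB, MADS), not
#' a redistribution of the full database.
#'
#' @return rules data.frame, see [read_tf_rules()].
#' @export
default_tf_rules <- function() {
  read_tf_rules(system.file("extdata", "tf_family_rules.tsv",
                            package = "spadix", mustWork = TRUE))
}

#' Assign TF families from PFAM domain annotations
#'
#' A gene is assigned the FIRST rule (in table order) whose required domains
#' are all present and whose forbidden domains are all absent; genes
#' matching no rule get `NA`.
#'
#' @param gene_domains named list (gene -> character vector of PFAM
#'   accessions) or an annotation data.frame with `gene_id` and
#'   semicolon-separated `pfam_domains`.
#' @param rules rules table from [read_tf_rules()].
#' @return named character vector, gene -> family (NA when no rule fires).
#' @export
classify_tfs <- function(gene_domains, rules = default_tf_rules()) {
  if (is.data.frame(gene_domains)) {
    doms <- strsplit(gene_domains$pfam_domains, ";", fixed = TRUE)
    doms <- lapply(doms, function(d) d[nzchar(d)])
    names(doms) <- gene_domains$gene_id
    gene_domains <- doms
  }
  req <- strsplit(rules$required, ";", fixed = TRUE)
  forb <- strsplit(rules$forbidden, ";", fixed = TRUE)
  vapply(gene_domains, function(d) {
    for (r in seq_len(nrow(rules))) {
      if (all(req[[r]] %in% d) && !any(forb[[r]] %in% d))
        return(rules$family[r])
    }
    NA_character_
  }, "")
}

#' Top-k TF lists per pathway gene
#'
#' For each pathway gene, transcription factors ranked by decreasing TOM
#' (ties: gene identifier ascending) and truncated to `top_tf_k`. A gene
#' annotated as both pathway member and TF is excluded from its own
#' candidate pool.
#'
#' @param tom TOM matrix over the network genes.
#' @param pathway_genes character vector of pathway gene ids (subset of
#'   network genes).
#' @param tf_genes character vector of TF gene ids (subset of network
#'   genes); must be non-empty.
#' @param top_tf_k list length (default 10).
#' @return named list: pathway gene -> data.frame (`tf`, `tom`) in rank
#'   order.
#' @export
top_tf_lists <- function(tom, pathway_genes, tf_genes, top_tf_k = 10) {
  if (!length(tf_genes)) stop("empty TF set", call. = FALSE)
  missing_g <- setdiff(c(pathway_genes, tf_genes), rownames(tom))
  if (length(missing_g))
    stop(sprintf("genes absent from network: %s",
                 paste(utils::head(missing_g, 5), collapse = ", ")), call. = FALSE)
  out <- lapply(pathway_genes, function(g) {
    cand <- setdiff(tf_genes, g)
    w <- tom[g, cand]
    ord <- order(-w, cand)[seq_len(min(top_tf_k, length(cand)))]
    data.frame(tf = cand[ord], tom = unname(w[ord]), stringsAsFactors = FALSE)
  })
  stats::setNames(out, pathway_genes)
}

#' Retain TFs recurring across pathway-gene lists
#'
#' A transcription factor is retained when it appears in at least
#' `min_list_count` of the top-k lists; bipartite edges connect each
#' retained TF to every pathway gene whose list contains it.
#'
#' @param tf_lists output of [top_tf_lists()].
#' @param min_list_count minimum number of lists (default 2).
#' @return list of class `regulator_report`: `tf_lists`, `retained_tfs`
#'   (data.frame `tf`, `n_lists`), `bipartite_edges` (data.frame `tf`,
#'   `pathway_gene`, `tom`).
#' @export
mine_regulators <- function(tf_lists, min_list_count = 2) {
  all_edges <- do.call(rbind, lapply(names(tf_lists), function(g)
    cbind(tf_lists[[g]], pathway_gene = g, stringsAsFactors = FALSE)))
  if (is.null(all_edges))
    all_edges <- data.frame(tf = character(0), tom = numeric(0),
                            pathway_gene = character(0))
  counts <- table(all_edges$tf)
  retained <- sort(names(counts)[counts >= min_list_count])
  edges <- all_edges[all_edges$tf %in% retained,
                     c("tf", "pathway_gene", "tom"), drop = FALSE]
  edges <- edges[order(edges$tf, edges$pathway_gene), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    tf_lists = tf_lists,
    retained_tfs = data.frame(tf = retained,
                              n_lists = as.integer(counts[retained]),
                              stringsAsFactors = FALSE),
    bipartite_edges = edges
  ), class = "regulator_report")
}

#' Score mined regulators against the planted truth
#'
#' @param report a [mine_regulators()] report.
#' @param truth a `synthetic_truth`.
#' @return named numeric vector `c(precision =, recall =)`; precision is NaN
#'   (with a warning) when nothing was retained.
#' @export
evaluate_recovery <- function(report, truth) {
  planted <- unique(truth$planted_links$tf)
  retained <- report$retained_tfs$tf
  hit <- length(intersect(retained, planted))
  precision <- if (length(retained)) hit / length(retained) else {
    warning("empty retained set: precision undefined")
    NaN
  }
  recall <- if (length(planted)) hit / length(planted) else NaN
  c(precision = precision, recall = recall)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement by the standard contingency-table formula.
#'
#' @param a,b label vectors of equal length (any label type).
#' @return ARI (1 = identical partitions, ~0 = chance agreement).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length", call. = FALSE)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Module recovery score
#'
#' ARI between a detected module partition and the planted one, over all
#' genes (background label 0 is a class in both partitions).
#'
#' @param partition a `module_partition`.
#' @param truth a `synthetic_truth`.
#' @return adjusted Rand index.
#' @export
module_recovery <- function(partition, truth) {
  genes <- names(partition$module_of_gene)
  adjusted_rand_index(partition$module_of_gene[genes],
                      truth$module_of_gene[genes])
}
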