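#' Configure the multi-organ count simulator
#'
#' Builds a validated configuration for [generate_dataset()]. The generator
#' emulates a small organ-resolved RNA-seq experiment: negative-binomial
#' counts over a 4-organ x 3-replicate design, planted co-expression modules
#' driven by shared latent factors, organ-level mean shifts, library-size
#' variation, lognormal gene lengths, hard-zero organ-exclusive genes, and a
#' planted regulator-to-pathway-gene module used to score transcription
#' factor mining.
#'
#' For gene g in sample s the NB mean is
#' `L_g * 2^(b_g + e[m(g), organ(s)] + lambda_g * f[m(g), s]) * d_s`
#' with gene length `L_g`, log2 baseline `b_g`, module organ effect `e`,
#' loading `lambda_g`, standard-normal latent factor `f`, and depth
#' multiplier `d_s`; `var = mu + dispersion * mu^2`.
#'
#' When `n_planted_links > 0`, the linked transcription factors and linked
#' pathway genes are placed together in one extra "regulatory" module
#' (id `n_modules + 1`) so that regulators co-express with their targets,
#' the way flavonoid-pathway genes and their MYB/bHLH regulators do.
#'
#' @param n_genes total number of genes.
#' @param organs organ names; one sample group per organ.
#' @param reps_per_organ biological replicates per organ (>= 2).
#' @param n_modules number of planted background co-expression modules.
#' @param module_sizes integer vector of module sizes (length `n_modules`).
#' @param organ_effect organ-level expression bias of each module, on the
#'   log2 scale. A scalar `s` gives every module a random organ profile
#'   (standardized to mean 0 / sd 1 over organs) scaled by `s`, emulating the
#'   graded multi-organ module profiles seen in real tissue panels; 0
#'   disables organ bias. Alternatively a full modules x organs matrix of
#'   explicit log2 shifts (rows beyond `n_modules` apply to the regulatory
#'   module).
#' @param factor_loading_range interval for per-gene loadings `lambda_g`.
#' @param dispersion NB dispersion `phi` (> 0), `var = mu + phi mu^2`.
#' @param depth_range interval for per-sample library-depth multipliers.
#' @param length_logmean,length_logsd lognormal gene-length parameters (bp).
#' @param baseline_logmean,baseline_logsd normal parameters of the per-gene
#'   log2 baseline `b_g`.
#' @param n_tfs genes annotated as transcription factors.
#' @param n_pathway_genes genes tagged as pathway ("flavonoid") members.
#' @param n_planted_links number of regulator-to-target links; requires
#'   `n_planted_links <= min(n_tfs, n_pathway_genes)`.
#' @param n_organ_specific genes expressed exclusively in one organ (counts
#'   forced to exactly zero elsewhere).
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              organs = c("root", "leaf", "spathe", "spadix"),
                              reps_per_organ = 3,
                              n_modules = 5,
                              module_sizes = rep(100L, n_modules),
                              organ_effect = 0,
                              factor_loading_range = c(0.7, 1.0),
                              dispersion = 0.1,
                              depth_range = c(0.5, 1.5),
                              length_logmean = log(1500),
                              length_logsd = 0.6,
                              baseline_logmean = -3,
                              baseline_logsd = 1,
                              n_tfs = 20,
                              n_pathway_genes = 10,
                              n_planted_links = 10,
                              n_organ_specific = 120,
                              seed = 1) {
  cfg <- list(
    n_genes = assert_count(n_genes, "n_genes", 1L),
    organs = as.character(organs),
    reps_per_organ = assert_count(reps_per_organ, "reps_per_organ", 2L),
    n_modules = assert_count(n_modules, "n_modules", 0L),
    module_sizes = vapply(module_sizes, assert_count, 1L, field = "module_sizes", min = 0L),
    organ_effect = organ_effect,
    factor_loading_range = assert_interval(factor_loading_range, "factor_loading_range", 0),
    dispersion = dispersion,
    depth_range = assert_interval(depth_range, "depth_range", 0),
    length_logmean = length_logmean,
    length_logsd = length_logsd,
    baseline_logmean = baseline_logmean,
    baseline_logsd = baseline_logsd,
    n_tfs = assert_count(n_tfs, "n_tfs"),
    n_pathway_genes = assert_count(n_pathway_genes, "n_pathway_genes"),
    n_planted_links = assert_count(n_planted_links, "n_planted_links"),
    n_organ_specific = assert_count(n_organ_specific, "n_organ_specific"),
    seed = assert_count(seed, "seed")
  )
  if (length(cfg$organs) < 1L) config_error("organs", "must name at least one organ")
  if (length(cfg$module_sizes) != cfg$n_modules)
    config_error("module_sizes", "must have length n_modules")
  if (!is.numeric(cfg$dispersion) || length(cfg$dispersion) != 1L || cfg$dispersion <= 0)
    config_error("dispersion", "must be a single value > 0")
  if (cfg$n_planted_links > min(cfg$n_tfs, cfg$n_pathway_genes))
    config_error("n_planted_links", "cannot exceed min(n_tfs, n_pathway_genes)")
  reserved <- sum(cfg$module_sizes) + cfg$n_tfs + cfg$n_pathway_genes + cfg$n_organ_specific
  if (reserved > cfg$n_genes)
    config_error("n_genes", sprintf(
      "too small: modules + TFs + pathway genes + organ-specific genes need %d genes", reserved))
  n_mod_total <- cfg$n_modules + (cfg$n_planted_links > 0L)
  if (is.matrix(cfg$organ_effect)) {
    if (nrow(cfg$organ_effect) < n_mod_total || ncol(cfg$organ_effect) != length(cfg$organs))
      config_error("organ_effect", "matrix must be (n_modules [+1]) x n_organs")
  } else if (!is.numeric(cfg$organ_effect) || length(cfg$organ_effect) != 1L) {
    config_error("organ_effect", "must be a scalar log2 shift or a module x organ matrix")
  }
  class(cfg) <- "simulation_config"
  cfg
}

# Scalar organ_effect s draws one random organ profile per module,
# standardized to mean 0 / sd 1 over organs, scaled by s. Must be called
# after set.seed() inside generate_dataset.
organ_effect_matrix <- function(cfg, n_mod_total) {
  K <- length(cfg$organs)
  if (is.matrix(cfg$organ_effect))
    return(cfg$organ_effect[seq_len(n_mod_total), , drop = FALSE])
  if (n_mod_total == 0 || cfg$organ_effect == 0 || K < 2)
    return(matrix(0, n_mod_total, K))
  z <- t(scale(t(matrix(stats::rnorm(n_mod_total * K), n_mod_total, K))))
  attributes(z)[c("scaled:center", "scaled:scale")] <- NULL
  cfg$organ_effect * z
}

#' Generate a synthetic multi-organ expression study with known truth
#'
#' Draws a count matrix from the model described in [simulation_config()] and
#' returns it together with the planted ground truth used by the recovery
#' scorers ([module_recovery()], [evaluate_recovery()]).
#'
#' @param config a `simulation_config`.
#' @return A list with elements `study` (an [expression_study()]) and `truth`
#'   (class `synthetic_truth`: `module_of_gene` (0 = background),
#'   `tf_genes`, `pathway_genes`, `planted_links` (data.frame `tf`,
#'   `pathway_gene`), `organ_specific_genes` (named organ vector),
#'   `latent_factors` (module x sample), `loadings`).
#' @examples
#' sim <- generate_dataset(simulation_config(n_genes = 300, module_sizes = rep(40, 5)))
#' sim$study
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  set.seed(config$seed)
  K <- length(config$organs)
  n_samples <- K * config$reps_per_organ
  sample_organ <- rep(config$organs, each = config$reps_per_organ)
  design <- data.frame(
    sample_id = paste(sample_organ, rep(seq_len(config$reps_per_organ), K), sep = "_"),
    organ = sample_organ,
    replicate = rep(seq_len(config$reps_per_organ), K),
    stringsAsFactors = FALSE
  )
  n <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))

  has_reg <- config$n_planted_links > 0L
  n_mod_total <- config$n_modules + has_reg
  module <- integer(n)
  cursor <- 0L
  for (m in seq_len(config$n_modules)) {
    sz <- config$module_sizes[m]
    module[cursor + seq_len(sz)] <- m
    cursor <- cursor + sz
  }
  # TFs then pathway genes immediately after the background modules; the
  # first n_planted_links of each are co-assigned to the regulatory module.
  tf_idx <- cursor + seq_len(config$n_tfs)
  cursor <- cursor + config$n_tfs
  pw_idx <- cursor + seq_len(config$n_pathway_genes)
  cursor <- cursor + config$n_pathway_genes
  if (has_reg) {
    linked_tf <- tf_idx[seq_len(config$n_planted_links)]
    linked_pw <- pw_idx[seq_len(config$n_planted_links)]
    module[c(linked_tf, linked_pw)] <- config$n_modules + 1L
  } else {
    linked_tf <- linked_pw <- integer(0)
  }
  os_idx <- if (config$n_organ_specific > 0L) cursor + seq_len(config$n_organ_specific) else integer(0)
  os_organ <- if (length(os_idx)) config$organs[((seq_along(os_idx) - 1L) %% K) + 1L] else character(0)

  E <- organ_effect_matrix(config, n_mod_total)
  # Latent factors are standardized to empirical mean 0 / variance 1 across
  # the samples, so a module's common-signal strength is exactly lambda_g^2
  # and does not depend on the 12-draw realization lottery.
  FF <- if (n_mod_total > 0) {
    f <- matrix(stats::rnorm(n_mod_total * n_samples), n_mod_total, n_samples)
    f <- t(scale(t(f)))
    attributes(f)[c("scaled:center", "scaled:scale")] <- NULL
    dimnames(f) <- list(seq_len(n_mod_total), design$sample_id)
    f
  } else {
    matrix(0, 0, n_samples, dimnames = list(NULL, design$sample_id))
  }

  lambda <- numeric(n)
  in_mod <- module > 0L
  lambda[in_mod] <- stats::runif(sum(in_mod),
                                 config$factor_loading_range[1],
                                 config$factor_loading_range[2])
  lengths <- pmax(200, round(stats::rlnorm(n, config$length_logmean, config$length_logsd)))
  baseline <- stats::rnorm(n, config$baseline_logmean, config$baseline_logsd)
  depth <- stats::runif(n_samples, config$depth_range[1], config$depth_range[2])

  log2mu <- matrix(baseline, n, n_samples)
  organ_of_sample <- match(design$organ, config$organs)
  if (any(in_mod)) {
    m <- module[in_mod]
    log2mu[in_mod, ] <- log2mu[in_mod, , drop = FALSE] +
      E[m, organ_of_sample, drop = FALSE] +
      lambda[in_mod] * FF[m, , drop = FALSE]
  }
  mu <- lengths * 2^log2mu
  mu <- sweep(mu, 2, depth, `*`)
  if (length(os_idx)) {
    off <- outer(os_organ, design$organ, `!=`)
    mu[os_idx, ][off] <- 0
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                   n, n_samples, dimnames = list(gene_ids, design$sample_id))
  counts[mu == 0] <- 0L
  storage.mode(counts) <- "integer"

  truth <- structure(list(
    module_of_gene = stats::setNames(module, gene_ids),
    tf_genes = gene_ids[tf_idx],
    pathway_genes = gene_ids[pw_idx],
    planted_links = data.frame(tf = gene_ids[linked_tf],
                               pathway_gene = gene_ids[linked_pw],
                               stringsAsFactors = FALSE),
    organ_specific_genes = stats::setNames(os_organ, gene_ids[os_idx]),
    latent_factors = FF,
    loadings = stats::setNames(lambda, gene_ids)
  ), class = "synthetic_truth")

  gene_length <- stats::setNames(as.numeric(lengths), gene_ids)
  list(study = expression_study(counts, gene_length, design), truth = truth)
}

#' Write / read planted ground truth as JSON
#'
#' Round-trips a `synthetic_truth` object losslessly through a plain-text
#' JSON file.
#'
#' @param truth a `synthetic_truth`.
#' @param path output file path.
#' @return `write_truth` invisibly returns `path`; `read_truth` returns the
#'   reconstructed `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    module_of_gene = as.list(truth$module_of_gene),
    tf_genes = truth$tf_genes,
    pathway_genes = truth$pathway_genes,
    planted_links = truth$planted_links,
    organ_specific_genes = as.list(truth$organ_specific_genes),
    latent_factors = list(
      rownames = rownames(truth$latent_factors),
      colnames = colnames(truth$latent_factors),
      values = truth$latent_factors
    ),
    loadings = as.list(truth$loadings)
  )
  ok <- tryCatch({
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write truth to '%s': %s", path, conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lf <- obj$latent_factors$values
  if (is.null(lf)) lf <- matrix(0, 0, 0)
  if (!is.matrix(lf)) lf <- matrix(lf, nrow = length(obj$latent_factors$rownames))
  dimnames(lf) <- list(obj$latent_factors$rownames, obj$latent_factors$colnames)
  links <- obj$planted_links
  if (length(links) == 0L)
    links <- data.frame(tf = character(0), pathway_gene = character(0))
  structure(list(
    module_of_gene = vapply(obj$module_of_gene, as.integer, 1L),
    tf_genes = as.character(obj$tf_genes),
    pathway_genes = as.character(obj$pathway_genes),
    planted_links = as.data.frame(links, stringsAsFactors = FALSE),
    organ_specific_genes = vapply(obj$organ_specific_genes, as.character, ""),
    latent_factors = lf,
    loadings = vapply(obj$loadings, as.numeric, 1)
  ), class = "synthetic_truth")
}

#' Build a gene annotation table from the planted truth
#'
#' Produces the `genes.tsv`-style annotation the pipeline consumes: lengths,
#' pathway tags ("flavonoid" for planted pathway genes) and PFAM domains.
#' Each transcription factor gene receives the required domain of one family
#' from `rules` (cycling through the table), so that [classify_tfs()] applied
#' to the annotation recovers exactly the planted TF set.
#'
#' @param truth a `synthetic_truth`.
#' @param study the matching `expression_study` (source of gene lengths).
#' @param rules TF family assignment rules, see [read_tf_rules()]; defaults
#'   to the table shipped with the package.
#' @return data.frame with columns `gene_id`, `length_bp`, `pathway_tags`,
#'   `pfam_domains` (semicolon-separated).
#' @export
make_annotation <- function(truth, study, rules = default_tf_rules()) {
  gene_ids <- names(truth$module_of_gene)
  ann <- data.frame(
    gene_id = gene_ids,
    length_bp = as.integer(study$gene_length[gene_ids]),
    pathway_tags = "",
    pfam_domains = "",
    stringsAsFactors = FALSE
  )
  ann$pathway_tags[ann$gene_id %in% truth$pathway_genes] <- "flavonoid"
  if (length(truth$tf_genes)) {
    fam_i <- ((seq_along(truth$tf_genes) - 1L) %% nrow(rules)) + 1L
    req <- vapply(strsplit(rules$required[fam_i], ";", fixed = TRUE),
                  function(d) paste(d, collapse = ";"), "")
    ann$pfam_domains[match(truth$tf_genes, ann$gene_id)] <- req
  }
  ann
}
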