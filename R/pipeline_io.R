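#' Read the pipeline's tabular inputs
#'
#' Tab-delimited, UTF-8, header row required. `read_counts` expects
#' `gene_id` plus one integer column per sample; `read_samples` expects
#' `sample_id`, `organ`, `replicate`; `read_genes` expects `gene_id`,
#' `length_bp` and optional `pathway_tags`, `pfam_domains`.
#'
#' @param path file path.
#' @return `read_counts`: integer matrix with gene rownames;
#'   `read_samples` / `read_genes`: data.frame.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df))
    stop(sprintf("'%s': missing gene_id column", path), call. = FALSE)
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @export
read_samples <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_counts
#' @export
read_genes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in intersect(c("pathway_tags", "pfam_domains"), names(df))) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Write an expression study and annotation to TSV files
#'
#' Emits `counts.tsv`, `samples.tsv` and `genes.tsv` in the pipeline's
#' exchange format, plus `truth.json` when a truth object is supplied.
#'
#' @param study an [expression_study()].
#' @param dir output directory (created if needed).
#' @param truth optional `synthetic_truth` (also writes the annotation from
#'   [make_annotation()] into `genes.tsv`).
#' @return named character vector of file paths.
#' @export
write_study <- function(study, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             genes = file.path(dir, "genes.tsv"))
  write_matrix_tsv(study$counts, paths["counts"])
  write_tsv(study$design, paths["samples"])
  genes <- if (is.null(truth)) {
    data.frame(gene_id = rownames(study$counts),
               length_bp = as.integer(study$gene_length),
               pathway_tags = "", pfam_domains = "", stringsAsFactors = FALSE)
  } else {
    make_annotation(truth, study)
  }
  write_tsv(genes, paths["genes"])
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    write_truth(truth, paths["truth"])
  }
  paths
}

#' Load an expression study from TSV files
#'
#' @param counts_path,samples_path,genes_path paths to the three input
#'   tables.
#' @return list with `study` (an [expression_study()]) and `annotation`
#'   (the genes table).
#' @export
read_study <- function(counts_path, samples_path, genes_path) {
  counts <- read_counts(counts_path)
  samples <- read_samples(samples_path)
  genes <- read_genes(genes_path)
  gl <- stats::setNames(as.numeric(genes$length_bp), genes$gene_id)
  list(study = expression_study(counts, gl, samples), annotation = genes)
}

#' Validate pipeline input files
#'
#' Checks headers, sample-sheet/counts column agreement, integer
#' non-negative counts and positive lengths. Failures are reported, not
#' thrown.
#'
#' @param counts_path,samples_path,genes_path input file paths.
#' @return list of class `validation_report`: `ok` (logical) and `failures`
#'   (character vector of itemized problems).
#' @export
validate_inputs <- function(counts_path, samples_path, genes_path) {
  failures <- character(0)
  note <- function(msg) failures <<- c(failures, msg)
  for (p in c(counts_path, samples_path, genes_path))
    if (!file.exists(p)) note(sprintf("missing file: %s", p))
  if (!length(failures)) {
    cdf <- utils::read.delim(counts_path, stringsAsFactors = FALSE, check.names = FALSE)
    sdf <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
    gdf <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
    if (!"gene_id" %in% names(cdf)) note("counts.tsv: missing gene_id header")
    if (!all(c("sample_id", "organ", "replicate") %in% names(sdf)))
      note("samples.tsv: header must contain sample_id, organ, replicate")
    if (!all(c("gene_id", "length_bp") %in% names(gdf)))
      note("genes.tsv: header must contain gene_id, length_bp")
    if ("gene_id" %in% names(cdf)) {
      samp_cols <- setdiff(names(cdf), "gene_id")
      missing_s <- setdiff(samp_cols, sdf$sample_id)
      for (s in missing_s) note(sprintf("sample '%s' absent from sample sheet", s))
      m <- as.matrix(cdf[samp_cols])
      bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
      if (nrow(bad))
        note(sprintf("invalid count at gene '%s', sample '%s'",
                     cdf$gene_id[bad[1, 1]], samp_cols[bad[1, 2]]))
    }
    if ("length_bp" %in% names(gdf) && any(gdf$length_bp <= 0))
      note(sprintf("non-positive length for gene '%s'",
                   gdf$gene_id[which(gdf$length_bp <= 0)[1]]))
  }
  structure(list(ok = !length(failures), failures = failures),
            class = "validation_report")
}

#' Read a pipeline configuration file
#'
#' YAML (if the `yaml` package is installed) or JSON, holding input paths
#' and stage parameters; missing parameters fall back to the documented
#' defaults.
#'
#' @param path config file path.
#' @return named list of settings.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs; use JSON instead", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run the full pipeline
#'
#' Executes normalize -> differential expression -> organ atlas -> network
#' -> modules -> sparsify -> mine from a configuration list, writing every
#' stage table plus a JSON manifest (input hashes, parameters, seed, output
#' hashes). Reruns with the same config reproduce identical outputs.
#'
#' @param config named list (or path handled by [read_pipeline_config()])
#'   with `counts`, `samples`, `genes` (and optionally `rules`) input paths,
#'   `out_dir`, `seed`, and optional stage parameters `alpha`, `lfc`,
#'   `n_perm`, `asymptotic`, `n_gene_clusters`, `beta`, `max_block_size`,
#'   `min_module_size`, `deep_split`, `merge_cut_height`, `per_gene_k`,
#'   `global_quantile`, `top_tf_k`, `min_list_count`.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  for (f in c("counts", "samples", "genes")) {
    if (is.null(config[[f]])) stop(sprintf("config missing input path '%s'", f), call. = FALSE)
    if (!file.exists(config[[f]]))
      stop(sprintf("missing input file for '%s': %s", f, config[[f]]), call. = FALSE)
  }
  out_dir <- config$out_dir %||% "pipeline_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  rules <- if (!is.null(config$rules)) read_tf_rules(config$rules) else default_tf_rules()

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE))
  }

  inp <- run_stage("input", read_study(config$counts, config$samples, config$genes))
  study <- inp$study
  norm <- run_stage("normalize", normalize_study(study))
  outputs <- character(0)
  emit <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    outputs <<- c(outputs, stats::setNames(p, name))
  }
  emit("tmm_factors.tsv", function(p) write_tsv(
    data.frame(sample_id = names(norm$tmm_factor), tmm_factor = norm$tmm_factor,
               effective_libsize = norm$effective_libsize), p))
  emit("fpkm.tsv", function(p) write_matrix_tsv(norm$fpkm, p))
  emit("log_cpm.tsv", function(p) write_matrix_tsv(norm$log_cpm, p))

  de <- run_stage("differential_expression", de_table(
    norm, study$design,
    alpha = config$alpha %||% 0.05, lfc = config$lfc %||% 1.5,
    n_perm = config$n_perm %||% 1000, seed = seed,
    asymptotic = isTRUE(config$asymptotic)))
  emit("de_table.tsv", function(p) write_tsv(de, p))
  de_genes <- de_call(de, config$alpha %||% 0.05, config$lfc %||% 1.5)

  presence <- run_stage("atlas", presence_call(norm$fpkm, study$design))
  emit("presence.tsv", function(p) write_tsv(presence, p))
  emit("venn.tsv", function(p) write_tsv(venn_partition(presence), p))
  excl <- exclusive_sets(presence)
  for (o in names(excl)) {
    local({
      oo <- o
      emit(sprintf("exclusive_%s.txt", oo), function(p)
        writeLines(excl[[oo]], p))
    })
  }
  emit("sample_dendrogram.nwk", function(p)
    writeLines(as_newick(sample_dendrogram(norm$log_fpkm)), p))
  cl_mat <- norm$centered[de_genes, , drop = FALSE]
  if (nrow(cl_mat) >= 2L) {
    clusters <- run_stage("atlas", gene_clusters(cl_mat, k = config$n_gene_clusters %||% 6))
    emit("gene_clusters.tsv", function(p) write_tsv(
      data.frame(gene_id = names(clusters$assignment), cluster = clusters$assignment), p))
    emit("cluster_profiles.tsv", function(p) write_matrix_tsv(clusters$profiles, p, "cluster"))
  }

  net_cfg <- network_config(
    beta = config$beta %||% 20,
    max_block_size = config$max_block_size %||% 11000,
    min_module_size = config$min_module_size %||% 30,
    deep_split = config$deep_split %||% 2,
    merge_cut_height = config$merge_cut_height %||% 0.2)
  net_genes <- if (length(de_genes) >= 3L) de_genes else rownames(study$counts)
  net <- run_stage("network", build_network(norm$log_fpkm[net_genes, , drop = FALSE], net_cfg))
  part <- run_stage("modules", detect_modules(net$diss_tom, net_cfg))
  merged <- if (any(part$module_of_gene > 0L))
    run_stage("modules", merge_modules(norm$log_fpkm[net_genes, , drop = FALSE],
                                       part$module_of_gene, net_cfg$merge_cut_height))
  else part
  emit("modules.tsv", function(p) write_tsv(
    data.frame(gene_id = names(merged$module_of_gene),
               module_id = merged$module_of_gene), p))
  if (!is.null(merged$eigengenes))
    emit("eigengenes.tsv", function(p) write_matrix_tsv(merged$eigengenes, p, "module"))
  emit("tom_dendrogram.nwk", function(p) writeLines(as_newick(part$tree), p))

  mine_cfg <- mining_config(
    per_gene_k = config$per_gene_k %||% 4,
    global_quantile = config$global_quantile %||% 0.01,
    top_tf_k = config$top_tf_k %||% 10,
    min_list_count = config$min_list_count %||% 2)
  edges <- run_stage("sparsify", sparsify(net$tom, mine_cfg$per_gene_k,
                                          mine_cfg$global_quantile))
  emit("edges.tsv", function(p) write_tsv(edges, p))
  emit("edges.sif", function(p) writeLines(
    sprintf("%s\tco\t%s", edges$gene_i, edges$gene_j), p))

  families <- classify_tfs(inp$annotation, rules)
  tf_genes <- names(families)[!is.na(families)]
  emit("tf_families.tsv", function(p) write_tsv(
    data.frame(gene_id = names(families), family = families)[!is.na(families), ], p))
  pathway_genes <- inp$annotation$gene_id[
    grepl("flavonoid", inp$annotation$pathway_tags %||% "")]
  tf_in <- intersect(tf_genes, net$genes)
  pw_in <- intersect(pathway_genes, net$genes)
  if (length(tf_in) && length(pw_in)) {
    lists <- run_stage("mine", top_tf_lists(net$tom, pw_in, tf_in, mine_cfg$top_tf_k))
    report <- mine_regulators(lists, mine_cfg$min_list_count)
    emit("regulators.tsv", function(p) {
      ret <- report$retained_tfs
      ret$family <- families[ret$tf]
      ret$pathway_genes <- vapply(ret$tf, function(t)
        paste(sort(report$bipartite_edges$pathway_gene[report$bipartite_edges$tf == t]),
              collapse = ";"), "")
      write_tsv(ret[, c("tf", "family", "n_lists", "pathway_genes")], p)
    })
    emit("bipartite_edges.tsv", function(p) write_tsv(report$bipartite_edges, p))
  }

  manifest <- list(
    inputs = as.list(tools::md5sum(c(config$counts, config$samples, config$genes))),
    parameters = list(
      seed = seed, alpha = config$alpha %||% 0.05, lfc = config$lfc %||% 1.5,
      n_perm = config$n_perm %||% 1000, asymptotic = isTRUE(config$asymptotic),
      beta = net_cfg$beta, min_module_size = net_cfg$min_module_size,
      deep_split = net_cfg$deep_split, merge_cut_height = net_cfg$merge_cut_height,
      max_block_size = net_cfg$max_block_size,
      per_gene_k = mine_cfg$per_gene_k, global_quantile = mine_cfg$global_quantile,
      top_tf_k = mine_cfg$top_tf_k, min_list_count = mine_cfg$min_list_count),
    n_de_genes = length(de_genes),
    outputs = as.list(tools::md5sum(unname(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
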