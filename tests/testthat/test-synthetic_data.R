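test_that("generation is deterministic under a fixed seed and seed-sensitive", {
  a <- quick_sim(seed = 7)
  b <- quick_sim(seed = 7)
  c <- quick_sim(seed = 8)
  expect_identical(a$study$counts, b$study$counts)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$study$counts, c$study$counts))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(simulation_config(reps_per_organ = 1), "reps_per_organ")
  expect_error(simulation_config(dispersion = 0), "dispersion")
  expect_error(simulation_config(n_genes = 50), "n_genes")
  expect_error(simulation_config(module_sizes = c(10, 10)), "module_sizes")
  expect_error(simulation_config(n_planted_links = 50, n_tfs = 5), "n_planted_links")
  expect_error(simulation_config(depth_range = c(2, 1)), "depth_range")
})

test_that("null configuration shows no organ bias, shrinking with replicates", {
  null_cfg <- function(reps) simulation_config(
    n_genes = 400, n_modules = 0, module_sizes = integer(0),
    factor_loading_range = c(0, 0), depth_range = c(1, 1),
    n_tfs = 0, n_pathway_genes = 0, n_planted_links = 0,
    n_organ_specific = 0, reps_per_organ = reps, seed = 11)
  gap <- vapply(c(3L, 24L), function(reps) {
    sim <- generate_dataset(null_cfg(reps))
    lab <- organ_labels(sim$study)
    means <- t(apply(sim$study$counts, 1, function(x) tapply(x, lab, mean)))
    rel <- (apply(means, 1, max) - apply(means, 1, min)) / rowMeans(means)
    mean(rel)
  }, 1)
  expect_lt(gap[2], gap[1])     # organ gap is sampling noise only
  expect_lt(gap[2], 0.5)
})

test_that("organ-specific genes are exactly zero outside their organ", {
  sim <- quick_sim(seed = 3)
  lab <- organ_labels(sim$study)
  for (g in names(sim$truth$organ_specific_genes)) {
    home <- sim$truth$organ_specific_genes[[g]]
    expect_true(all(sim$study$counts[g, lab != home] == 0L))
    expect_gt(sum(sim$study$counts[g, lab == home]), 0L)
  }
})

test_that("truth round-trips losslessly through JSON", {
  sim <- quick_sim(seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$module_of_gene, sim$truth$module_of_gene)
  expect_equal(back$tf_genes, sim$truth$tf_genes)
  expect_equal(back$pathway_genes, sim$truth$pathway_genes)
  expect_equal(back$planted_links, sim$truth$planted_links)
  expect_equal(back$organ_specific_genes, sim$truth$organ_specific_genes)
  expect_equal(back$latent_factors, sim$truth$latent_factors)
  expect_equal(back$loadings, sim$truth$loadings, tolerance = 1e-12)
  expect_error(suppressWarnings(write_truth(sim$truth, "/nonexistent-dir/truth.json")),
               "cannot write")
})

test_that("annotation tags pathway genes and gives TFs rule-matching domains", {
  sim <- quick_sim(seed = 2)
  ann <- make_annotation(sim$truth, sim$study)
  fam <- classify_tfs(ann)
  expect_setequal(names(fam)[!is.na(fam)], sim$truth$tf_genes)
  expect_setequal(ann$gene_id[ann$pathway_tags == "flavonoid"], sim$truth$pathway_genes)
  expect_equal(ann$length_bp, as.integer(sim$study$gene_length[ann$gene_id]))
})

test_that("planted links connect TFs and pathway genes in a shared module", {
  sim <- quick_sim(seed = 4)
  links <- sim$truth$planted_links
  expect_true(all(links$tf %in% sim$truth$tf_genes))
  expect_true(all(links$pathway_gene %in% sim$truth$pathway_genes))
  expect_length(intersect(sim$truth$tf_genes, sim$truth$pathway_genes), 0)
  mods <- sim$truth$module_of_gene[c(links$tf, links$pathway_gene)]
  expect_length(unique(mods), 1L)
  expect_gt(unique(mods), 0L)
})

test_that("within-module correlation exceeds between-module correlation", {
  sim <- generate_dataset(simulation_config(
    n_genes = 300, n_modules = 3, module_sizes = rep(50, 3),
    factor_loading_range = c(0.5, 1.0), n_tfs = 0, n_pathway_genes = 0,
    n_planted_links = 0, n_organ_specific = 0, seed = 9))
  lc <- log_cpm(sim$study$counts, colSums(sim$study$counts))
  cc <- cor(t(lc[sim$truth$module_of_gene > 0, ]))
  same <- outer(sim$truth$module_of_gene[rownames(cc)],
                sim$truth$module_of_gene[colnames(cc)], `==`)
  diag(same) <- NA
  expect_gt(mean(cc[same & !is.na(same)]), mean(cc[!same & !is.na(same)]))
})

test_that("counts follow the NB mean-variance law var = mu + phi mu^2", {
  phi <- 0.2
  sim <- generate_dataset(simulation_config(
    n_genes = 60, organs = "root", reps_per_organ = 600,
    n_modules = 0, module_sizes = integer(0), dispersion = phi,
    depth_range = c(1, 1), length_logmean = log(400), length_logsd = 0.3,
    baseline_logmean = -4, baseline_logsd = 0.5,
    n_tfs = 0, n_pathway_genes = 0, n_planted_links = 0,
    n_organ_specific = 0, seed = 21))
  n <- ncol(sim$study$counts)
  ok <- apply(sim$study$counts, 1, function(x) {
    mu <- mean(x)
    v_expect <- mu + phi * mu^2
    # MC tolerance from the theoretical sampling sd of s^2 under NB(mu, phi)
    size <- 1 / phi
    supp <- 0:max(qnbinom(1 - 1e-12, mu = mu, size = size), 10)
    p <- dnbinom(supp, mu = mu, size = size)
    mu4 <- sum(p * (supp - mu)^4)
    se <- sqrt((mu4 - v_expect^2 * (n - 3) / (n - 1)) / n)
    abs(var(x) - v_expect) < 3 * se
  })
  expect_gt(mean(ok), 0.95)     # ~3-sigma band: a few misses allowed
})
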