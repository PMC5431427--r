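make_presence <- function(fpkm_by_organ) {
  # fpkm_by_organ: gene x (organ x 3 reps) matrix built from per-organ triples
  organs <- c("root", "leaf", "spathe", "spadix")
  design <- data.frame(sample_id = colnames(fpkm_by_organ),
                       organ = rep(organs, each = 3), replicate = rep(1:3, 4))
  presence_call(fpkm_by_organ, design)
}

organ_fpkm <- function(...) {
  # each argument: one gene's 4 organ triples, in organ order
  rows <- list(...)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(paste0("g", seq_along(rows)),
                      paste(rep(c("root", "leaf", "spathe", "spadix"), each = 3),
                            rep(1:3, 4), sep = "_"))
  m
}

test_that("presence rules: expressed >= 1, absent = 0, else indeterminate", {
  fpkm <- organ_fpkm(c(0, 0, 0, 0.2, 1.3, 0, 0.4, 0.2, 0, 5, 5, 5))
  pc <- make_presence(fpkm)
  status <- setNames(pc$status, pc$organ)
  expect_equal(unname(status[c("root", "leaf", "spathe", "spadix")]),
               c("absent", "expressed", "indeterminate", "expressed"))
  expect_equal(sort(unique(pc$max_fpkm)), c(0, 0.4, 1.3, 5))
  bad_design <- data.frame(sample_id = colnames(fpkm),
                           organ = rep(c("root", "leaf", "spathe", "spadix"), each = 3),
                           replicate = rep(1:3, 4))
  bad_design$organ[bad_design$organ == "leaf"] <- "root"
  expect_error(presence_call(fpkm, rbind(bad_design,
                                         data.frame(sample_id = "x", organ = "leaf",
                                                    replicate = 1))), "no samples")
})

test_that("Venn partition counts match exhaustive enumeration", {
  fpkm <- organ_fpkm(
    c(2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),       # root only
    c(3, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),       # root only
    c(2, 0, 0, 1, 1, 1, 0, 0, 0, 0, 0, 0),       # root + leaf
    c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4),       # all four
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),       # nowhere
    c(0.5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))     # indeterminate only
  pc <- make_presence(fpkm)
  venn <- venn_partition(pc)
  expect_equal(nrow(venn), 15L)
  expect_equal(venn$count[venn$region == "root"], 2L)
  expect_equal(venn$count[venn$region == "root+leaf"], 1L)
  expect_equal(venn$count[venn$region == "root+leaf+spathe+spadix"], 1L)
  expect_equal(sum(venn$count), 4L)   # genes expressed somewhere only
})

test_that("Venn regions are disjoint and exhaustive on random presence data", {
  set.seed(30)
  fpkm <- matrix(sample(c(0, 0.5, 3), 50 * 12, replace = TRUE), 50, 12,
                 dimnames = list(paste0("g", 1:50),
                                 paste(rep(c("root", "leaf", "spathe", "spadix"), each = 3),
                                       rep(1:3, 4), sep = "_")))
  pc <- make_presence(fpkm)
  venn <- venn_partition(pc)
  expressed_somewhere <- unique(pc$gene_id[pc$status == "expressed"])
  expect_equal(sum(venn$count), length(expressed_somewhere))
})

test_that("exclusivity needs expression in one organ and absence in all others", {
  fpkm <- organ_fpkm(
    c(2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),       # root exclusive
    c(2, 0, 0, 0.4, 0, 0, 0, 0, 0, 0, 0, 0),     # blocked by indeterminate leaf
    c(2, 0, 0, 1.5, 0, 0, 0, 0, 0, 0, 0, 0))     # expressed twice
  excl <- exclusive_sets(make_presence(fpkm))
  expect_equal(excl$root, "g1")
  expect_equal(lengths(excl)[c("leaf", "spathe", "spadix")],
               c(leaf = 0L, spathe = 0L, spadix = 0L))
  # exclusive sets are a subset of the single-organ Venn region
  venn <- venn_partition(make_presence(fpkm))
  expect_lte(length(excl$root), venn$count[venn$region == "root"])
})

test_that("sample dendrogram merges identical columns first and serializes", {
  mat <- cbind(s1 = c(0, 0), s2 = c(0, 0), s3 = c(10, 10))
  hc <- sample_dendrogram(mat)
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$merge[1, ], c(-1L, -2L))   # first merge joins s1 and s2
  nwk <- as_newick(hc)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, c("s1", "s2", "s3"))
  expect_error(sample_dendrogram(cbind(c(NA, 1), c(1, 2))), "NA")
})

test_that("complete-linkage cophenetic distances dominate pairwise distances", {
  set.seed(31)
  mat <- matrix(rnorm(8 * 10), 10, 8, dimnames = list(NULL, paste0("s", 1:8)))
  hc <- sample_dendrogram(mat)
  expect_true(all(cophenetic(hc) >= dist(t(mat)) - 1e-12))
})

test_that("gene clusters partition all genes and profile matrix is per-cluster median", {
  set.seed(32)
  centered <- matrix(rnorm(40 * 6), 40, 6,
                     dimnames = list(paste0("g", 1:40), paste0("s", 1:6)))
  cl <- gene_clusters(centered, k = 4)
  expect_length(cl$assignment, 40)
  expect_equal(sort(unique(cl$assignment)), 1:4)
  for (k in 1:4)
    expect_equal(cl$profiles[as.character(k), ],
                 apply(centered[cl$assignment == k, , drop = FALSE], 2, median))
})

test_that("concordance R^2 matches hand computation and flags degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(expression_concordance(x, 2 * x + 1), 1)
  expect_equal(expression_concordance(x, -x), 1)
  expect_equal(expression_concordance(x, c(1, 2, 4)), 0.9643, tolerance = 1e-4)
  expect_error(expression_concordance(x, c(1, 1, 1)), "zero variance")
  expect_error(expression_concordance(1:2, 1:2), "length")
})
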