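test_that("sparsification saturates, de-duplicates, and keeps best edges", {
  tom3 <- matrix(c(1, .5, .4, .5, 1, .3, .4, .3, 1), 3, 3,
                 dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  net <- sparsify(tom3, per_gene_k = 2, global_quantile = 1)
  expect_equal(nrow(net), 3L)                    # complete graph, each pair once
  expect_equal(anyDuplicated(paste(net$gene_i, net$gene_j)), 0L)

  set.seed(50)
  tom <- random_tom(20)
  dimnames(tom) <- list(sprintf("g%02d", 1:20), sprintf("g%02d", 1:20))
  net <- sparsify(tom, per_gene_k = 1, global_quantile = 0.01)
  # every gene keeps its single best partner
  W <- tom; diag(W) <- -Inf
  for (i in 1:20) {
    best <- colnames(W)[which.max(W[i, ])]
    pair <- paste(sort(c(rownames(W)[i], best)), collapse = "|")
    expect_true(pair %in% paste(net$gene_i, net$gene_j, sep = "|"))
  }
  expect_error(sparsify(tom, per_gene_k = 20), "parameter error")
})

test_that("sparsified edge count respects the union bound", {
  set.seed(51)
  n <- 40; k <- 3; q <- 0.02
  m_top <- ceiling(q * n * (n - 1) / 2)
  for (i in 1:25) {
    tom <- random_tom(n)
    net <- sparsify(tom, per_gene_k = k, global_quantile = q)
    expect_gte(nrow(net), m_top)
    expect_lte(nrow(net), n * k + m_top)
  }
})

test_that("TF classification applies first-match rules with forbidden domains", {
  rules <- default_tf_rules()
  doms <- list(myb = "PF00249",
               blocked = c("PF00249", "PF01388"),
               fallthrough = c("PF00249", "PF01388", "PF00010"),
               none = character(0),
               madsy = c("PF00319", "PF04690"))
  fam <- classify_tfs(doms, rules)
  expect_equal(unname(fam["myb"]), "MYB")
  expect_true(is.na(fam["blocked"]))             # forbidden domain blocks MYB
  expect_equal(unname(fam["fallthrough"]), "bHLH")  # falls through to later rule
  expect_true(is.na(fam["none"]))
  expect_equal(unname(fam["madsy"]), "YABBY")    # first matching rule in table order
  bad_header <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family\trequired", "MYB\tPF00249"), bad_header)
  expect_error(read_tf_rules(bad_header), "header")
  bad_row <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family\trequired\tforbidden", "MYB\t\t"), bad_row)
  expect_error(read_tf_rules(bad_row), "line 2")
})

test_that("top TF lists are ranked, tie-broken by id, and self-excluding", {
  genes <- c("p1", "t1", "t2", "t3")
  tom <- diag(4) * 0 + 0.1
  dimnames(tom) <- list(genes, genes)
  tom["p1", c("t1", "t2", "t3")] <- tom[c("t1", "t2", "t3"), "p1"] <- c(0.9, 0.5, 0.1)
  diag(tom) <- 1
  lists <- top_tf_lists(tom, "p1", c("t1", "t2", "t3"), top_tf_k = 2)
  expect_equal(lists$p1$tf, c("t1", "t2"))
  expect_equal(lists$p1$tom, c(0.9, 0.5))
  # tie: lower identifier first
  tom["p1", c("t1", "t2")] <- tom[c("t1", "t2"), "p1"] <- 0.7
  expect_equal(top_tf_lists(tom, "p1", c("t2", "t1"), top_tf_k = 1)$p1$tf, "t1")
  # k larger than the TF pool returns the full list, unpadded
  expect_equal(nrow(top_tf_lists(tom, "p1", c("t1", "t2"), top_tf_k = 10)$p1), 2L)
  # a pathway gene that is itself a TF never lists itself
  expect_false("p1" %in% top_tf_lists(tom, "p1", genes, top_tf_k = 10)$p1$tf)
  expect_error(top_tf_lists(tom, "p1", character(0)), "empty TF set")
})

test_that("regulator mining retains recurring TFs and matches enumeration", {
  lists <- list(
    A = data.frame(tf = c("t1", "t2"), tom = c(0.9, 0.8)),
    B = data.frame(tf = c("t1", "t3"), tom = c(0.7, 0.6)),
    C = data.frame(tf = c("t4", "t1"), tom = c(0.5, 0.4)))
  rep <- mine_regulators(lists, min_list_count = 2)
  expect_equal(rep$retained_tfs$tf, "t1")
  expect_equal(rep$retained_tfs$n_lists, 3L)
  expect_setequal(rep$bipartite_edges$pathway_gene, c("A", "B", "C"))

  # brute-force check over a hand-built TOM: 3 pathway genes, 4 TFs, k = 2
  genes <- c("pA", "pB", "pC", "t1", "t2", "t3", "t4")
  set.seed(52)
  tom <- random_tom(7)
  dimnames(tom) <- list(genes, genes)
  lists2 <- top_tf_lists(tom, c("pA", "pB", "pC"), c("t1", "t2", "t3", "t4"), top_tf_k = 2)
  got <- mine_regulators(lists2, min_list_count = 2)$retained_tfs$tf
  manual <- table(unlist(lapply(c("pA", "pB", "pC"), function(p) {
    w <- tom[p, c("t1", "t2", "t3", "t4")]
    names(sort(w, decreasing = TRUE))[1:2]
  })))
  expect_setequal(got, names(manual)[manual >= 2])
})

test_that("mining is invariant under gene relabeling", {
  set.seed(53)
  genes <- c("pA", "pB", "t1", "t2", "t3")
  tom <- random_tom(5)
  dimnames(tom) <- list(genes, genes)
  r1 <- mine_regulators(top_tf_lists(tom, c("pA", "pB"), c("t1", "t2", "t3"), 2), 2)
  relab <- c(pA = "xA", pB = "xB", t1 = "y1", t2 = "y2", t3 = "y3")
  tom2 <- tom; dimnames(tom2) <- list(relab[genes], relab[genes])
  r2 <- mine_regulators(top_tf_lists(tom2, c("xA", "xB"), c("y1", "y2", "y3"), 2), 2)
  expect_equal(unname(relab[r1$retained_tfs$tf]), r2$retained_tfs$tf)
})

test_that("recovery scoring handles perfect and empty cases", {
  truth <- structure(list(planted_links = data.frame(tf = c("t1", "t2"),
                                                     pathway_gene = c("p1", "p2"))),
                     class = "synthetic_truth")
  good <- list(retained_tfs = data.frame(tf = c("t1", "t2")))
  expect_equal(unname(evaluate_recovery(good, truth)), c(1, 1))
  empty <- list(retained_tfs = data.frame(tf = character(0)))
  expect_warning(pr <- evaluate_recovery(empty, truth), "empty retained")
  expect_true(is.nan(pr["precision"]))
  expect_equal(unname(pr["recall"]), 0)
})

test_that("adjusted Rand index matches the contingency formula", {
  a <- rep(1:2, each = 50)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, ifelse(a == 1, "x", "y")), 1)  # label-invariant
  b <- a; b[1] <- 2L
  ari <- adjusted_rand_index(a, b)
  expect_lt(ari, 1)
  # direct evaluation of the formula for the one-gene move
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); sa <- sum(ch2(rowSums(tab))); sb <- sum(ch2(colSums(tab)))
  exp_idx <- sa * sb / ch2(100)
  expect_equal(ari, (sij - exp_idx) / ((sa + sb) / 2 - exp_idx))
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})
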