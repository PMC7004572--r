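score_mat <- function(v, genes = 2, tfs = 2) {
  matrix(v, genes, tfs, dimnames = list(paste0("g", seq_len(genes)),
                                        paste0("t", seq_len(tfs))))
}

test_that("bootstrap indices are sized, seeded and cover ~63% of samples", {
  idx <- bootstrap_indices(50, 4, seed = 2)
  expect_length(idx, 4)
  expect_true(all(lengths(idx) == 50))
  expect_identical(bootstrap_indices(50, 4, seed = 2), idx)
  expect_false(identical(bootstrap_indices(50, 4, seed = 3), idx))
  n <- 500
  frac <- mean(vapply(bootstrap_indices(n, 200, seed = 1),
                      function(i) length(unique(i)) / n, numeric(1)))
  expect_lt(abs(frac - (1 - (1 - 1 / n)^n)), 0.01)
})

test_that("rank combination preserves single-input order and cancels reversals", {
  m <- score_mat(c(0.9, 0.1, 0.5, 0.3))
  c1 <- combine_ranks(list(m))
  expect_equal(order(as.vector(c1)), order(as.vector(m)))
  expect_equal(range(c1), c(0, 1))
  # exactly reversed orderings of 4 edges cancel: rank sums all equal
  rev_m <- score_mat(c(0.1, 0.9, 0.3, 0.5))
  cc <- combine_ranks(list(m, rev_m))
  expect_true(all(cc == cc[1]))
})

test_that("rank combination is invariant to strictly monotone transforms", {
  set.seed(6)
  m1 <- score_mat(runif(12), 4, 3)
  m2 <- score_mat(runif(12), 4, 3)
  base <- combine_ranks(list(m1, m2))
  expect_equal(combine_ranks(list(exp(3 * m1), m2)), base)
  expect_equal(combine_ranks(list(m1, m2^3 + 7)), base)
  # symmetric in input order
  expect_equal(combine_ranks(list(m2, m1)), base)
  expect_error(combine_ranks(list(m1, score_mat(runif(4)))), "share axes")
})

test_that("task combination rewards consistency across tasks", {
  same <- replicate(11, score_mat(c(0.9, 0.2, 0.6, 0.4)), simplify = FALSE)
  cc <- combine_tasks(same)
  expect_equal(order(as.vector(cc)), order(as.vector(same[[1]])))
  expect_true(all(cc >= 0 & cc <= 1))
  # an edge confident everywhere outranks one confident in a single task
  t1 <- score_mat(c(0.9, 0.8, 0.1, 0.1))
  t2 <- score_mat(c(0.9, 0.1, 0.1, 0.1))
  t3 <- score_mat(c(0.9, 0.1, 0.1, 0.1))
  cc2 <- combine_tasks(list(t1, t2, t3))
  expect_gt(cc2["g1", "t1"], cc2["g2", "t1"])
})

test_that("precision walk keeps the longest prefix meeting the target", {
  std <- prior_matrix(matrix(c(1, 1, 0, 0), 4, 1,
                             dimnames = list(paste0("g", 1:4), "t1")))
  net <- ranked_network(matrix(c(0.9, 0.8, 0.7, 0.6), 4, 1,
                               dimnames = list(paste0("g", 1:4), "t1")))
  # [hit, hit, miss, miss]: precision at 4 is exactly 0.5 -> whole list kept
  kept <- threshold_by_precision(net, std, 0.5)
  expect_equal(nrow(kept), 4)
  expect_equal(attr(kept, "precision"), 0.5)
  # stricter target: only the all-hit prefix survives
  kept2 <- threshold_by_precision(net, std, 0.75)
  expect_equal(nrow(kept2), 2)
  expect_equal(kept2$gene_id, c("g1", "g2"))
  # all edges in the standard -> everything kept
  all_std <- prior_matrix(matrix(1, 4, 1, dimnames = dimnames(std)))
  expect_equal(nrow(threshold_by_precision(net, all_std, 0.5)), 4)
  # no hits -> empty network
  none_std <- prior_matrix(matrix(0, 4, 1, dimnames = dimnames(std)))
  expect_equal(nrow(threshold_by_precision(net, none_std, 0.5)), 0)
})

test_that("edges outside the standard's universe ride on the cutoff", {
  conf <- matrix(c(0.9, 0.85, 0.8, 0.2), 2, 2,
                 dimnames = list(c("g1", "gX"), c("t1", "t2")))
  net <- ranked_network(conf)
  std <- prior_matrix(matrix(c(1, 1), 1, 2, dimnames = list("g1", c("t1", "t2"))))
  kept <- threshold_by_precision(net, std, 0.5)
  # the gX edge at 0.85 sits above the 0.8 cutoff and is retained
  expect_setequal(kept$combined_confidence, c(0.9, 0.85, 0.8))
  expect_true("gX" %in% kept$gene_id)
})

test_that("ranked networks order deterministically and round-trip as TSV", {
  conf <- matrix(c(0.9, 0.9, 0, 0.4), 2, 2,
                 dimnames = list(c("g1", "g2"), c("tA", "tB")))
  signs <- list(matrix(c(1, -1, 0, 1), 2, 2, dimnames = dimnames(conf)))
  prior <- prior_matrix(matrix(c(1, 0, 0, 0), 2, 2, dimnames = dimnames(conf)))
  net <- ranked_network(conf, signs = signs, prior = prior)
  expect_equal(nrow(net), 3)   # zero-confidence edge excluded
  # tie on confidence broken by (tf, gene)
  expect_equal(net$gene_id[1:2], c("g1", "g2"))
  expect_true(net$in_prior[net$gene_id == "g1" & net$tf_id == "tA"])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path, fmt = "tsv")
  back <- read_network(path)
  expect_equal(back$tf_id, net$tf_id)
  expect_equal(back$combined_confidence, net$combined_confidence)
  expect_equal(back$sign, net$sign)
  expect_equal(back$in_prior, net$in_prior)
  # empty network -> header-only TSV
  write_network(net[0, ], path, fmt = "tsv")
  expect_equal(nrow(read_network(path)), 0)
})

test_that("GEXF output is well-formed XML with edge attributes", {
  conf <- matrix(c(0.9, 0.4), 2, 1, dimnames = list(c("g1", "g2"), "tA"))
  net <- ranked_network(conf)
  path <- withr::local_tempfile(fileext = ".gexf")
  write_network(net, path, fmt = "gexf")
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "gexf")
  edges <- xml2::xml_find_all(doc, "//*[local-name()='edge']")
  expect_length(edges, 2)
  expect_error(write_network(net, path, fmt = "dot"))
})

test_that("edge signs never contradict a unanimous coefficient sign", {
  conf <- matrix(c(0.8, 0.6), 2, 1, dimnames = list(c("g1", "g2"), "tA"))
  signs <- replicate(5, matrix(c(1, -1), 2, 1, dimnames = dimnames(conf)),
                     simplify = FALSE)
  net <- ranked_network(conf, signs = signs)
  expect_equal(net$sign[net$gene_id == "g1"], 1)
  expect_equal(net$sign[net$gene_id == "g2"], -1)
})
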