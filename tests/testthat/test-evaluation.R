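mini_net <- function(conf) ranked_network(conf)

test_that("perfect rankings give precision 1 everywhere and AUPR 1", {
  gs <- prior_matrix(matrix(c(1, 1, 0, 0), 4, 1,
                            dimnames = list(paste0("g", 1:4), "t1")),
                     gold_standard = TRUE)
  net <- mini_net(matrix(c(0.9, 0.8, 0.2, 0.1), 4, 1, dimnames = dimnames(gs)))
  pr <- precision_recall(net, gs)
  expect_true(all(pr$precision[pr$rank <= 2] == 1))
  expect_equal(max(pr$recall), 1)
  expect_equal(aupr(pr), 1)
})

test_that("precision-recall matches brute-force prefix counting", {
  set.seed(13)
  genes <- paste0("g", 1:20); tfs <- paste0("t", 1:5)
  gsv <- matrix(rbinom(100, 1, 0.25), 20, 5, dimnames = list(genes, tfs))
  gs <- prior_matrix(gsv, gold_standard = TRUE)
  conf <- matrix(runif(100), 20, 5, dimnames = list(genes, tfs))
  net <- mini_net(conf)
  pr <- precision_recall(net, gs)
  hits <- gsv[cbind(pr$gene_id, pr$tf_id)] != 0
  ora <- oracle_prefix_pr(hits, sum(gsv != 0))
  expect_equal(pr$precision, ora$precision)
  expect_equal(pr$recall, ora$recall)
  expect_equal(aupr(pr), ora$aupr)
})

test_that("prior exclusion removes edges from both list and positives", {
  genes <- paste0("g", 1:6)
  gs <- prior_matrix(matrix(c(1, 1, 1, 0, 0, 0), 6, 1,
                            dimnames = list(genes, "t1")), gold_standard = TRUE)
  excl <- prior_matrix(matrix(c(1, 0, 0, 0, 0, 0), 6, 1,
                              dimnames = list(genes, "t1")))
  net <- mini_net(matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), 6, 1,
                         dimnames = list(genes, "t1")))
  pr <- precision_recall(net, gs, exclude = excl)
  expect_equal(attr(pr, "n_positives"), 2)
  expect_false("g1" %in% pr$gene_id)
  expect_error(precision_recall(net, gs, exclude = gs), "no positive")
})

test_that("recall arithmetic of the published-scale network reproduces", {
  # 11486 known interactions of which 5372 are not recovered
  n_std <- 11486; n_missed <- 5372
  recovered <- n_std - n_missed
  expect_equal(recovered, 6114)
  expect_equal(round(recovered / n_std, 3), 0.532)
  # 6114 recovered prior edges plus 6114 new edges
  expect_equal(recovered + 6114, 12228)
})

test_that("random-ranking AUPR approximates the positive fraction", {
  set.seed(23)
  genes <- paste0("g", 1:100); tfs <- paste0("t", 1:10)
  n_univ <- length(genes) * length(tfs)
  gsv <- matrix(rbinom(n_univ, 1, 0.2), length(genes), length(tfs),
                dimnames = list(genes, tfs))
  gs <- prior_matrix(gsv, gold_standard = TRUE)
  pos_frac <- sum(gsv) / n_univ
  vals <- vapply(1:1000, function(s) {
    set.seed(s + 5000)
    conf <- matrix(runif(n_univ), length(genes), length(tfs),
                   dimnames = list(genes, tfs))
    aupr(precision_recall(mini_net(conf), gs))
  }, numeric(1))
  expect_lt(abs(mean(vals) - pos_frac), 0.01)
})

test_that("small-instance AUPR matches exhaustive enumeration", {
  # 2 positives among 4 candidates: all 24 orderings enumerable
  genes <- paste0("g", 1:4)
  gs <- prior_matrix(matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(genes, "t1")),
                     gold_standard = TRUE)
  perms <- list(c(1, 2, 3, 4), c(3, 1, 4, 2), c(3, 4, 1, 2), c(2, 3, 1, 4))
  for (pm in perms) {
    conf <- matrix(0, 4, 1, dimnames = list(genes, "t1"))
    conf[pm, 1] <- c(0.9, 0.7, 0.5, 0.3)
    pr <- precision_recall(mini_net(conf), gs)
    hits <- c(1, 2) %in% pm[order(-conf[pm, 1])]   # sanity on construction
    ora <- oracle_prefix_pr(pr$hit, 2)
    expect_equal(aupr(pr), ora$aupr)
  }
})

test_that("edge-count summaries agree with the precision walk", {
  genes <- paste0("g", 1:7)
  gs <- prior_matrix(matrix(1, 7, 1, dimnames = list(genes, "t1")),
                     gold_standard = TRUE)
  conf <- matrix(seq(0.99, 0.6, length.out = 7), 7, 1,
                 dimnames = list(genes, "t1"))
  net <- mini_net(conf)
  counts <- edge_count_summaries(net, gs)
  expect_equal(counts[["n_precision_edges"]], 7)
  expect_equal(counts[["n_confidence_edges"]], sum(conf > 0.95))
  expect_equal(counts[["n_precision_edges"]],
               nrow(threshold_by_precision(net, gs, 0.5)))
  empty <- net[0, ]
  expect_equal(unname(edge_count_summaries(empty, gs)), c(0L, 0L))
})

test_that("cross-validation yields one AUPR per repeat, reproducibly", {
  bm <- make_benchmark(n_genes = 40, n_tfs = 6, targets_per_tf = 6,
                       n_conditions = 2, cells_per_condition = 60, seed = 5)
  x <- log_transform(filter_zero_variance(bm$counts))
  cv <- crossvalidate(x, bm$meta, bm$truth$network, method = "bbsr-by-task",
                      n_repeats = 3, seed = 7, n_bootstraps = 2)
  expect_equal(nrow(cv), 3)
  expect_true(all(cv$aupr >= 0 & cv$aupr <= 1))
  cv2 <- crossvalidate(x, bm$meta, bm$truth$network, method = "bbsr-by-task",
                       n_repeats = 3, seed = 7, n_bootstraps = 2)
  expect_equal(cv$aupr, cv2$aupr)
  g <- glance(cv)
  expect_equal(g$mean_aupr, mean(cv$aupr))
})

test_that("negative controls run the same pipeline and return CV tables", {
  bm <- make_benchmark(n_genes = 30, n_tfs = 5, targets_per_tf = 5,
                       n_conditions = 2, cells_per_condition = 50, seed = 9)
  nc <- negative_controls(bm$counts, bm$meta, bm$truth$network,
                          method = "bbsr-by-task", n_repeats = 2, seed = 3,
                          n_bootstraps = 2)
  expect_s3_class(nc$shuffled, "cv_result")
  expect_s3_class(nc$simulated, "cv_result")
  expect_equal(nrow(nc$shuffled), 2)
  expect_true(all(nc$simulated$aupr >= 0 & nc$simulated$aupr <= 1))
})
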