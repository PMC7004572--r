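make_tasks <- function(d = 3, n = 60, p = 5, beta_shared = NULL,
                       beta_specific = NULL, noise = 0.2, seed = 1) {
  set.seed(seed)
  tfs <- paste0("TF", seq_len(p))
  ys <- vector("list", d); As <- vector("list", d)
  for (t in seq_len(d)) {
    A <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, tfs))
    b <- if (is.null(beta_shared)) numeric(p) else beta_shared
    if (!is.null(beta_specific)) b <- b + beta_specific[, t]
    ys[[t]] <- as.vector(A %*% b + rnorm(n, sd = noise))
    As[[t]] <- A
  }
  list(ys = ys, As = As)
}

test_that("lambda grid has 200 pairs, exact endpoints, and the ratio constraint", {
  g <- build_lambda_grid(d = 3, n = 100, p = 20)
  expect_equal(nrow(g), 200)
  expect_equal(length(unique(g$c_b)), 20)
  expect_equal(length(unique(g$c_s)), 10)
  expect_equal(min(g$c_b), 0.1)
  expect_equal(max(g$c_b), 10.0)
  ratio <- g$lambda_s / g$lambda_b
  expect_true(all(ratio > 1 / 3 & ratio < 1))
  expect_equal(g$lambda_b, g$c_b * sqrt(3 * log(20) / 100))
  # alternative scaling reading
  g2 <- build_lambda_grid(d = 3, n = 100, p = 20, scaling = "linear")
  expect_equal(g2$lambda_b, g2$c_b * 3 * sqrt(log(20) / 100))
  expect_error(build_lambda_grid(d = 3, n = 1, p = 20), "n >= 2")
})

test_that("EBIC reduces to BIC at gamma 0 and penalizes irrelevant predictors", {
  expect_equal(ebic(4, 10, 0, 8), 10 * log(0.4))
  expect_equal(ebic(4, 10, 3, 8, gamma = 0), 10 * log(0.4) + 3 * log(10))
  expect_equal(ebic(0, 10, 2, 8), -Inf)
  base <- ebic(2.000001, 50, 2, 10)
  worse <- ebic(2.000000, 50, 3, 10)
  expect_gt(worse, base)
})

test_that("full shrinkage drives every coefficient to zero", {
  td <- make_tasks(d = 2, beta_shared = c(3, 0, 0, 0, 0), seed = 4)
  fit <- fit_amusr_gene(td$ys, td$As, lambda_s = 1e6, lambda_b = 1e6)
  expect_true(all(fit$W == 0))
})

test_that("a shared regulator loads on the conserved component", {
  td <- make_tasks(d = 3, n = 100, beta_shared = c(2.5, 0, 0, 0, 0),
                   noise = 0.1, seed = 7)
  fit <- fit_amusr_gene(td$ys, td$As)
  expect_true(all(fit$W["TF1", ] != 0))
  expect_lte(sum(abs(fit$S)), 0.05 * sum(abs(fit$B)) + 1e-9)
  # the returned split scores below the equivalent all-in-S solution
  std <- standardize_tasks(td$ys, td$As)
  obj_ret <- oracle_amusr_objective(std$ys, std$As, fit$S, fit$B,
                                    fit$lambda_s, fit$lambda_b)
  obj_allS <- oracle_amusr_objective(std$ys, std$As, fit$S + fit$B, 0 * fit$B,
                                     fit$lambda_s, fit$lambda_b)
  expect_lte(obj_ret, obj_allS + 1e-9)
})

test_that("shared and task-specific regulators separate on synthetic truth", {
  spec <- matrix(0, 5, 2)
  spec[2, 1] <- 2            # TF2 acts only in task 1
  td <- make_tasks(d = 2, n = 200, beta_shared = c(2, 0, 0, 0, 0),
                   beta_specific = spec, noise = 0.05, seed = 9)
  fit <- fit_amusr_gene(td$ys, td$As)
  expect_true(all(fit$W["TF1", ] != 0))      # shared edge in both tasks
  expect_gt(abs(fit$W["TF2", 1]), 0.1)       # unique edge strong in task 1
  # any task-2 loading of the unique regulator is at noise scale: inside a
  # selected l1/linf row, entries below the row maximum are penalty-free
  expect_lt(abs(fit$W["TF2", 2]), 0.05 * abs(fit$W["TF2", 1]))
})

test_that("solver objective is non-increasing on random instances", {
  for (s in 1:10) {
    td <- make_tasks(d = sample(2:4, 1), n = 40,
                     beta_shared = rnorm(5) * rbinom(5, 1, 0.4), seed = 200 + s)
    g <- build_lambda_grid(length(td$ys), 40, 5)
    pick <- g[sample(nrow(g), 1), ]
    fit <- fit_amusr_gene(td$ys, td$As, lambda_s = pick$lambda_s,
                          lambda_b = pick$lambda_b)
    expect_true(all(diff(fit$objective) <= 1e-8))
  }
})

test_that("penalty limits zero out the corresponding component", {
  td <- make_tasks(d = 2, n = 80, beta_shared = c(2, -1, 0, 0, 0), seed = 12)
  f1 <- fit_amusr_gene(td$ys, td$As, lambda_s = 1e7, lambda_b = 0.5)
  expect_true(all(f1$S == 0))
  expect_true(any(f1$B != 0))
  f2 <- fit_amusr_gene(td$ys, td$As, lambda_s = 0.5, lambda_b = 1e7)
  expect_true(all(f2$B == 0))
  expect_true(any(f2$S != 0))
})

test_that("permuting task order permutes the outputs identically", {
  td <- make_tasks(d = 3, n = 60, beta_shared = c(2, 0, 0, 0, 0), seed = 15)
  g <- build_lambda_grid(3, 60, 5)
  fit <- fit_amusr_gene(td$ys, td$As, grid = g)
  perm <- c(3, 1, 2)
  fit_p <- fit_amusr_gene(td$ys[perm], td$As[perm], grid = g)
  expect_equal(unname(fit_p$W), unname(fit$W[, perm]), tolerance = 1e-8)
})

test_that("multitask bootstrap run returns per-task gene x TF scores", {
  bm <- make_benchmark(n_genes = 25, n_tfs = 5, targets_per_tf = 6,
                       n_conditions = 2, cells_per_condition = 80,
                       noise_sd = 0.15, seed = 21)
  x <- log_transform(filter_zero_variance(bm$counts))
  tasks <- split_tasks(x, bm$meta)
  acts <- lapply(tasks, estimate_tfa, p = bm$truth$network)
  res <- run_amusr(tasks, acts, bm$truth$network, n_bootstraps = 2, seed = 3)
  expect_length(res, 2)
  for (t in seq_along(res)) {
    sc <- res[[t]]$scores[[1]]
    expect_equal(dim(sc), c(ncol(x), 5))
    expect_true(all(sc >= 0 & sc <= 1))
  }
  # shared true edges receive nonzero scores in >= 2 tasks
  truth <- unclass(bm$truth$network)
  mean_sc <- lapply(res, function(r) Reduce(`+`, r$scores) / length(r$scores))
  nz_both <- truth != 0 & mean_sc[[1]] > 0 & mean_sc[[2]] > 0
  expect_gt(sum(nz_both), 0)
})
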