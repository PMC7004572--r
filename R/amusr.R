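# Multitask sparse regression: per gene, the coefficient matrix W
# (regulators x tasks) is decomposed as W = S + B, with an l1/l1 penalty on
# the task-specific component S and an l1/linf penalty on the conserved
# component B; the (lambda_s, lambda_b) pair is chosen by extended BIC.

#' Build the regularization-parameter grid for multitask fitting
#'
#' The shared-penalty weight is `lambda_b = c_b * sqrt(d * ln(p) / n)` for 20
#' log-spaced values of `c_b` in `[0.1, 10.0]`, and the sparse-penalty weight
#' is `lambda_s = c_s * lambda_b` for 10 linearly spaced values of `c_s` in
#' `[1/d + 0.01, 0.99]`, so every pair satisfies `1/d < lambda_s/lambda_b <
#' 1`. An alternative scaling `lambda_b = c_b * d * sqrt(ln(p) / n)` is
#' available; the 100-fold range of the `c_b` grid absorbs the difference.
#'
#' @param d Number of tasks (>= 1; `d = 1` degenerates to single-task
#'   fitting where the shared and specific components coincide).
#' @param n Mean number of samples per task.
#' @param p Number of candidate predictors.
#' @param n_cb,n_cs Grid sizes (defaults 20 and 10).
#' @param scaling `"sqrt"` (default) or `"linear"` for the alternative
#'   `lambda_b` reading.
#' @return A `lambda_grid` tibble with columns `c_b`, `c_s`, `lambda_b`,
#'   `lambda_s` (one row per pair, `n_cb * n_cs` rows).
#' @export
build_lambda_grid <- function(d, n, p, n_cb = 20L, n_cs = 10L,
                              scaling = c("sqrt", "linear")) {
  scaling <- match.arg(scaling)
  if (p < 2 || n < 2) stop("need p >= 2 predictors and n >= 2 samples", call. = FALSE)
  if (d < 1) stop("need at least one task", call. = FALSE)
  c_b <- exp(seq(log(0.1), log(10.0), length.out = n_cb))
  c_b[1] <- 0.1; c_b[n_cb] <- 10.0
  lo <- 1 / d + 0.01
  if (lo >= 0.99) lo <- 0.99 - 1e-6   # d = 1 degeneracy
  c_s <- seq(lo, 0.99, length.out = n_cs)
  base <- if (scaling == "sqrt") sqrt(d * log(p) / n) else d * sqrt(log(p) / n)
  grid <- tidyr::expand_grid(c_b = c_b, c_s = c_s)
  grid$lambda_b <- grid$c_b * base
  grid$lambda_s <- grid$c_s * grid$lambda_b
  structure(grid, class = c("lambda_grid", class(grid)))
}

#' Extended Bayesian Information Criterion
#'
#' `n*ln(rss/n) + q*ln(n) + 2*gamma*q*ln(p)`; reduces to BIC at `gamma = 0`.
#' A perfect fit (`rss = 0`) scores `-Inf`.
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n Number of samples.
#' @param q Number of nonzero coefficients.
#' @param p Number of candidate predictors.
#' @param gamma Dimensional-penalty weight (default 1).
#' @return The EBIC score.
#' @export
ebic <- function(rss, n, q, p, gamma = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (rss < 0) stop("rss must be >= 0", call. = FALSE)
  if (rss == 0) return(-Inf)
  n * log(rss / n) + q * log(n) + 2 * gamma * q * log(p)
}

#' Fit the multitask model for one gene
#'
#' Minimizes, over the task-specific component `S` and the conserved
#' component `B`,
#' `sum_d ||y_d - A_d (S_d + B_d)||^2 + lambda_s * sum |S| + lambda_b *
#' ||B||_{1,inf}`, by alternating exact coordinate descent on `S` with a
#' proximal gradient step on `B` (l1/linf proximal operator via l1-ball
#' projection). Either a single `(lambda_s, lambda_b)` pair is fitted, or
#' the whole grid is searched and the extended-BIC minimizer returned.
#'
#' @param responses List of per-task response vectors.
#' @param activities List of per-task samples x regulators matrices (same
#'   regulator columns in every task).
#' @param grid A [build_lambda_grid()] tibble, or `NULL` when `lambda_s` and
#'   `lambda_b` are given directly.
#' @param lambda_s,lambda_b Optional single penalty pair overriding `grid`.
#' @param gamma EBIC weight (default 1).
#' @param max_iter,tol Solver controls: at most `max_iter` alternations
#'   (default 1000), stopping when the relative objective change falls below
#'   `tol` (default 1e-2).
#' @param scale_data Center and unit-scale responses and activities within
#'   each task before fitting (default `TRUE`), so one lambda grid is
#'   meaningful across tasks of different depth.
#' @return A `multitask_gene_model` list: `W`, `S`, `B` (regulators x tasks),
#'   `lambda_s`, `lambda_b`, `ebic`, `objective` (solver trace for the
#'   returned fit), `var_exp` (regulators x tasks explained-variance
#'   fractions), `tasks` (task names).
#' @export
fit_amusr_gene <- function(responses, activities, grid = NULL,
                           lambda_s = NULL, lambda_b = NULL, gamma = 1,
                           max_iter = 1000L, tol = 1e-2, scale_data = TRUE) {
  d <- length(responses)
  stopifnot(d == length(activities), d >= 1)
  tfs <- colnames(activities[[1]])
  task_names <- names(responses)
  if (is.null(task_names)) task_names <- paste0("task", seq_len(d))
  prep <- prepare_amusr_data(responses, activities, scale_data)
  if (!is.null(lambda_s) && !is.null(lambda_b)) {
    fit <- amusr_core_single(prep$A, prep$y, lambda_s, lambda_b,
                             as.integer(max_iter), tol)
    W <- fit$S + fit$B
    chosen <- c(lambda_s = lambda_s, lambda_b = lambda_b)
    sc <- ebic(amusr_rss(prep, W), sum(prep$n), sum(W != 0), length(tfs), gamma)
  } else {
    if (is.null(grid)) {
      grid <- build_lambda_grid(d, mean(prep$n), max(length(tfs), 2))
    }
    fit <- amusr_core_grid(prep$A, prep$y, grid$lambda_s, grid$lambda_b,
                           gamma, as.integer(max_iter), tol)
    W <- fit$S + fit$B
    chosen <- c(lambda_s = fit$lambda_s, lambda_b = fit$lambda_b)
    sc <- fit$ebic
  }
  dimnames(W) <- list(tfs, task_names)
  S <- fit$S; B <- fit$B
  dimnames(S) <- dimnames(B) <- dimnames(W)
  structure(list(W = W, S = S, B = B,
                 lambda_s = unname(chosen["lambda_s"]),
                 lambda_b = unname(chosen["lambda_b"]),
                 ebic = sc, objective = fit$objective,
                 var_exp = amusr_var_exp(prep, W), tasks = task_names),
            class = "multitask_gene_model")
}

prepare_amusr_data <- function(responses, activities, scale_data) {
  d <- length(responses)
  A <- vector("list", d); y <- vector("list", d); n <- integer(d)
  for (t in seq_len(d)) {
    at <- as.matrix(activities[[t]])
    yt <- as.numeric(responses[[t]])
    stopifnot(nrow(at) == length(yt), length(yt) >= 2)
    if (scale_data) {
      yt <- yt - mean(yt)
      syt <- sd(yt)
      if (syt > 0) yt <- yt / syt
      at <- scale(at)
      at[, !is.finite(colSums(at))] <- 0   # constant predictors in this task
    }
    A[[t]] <- unname(at); y[[t]] <- yt; n[t] <- length(yt)
  }
  list(A = A, y = y, n = n)
}

amusr_rss <- function(prep, W) {
  sum(vapply(seq_along(prep$A), function(t) {
    r <- prep$y[[t]] - prep$A[[t]] %*% W[, t]
    sum(r^2)
  }, numeric(1)))
}

# explained variance per (regulator, task): relative reduction in residual
# variance when the coefficient is zeroed (no refit), clamped to [0, 1]
amusr_var_exp <- function(prep, W) {
  out <- matrix(0, nrow = nrow(W), ncol = ncol(W))
  for (t in seq_len(ncol(W))) {
    w <- W[, t]
    nz <- which(w != 0)
    if (!length(nz)) next
    r_full <- prep$y[[t]] - prep$A[[t]] %*% w
    rss_full <- sum(r_full^2)
    for (j in nz) {
      wd <- w; wd[j] <- 0
      rss_drop <- sum((prep$y[[t]] - prep$A[[t]] %*% wd)^2)
      ve <- if (rss_drop <= 1e-12) 0 else 1 - rss_full / rss_drop
      out[j, t] <- min(1, max(0, ve))
    }
  }
  dimnames(out) <- dimnames(W)
  out
}

#' Run multitask inference over bootstraps
#'
#' For each bootstrap (cells resampled with replacement within every task):
#' candidate regulators per gene are the union of each task's top-`k` CLR
#' TFs plus prior regulators; [fit_amusr_gene()] is fitted over the lambda
#' grid; edges are scored per task by the explained-variance fraction of the
#' fitted coefficients.
#'
#' @param tasks A `task_set` from [split_tasks()].
#' @param activities List of per-task TFs x cells activity matrices aligned
#'   to the task cells.
#' @param prior Optional [prior_matrix()] forcing known regulators into the
#'   candidate sets.
#' @param n_bootstraps,seed,k,cap,n_bins As in [run_bbsr_task()].
#' @param gamma,max_iter,tol Passed to [fit_amusr_gene()].
#' @return A list with one element per task, each a list of per-bootstrap
#'   `scores` and `signs` matrices (genes x TFs), shaped as in
#'   [run_bbsr_task()].
#' @export
run_amusr <- function(tasks, activities, prior = NULL, n_bootstraps = 20L,
                      seed = 1L, k = 10L, cap = 14L, n_bins = 10L,
                      gamma = 1, max_iter = 1000L, tol = 1e-2) {
  d <- length(tasks)
  genes <- colnames(tasks[[1]])
  tfs <- rownames(activities[[1]])
  grid <- build_lambda_grid(d, mean(vapply(tasks, nrow, integer(1))),
                            max(length(tfs), 2))
  out <- lapply(seq_len(d), function(t) {
    list(scores = vector("list", n_bootstraps),
         signs = vector("list", n_bootstraps))
  })
  names(out) <- names(tasks)
  for (b in seq_len(n_bootstraps)) {
    xb <- vector("list", d); ab <- vector("list", d)
    for (t in seq_len(d)) {
      idx <- bootstrap_indices(nrow(tasks[[t]]), 1L,
                               derive_seed(seed, b * 131L + t))[[1]]
      xb[[t]] <- unclass(tasks[[t]])[idx, , drop = FALSE]
      ab[[t]] <- unclass(activities[[t]])[, idx, drop = FALSE]
    }
    # per-task CLR; candidates per gene = union of top-k across tasks + priors
    zs <- lapply(seq_len(d), function(t) {
      clr_matrix(mi_matrix(ab[[t]], xb[[t]], n_bins = n_bins))
    })
    smats <- lapply(seq_len(d), function(t) {
      matrix(0, length(genes), length(tfs), dimnames = list(genes, tfs))
    })
    gmats <- smats
    for (i in seq_along(genes)) {
      g <- genes[i]
      prior_row <- if (!is.null(prior) && g %in% rownames(prior)) {
        unclass(prior)[g, , drop = TRUE]
      } else NULL
      prior_regs <- if (is.null(prior_row)) character(0) else names(prior_row)[prior_row != 0]
      sel <- character(0)
      for (t in seq_len(d)) {
        sel <- union(sel, select_regulators(zs[[t]][, i], prior_row, k = k,
                                            self_tf = if (g %in% tfs) g))
      }
      zbar <- Reduce(`+`, lapply(zs, function(z) z[, i])) / d
      sel <- cap_candidates(sel[order(match(sel, tfs))], zbar, prior_regs, cap)
      if (length(sel) < 2) next
      responses <- lapply(seq_len(d), function(t) xb[[t]][, i])
      acts <- lapply(seq_len(d), function(t) t(ab[[t]][sel, , drop = FALSE]))
      fit <- fit_amusr_gene(responses, acts, grid = grid, gamma = gamma,
                            max_iter = max_iter, tol = tol)
      for (t in seq_len(d)) {
        smats[[t]][g, sel] <- fit$var_exp[, t]
        gmats[[t]][g, sel] <- sign(fit$W[, t])
      }
    }
    for (t in seq_len(d)) {
      out[[t]]$scores[[b]] <- smats[[t]]
      out[[t]]$signs[[b]] <- gmats[[t]]
    }
  }
  out
}
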