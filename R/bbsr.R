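# Single-task network inference: per gene, exhaustive best-subset ordinary
# least squares over a CLR-preselected candidate set, scored by BIC.

#' Best-subset regression for one gene
#'
#' Enumerates every subset of the candidate regulators, fits ordinary least
#' squares on centered response and predictors (no intercept), and keeps the
#' subset with the lowest BIC, `n*ln(RSS/n) + q*ln(n)`. Ties go to the
#' smaller subset, then to the lexicographically first regulator set. The
#' per-regulator explained-variance fraction is the relative reduction in
#' residual variance when that regulator is dropped from the chosen model,
#' clamped to `[0, 1]`.
#'
#' @param y Numeric response over samples (the gene's expression).
#' @param a Samples x regulators matrix of candidate activities, with
#'   regulator column names.
#' @param gene_id Optional gene identifier carried into the result.
#' @return A `gene_model` list: `gene_id`, `regulators` (chosen set),
#'   `beta` (named coefficients, zero outside the chosen set), `var_exp`
#'   (named explained-variance fractions), `bic`, `rss`, `r2`.
#' @export
best_subset_regression <- function(y, a, gene_id = NA_character_) {
  a <- as.matrix(a)
  if (length(y) != nrow(a)) stop("response and predictors disagree on samples", call. = FALSE)
  if (length(y) < 2) stop("need at least two samples", call. = FALSE)
  if (is.null(colnames(a))) colnames(a) <- paste0("tf", seq_len(ncol(a)))
  yc <- y - mean(y)
  ac <- scale(a, center = TRUE, scale = FALSE)
  fit <- best_subset_core(ac, yc)
  tfs <- colnames(a)
  chosen <- tfs[fit$idx + 1L]
  beta <- setNames(numeric(length(tfs)), tfs)
  beta[chosen] <- fit$beta
  var_exp <- setNames(numeric(length(tfs)), tfs)
  var_exp[chosen] <- fit$var_exp
  structure(list(gene_id = gene_id, regulators = chosen, beta = beta,
                 var_exp = var_exp, bic = fit$bic, rss = fit$rss,
                 r2 = fit$r2),
            class = "gene_model")
}

# Trim a candidate set to the enumeration cap: keep all prior regulators,
# then the highest-CLR remainder until the cap is met.
cap_candidates <- function(sel, z_row, prior_regs, cap) {
  if (length(sel) <= cap) return(sel)
  keep <- intersect(sel, prior_regs)
  if (length(keep) > cap) keep <- keep[seq_len(cap)]
  rest <- setdiff(sel, keep)
  rest <- rest[order(-z_row[rest], rest)]
  out <- c(keep, head(rest, cap - length(keep)))
  out[order(match(out, names(z_row)))]
}

#' Run single-task best-subset inference over bootstraps
#'
#' For each bootstrap resample of the cells: computes the mutual-information
#' matrix between TF activities and gene expression, converts it to CLR
#' scores, preselects up to `k` candidate regulators per gene (always
#' including prior regulators), and fits [best_subset_regression()]. The
#' edge score is the per-regulator explained-variance fraction.
#'
#' @param task An [expression_matrix()] for one task (cells x genes).
#' @param activities TFs x cells [estimate_tfa()] output aligned to the task
#'   cells.
#' @param prior A [prior_matrix()] used to force known regulators into the
#'   candidate sets (may be `NULL`).
#' @param n_bootstraps Number of bootstrap resamples (default 20).
#' @param seed Integer seed; bootstrap `b` uses a seed derived from
#'   `(seed, b)`.
#' @param k Number of top-CLR candidates per gene (default 10).
#' @param cap Exhaustive-enumeration cap on candidate-set size (default 14);
#'   larger sets are trimmed, keeping priors plus the highest-CLR TFs.
#' @param n_bins Bins for the mutual-information estimator (default 10).
#' @param score Edge-score rule: `"var_exp"` (default) scores each edge by
#'   its explained-variance fraction; `"var_exp_r2"` additionally multiplies
#'   by the model's total R^2.
#' @return A list with `scores` and `signs`: lists (one per bootstrap) of
#'   genes x TFs matrices of non-negative edge scores and coefficient signs.
#' @export
run_bbsr_task <- function(task, activities, prior = NULL, n_bootstraps = 20L,
                          seed = 1L, k = 10L, cap = 14L, n_bins = 10L,
                          score = c("var_exp", "var_exp_r2")) {
  score <- match.arg(score)
  genes <- colnames(task)
  tfs <- rownames(activities)
  stopifnot(identical(colnames(activities), rownames(task)))
  idx_list <- bootstrap_indices(nrow(task), n_bootstraps, seed)
  scores <- signs <- vector("list", n_bootstraps)
  for (b in seq_len(n_bootstraps)) {
    idx <- idx_list[[b]]
    xb <- unclass(task)[idx, , drop = FALSE]
    ab <- unclass(activities)[, idx, drop = FALSE]
    sc <- fit_bbsr_once(xb, ab, prior, k = k, cap = cap, n_bins = n_bins,
                        score = score)
    scores[[b]] <- sc$scores
    signs[[b]] <- sc$signs
  }
  list(scores = scores, signs = signs)
}

fit_bbsr_once <- function(xb, ab, prior, k, cap, n_bins, score = "var_exp") {
  genes <- colnames(xb)
  tfs <- rownames(ab)
  mi <- mi_matrix(ab, xb, n_bins = n_bins)
  z <- clr_matrix(mi)
  smat <- matrix(0, nrow = length(genes), ncol = length(tfs),
                 dimnames = list(genes, tfs))
  gmat <- smat
  at <- t(ab)
  for (i in seq_along(genes)) {
    g <- genes[i]
    prior_row <- if (!is.null(prior) && g %in% rownames(prior)) {
      unclass(prior)[g, , drop = TRUE]
    } else NULL
    prior_regs <- if (is.null(prior_row)) character(0) else names(prior_row)[prior_row != 0]
    sel <- select_regulators(z[, i], prior_row, k = k, self_tf = if (g %in% tfs) g)
    sel <- cap_candidates(sel, z[, i], prior_regs, cap)
    if (!length(sel)) next
    fit <- best_subset_regression(xb[, i], at[, sel, drop = FALSE], gene_id = g)
    if (!length(fit$regulators)) next
    val <- fit$var_exp[fit$regulators]
    if (score == "var_exp_r2") val <- val * fit$r2
    smat[g, fit$regulators] <- val
    gmat[g, fit$regulators] <- sign(fit$beta[fit$regulators])
  }
  list(scores = smat, signs = gmat)
}
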