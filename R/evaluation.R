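# Evaluation against a gold standard: precision-recall curves, AUPR by
# average precision, edge-count summaries, and the repeated cross-validation
# harness with the two negative controls.

#' Precision-recall curve of a ranked network against a gold standard
#'
#' Evaluation is restricted to the gold standard's gene x TF universe.
#' Edges present in `exclude` (the priors used for fitting) are removed from
#' both the ranked list and the positive set, so only interactions the model
#' could not have memorized are scored. Precision and recall are accumulated
#' down the ranked list.
#'
#' @param net A `ranked_network` tibble.
#' @param gs A gold-standard [prior_matrix()].
#' @param exclude Optional [prior_matrix()] of edges to exclude.
#' @return A `pr_curve` tibble with columns `rank`, `tf_id`, `gene_id`,
#'   `hit`, `precision`, `recall`; total positives in attribute
#'   `"n_positives"`.
#' @export
precision_recall <- function(net, gs, exclude = NULL) {
  gs_m <- unclass(gs)
  pos <- gs_m != 0
  if (!is.null(exclude)) {
    eg <- intersect(rownames(exclude), rownames(gs))
    et <- intersect(colnames(exclude), colnames(gs))
    if (length(eg) && length(et)) {
      pos[eg, et] <- pos[eg, et] & (unclass(exclude)[eg, et] == 0)
    }
  }
  n_pos <- sum(pos)
  if (n_pos == 0) stop("no positive interactions remain after exclusion", call. = FALSE)
  sub <- net[net$gene_id %in% rownames(gs) & net$tf_id %in% colnames(gs), ]
  if (!is.null(exclude)) {
    drop <- rep(FALSE, nrow(sub))
    ok <- sub$gene_id %in% rownames(exclude) & sub$tf_id %in% colnames(exclude)
    drop[ok] <- unclass(exclude)[cbind(sub$gene_id[ok], sub$tf_id[ok])] != 0
    sub <- sub[!drop, ]
  }
  hit <- if (nrow(sub)) pos[cbind(sub$gene_id, sub$tf_id)] else logical(0)
  pr <- tibble::tibble(
    rank = seq_len(nrow(sub)),
    tf_id = sub$tf_id, gene_id = sub$gene_id, hit = hit,
    precision = cumsum(hit) / seq_len(nrow(sub)),
    recall = cumsum(hit) / n_pos
  )
  attr(pr, "n_positives") <- n_pos
  structure(pr, class = c("pr_curve", class(pr)))
}

#' Area under the precision-recall curve (average precision)
#'
#' Sums precision-at-rank over the ranks at which a positive is recovered
#' and divides by the total number of positives; unrecovered positives
#' contribute zero, so the value lives in `[0, 1]`.
#'
#' @param pr A `pr_curve` from [precision_recall()].
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(pr) {
  n_pos <- attr(pr, "n_positives")
  if (is.null(n_pos)) stop("pr lacks the n_positives attribute", call. = FALSE)
  sum(pr$precision[pr$hit]) / n_pos
}

#' Edge counts at the precision and confidence cutoffs
#'
#' Reports the number of network edges kept at a precision (> 0.5 by
#' default) cutoff against the standard, and the number with combined
#' confidence above a fixed cutoff (0.95 by default).
#'
#' @param net A `ranked_network` tibble.
#' @param standard Prior/gold-standard matrix for the precision walk.
#' @param target_precision,confidence_cutoff Cutoffs (defaults 0.5, 0.95).
#' @return Named integer vector `c(n_precision_edges, n_confidence_edges)`.
#' @export
edge_count_summaries <- function(net, standard, target_precision = 0.5,
                                 confidence_cutoff = 0.95) {
  n_prec <- tryCatch(
    nrow(threshold_by_precision(net, standard, target_precision)),
    error = function(e) 0L
  )
  c(n_precision_edges = as.integer(n_prec),
    n_confidence_edges = sum(net$combined_confidence > confidence_cutoff))
}

#' One end-to-end inference run
#'
#' Estimates activities from the prior, splits cells into per-condition
#' tasks, runs the chosen regression engine over bootstraps, rank-combines
#' within tasks and then across tasks, and returns the ranked global
#' network.
#'
#' @param x An [expression_matrix()] (cells x genes).
#' @param meta Cell metadata with `condition`.
#' @param prior A [prior_matrix()] used for TFA estimation and candidate
#'   seeding.
#' @param method `"bbsr"` (all cells as one task), `"bbsr-by-task"`
#'   (independent per-condition fits combined afterwards) or `"amusr"`
#'   (joint multitask fit).
#' @param n_bootstraps,seed,k,cap,n_bins Engine controls; see
#'   [run_bbsr_task()].
#' @param keep_task_networks Attach per-task combined confidence matrices as
#'   attribute `"task_confidences"`.
#' @return A `ranked_network` tibble for the global network.
#' @export
infer_network <- function(x, meta, prior,
                          method = c("bbsr", "bbsr-by-task", "amusr"),
                          n_bootstraps = 5L, seed = 1L, k = 10L, cap = 14L,
                          n_bins = 10L, keep_task_networks = FALSE) {
  method <- match.arg(method)
  if (method == "bbsr") {
    meta <- cell_metadata(meta, x)
    meta$condition <- "all"
  }
  tasks <- split_tasks(x, meta)
  acts <- lapply(tasks, function(tk) {
    a <- estimate_tfa(tk, prior)
    a
  })
  if (method == "amusr") {
    res <- run_amusr(tasks, acts, prior, n_bootstraps = n_bootstraps,
                     seed = seed, k = k, cap = cap, n_bins = n_bins)
  } else {
    res <- lapply(seq_along(tasks), function(t) {
      run_bbsr_task(tasks[[t]], acts[[t]], prior, n_bootstraps = n_bootstraps,
                    seed = derive_seed(seed, t), k = k, cap = cap,
                    n_bins = n_bins)
    })
    names(res) <- names(tasks)
  }
  task_conf <- lapply(res, function(r) combine_ranks(r$scores))
  global_conf <- if (length(task_conf) > 1) combine_tasks(task_conf) else task_conf[[1]]
  all_signs <- unlist(lapply(res, function(r) r$signs), recursive = FALSE)
  net <- ranked_network(global_conf, signs = all_signs, prior = prior,
                        task_presence = task_conf)
  if (keep_task_networks) attr(net, "task_confidences") <- task_conf
  net
}

#' Repeated cross-validation of network inference
#'
#' Each repeat: the gold-standard genes are split in half; the retained half
#' (removed from the evaluation) conditions the prior, activities are
#' estimated, the network is inferred and assembled, and AUPR plus edge
#' counts are scored on the held-out half with prior edges excluded.
#'
#' @param x An [expression_matrix()].
#' @param meta Cell metadata.
#' @param gs Gold standard for splitting/evaluation.
#' @param p Prior matrix (may equal `gs`).
#' @param method,n_bootstraps,k,cap,n_bins Passed to [infer_network()].
#' @param n_repeats Number of cross-validation repeats (default 10).
#' @param seed Master seed; repeat `r` derives its own split and bootstrap
#'   seeds.
#' @param shuffle Shuffle the prior half before fitting (the randomized
#'   negative control).
#' @return A `cv_result` tibble: `repeat_id`, `aupr`, `n_precision_edges`,
#'   `n_confidence_edges`.
#' @export
crossvalidate <- function(x, meta, gs, p = gs,
                          method = c("bbsr", "bbsr-by-task", "amusr"),
                          n_repeats = 10L, seed = 1L, n_bootstraps = 5L,
                          k = 10L, cap = 14L, n_bins = 10L, shuffle = FALSE) {
  method <- match.arg(method)
  rows <- lapply(seq_len(n_repeats), function(r) {
    sp <- cv_split_gold_standard(gs, p, fraction = 0.5,
                                 seed = derive_seed(seed, r))
    prior <- sp$prior_part
    if (shuffle) prior <- shuffle_prior(prior, seed = derive_seed(seed, r + 7000L))
    net <- infer_network(x, meta, prior, method = method,
                         n_bootstraps = n_bootstraps,
                         seed = derive_seed(seed, r + 3000L),
                         k = k, cap = cap, n_bins = n_bins)
    pr <- precision_recall(net, sp$eval_part, exclude = prior)
    counts <- edge_count_summaries(net, sp$eval_part)
    tibble::tibble(repeat_id = r, aupr = aupr(pr),
                   n_precision_edges = counts[["n_precision_edges"]],
                   n_confidence_edges = counts[["n_confidence_edges"]])
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cv_result", class(out)))
}

#' Negative controls for the cross-validation harness
#'
#' Runs the identical pipeline on (a) a shuffled prior (gene names randomly
#' reassigned) and (b) null-sampled counts in which each cell keeps its
#' metadata and total UMI count but the individual gene counts are redrawn
#' from a fixed transcriptome-wide gene-frequency distribution, severing any
#' gene-specific regulatory signal.
#'
#' @param counts A raw [count_matrix()] (used to build the null resample and
#'   its gene-frequency distribution).
#' @param meta Cell metadata.
#' @param gs,p Gold standard and prior as in [crossvalidate()].
#' @param method,n_repeats,seed,n_bootstraps,... Passed through.
#' @return A list with `shuffled` and `simulated` `cv_result` tibbles.
#' @export
negative_controls <- function(counts, meta, gs, p = gs,
                              method = c("bbsr", "bbsr-by-task", "amusr"),
                              n_repeats = 10L, seed = 1L, n_bootstraps = 5L,
                              ...) {
  method <- match.arg(method)
  x <- log_transform(filter_zero_variance(counts))
  shuffled <- crossvalidate(x, meta, gs, p, method = method,
                            n_repeats = n_repeats, seed = seed,
                            n_bootstraps = n_bootstraps, shuffle = TRUE, ...)
  gene_probs <- colSums(unclass(counts)) / sum(counts)
  totals <- rowSums(unclass(counts))
  null_counts <- null_count_sampler(gene_probs, totals,
                                    seed = derive_seed(seed, 99991L))
  rownames(null_counts) <- rownames(counts)
  xn <- log_transform(filter_zero_variance(null_counts))
  simulated <- crossvalidate(xn, meta, gs, p, method = method,
                             n_repeats = n_repeats, seed = seed,
                             n_bootstraps = n_bootstraps, shuffle = FALSE, ...)
  list(shuffled = shuffled, simulated = simulated)
}
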