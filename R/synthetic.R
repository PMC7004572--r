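# Synthetic benchmark: a multinomial null-count sampler (the simulated
# negative control) and a GRN-driven positive control emulating a pooled
# multi-condition experiment with genotype barcodes.

#' Sample null counts from a fixed gene-frequency distribution
#'
#' Each cell's gene counts are drawn multinomially from one shared
#' transcriptome-wide probability vector, with the cell's stated total UMI
#' count preserved exactly; marginally each gene's count is binomial
#' (total, p_gene).
#'
#' @param gene_probs Probability simplex over genes (sums to 1 within 1e-9);
#'   names become gene identifiers.
#' @param per_cell_totals Integer vector of per-cell UMI totals (>= 0);
#'   names become cell identifiers.
#' @param seed Integer seed.
#' @return A [count_matrix()], cells x genes, with row sums equal to
#'   `per_cell_totals`.
#' @export
null_count_sampler <- function(gene_probs, per_cell_totals, seed = 1L) {
  if (any(gene_probs < 0)) stop("gene probabilities must be >= 0", call. = FALSE)
  if (abs(sum(gene_probs) - 1) > 1e-9) stop("gene probabilities must sum to 1", call. = FALSE)
  if (any(per_cell_totals < 0)) stop("per-cell totals must be >= 0", call. = FALSE)
  set.seed(seed)
  n_cells <- length(per_cell_totals)
  genes <- names(gene_probs)
  if (is.null(genes)) genes <- paste0("g", seq_along(gene_probs))
  cells <- names(per_cell_totals)
  if (is.null(cells)) cells <- paste0("cell", seq_len(n_cells))
  out <- matrix(0, nrow = n_cells, ncol = length(gene_probs),
                dimnames = list(cells, genes))
  for (j in seq_len(n_cells)) {
    if (per_cell_totals[j] > 0) {
      out[j, ] <- rmultinom(1, per_cell_totals[j], gene_probs)[, 1]
    }
  }
  count_matrix(out)
}

#' Generate a sparse signed truth network and its simulation parameters
#'
#' The truth emulates a curated gold standard's structure: a sparse genes x
#' TFs signed matrix with a stated TF out-degree and an
#' activator/repressor mix, together with heavy-tailed gene base rates and a
#' per-cell depth model.
#'
#' @param n_genes,n_tfs Network dimensions.
#' @param targets_per_tf Mean targets per TF (>= 1).
#' @param activator_fraction Fraction of edges with positive sign.
#' @param seed Integer seed.
#' @return A `synthetic_truth` list: `network` (a [prior_matrix()] with
#'   entries in \{-1, 0, +1\}; TF genes are the first `n_tfs` gene ids),
#'   `base_rates` (probability simplex over genes), `gene_ids`, `tf_ids`,
#'   `seed`.
#' @export
generate_truth <- function(n_genes = 200L, n_tfs = 20L, targets_per_tf = 14L,
                           activator_fraction = 0.8, seed = 1L) {
  if (targets_per_tf < 1) stop("targets_per_tf must be >= 1", call. = FALSE)
  if (activator_fraction < 0 || activator_fraction > 1) {
    stop("activator_fraction must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  # TFs are themselves genes: TF k is gene k
  net <- matrix(0, n_genes, n_tfs, dimnames = list(gene_ids, tf_ids))
  for (k in seq_len(n_tfs)) {
    pool <- setdiff(seq_len(n_genes), k)   # no self-regulation
    targets <- sample(pool, min(targets_per_tf, length(pool)))
    sgn <- ifelse(runif(length(targets)) < activator_fraction, 1, -1)
    net[targets, k] <- sgn
  }
  base <- rlnorm(n_genes, meanlog = 0, sdlog = 1.5)
  structure(list(network = prior_matrix(net, gold_standard = TRUE),
                 base_rates = setNames(base / sum(base), gene_ids),
                 gene_ids = gene_ids, tf_ids = tf_ids, seed = seed),
            class = "synthetic_truth")
}

#' Simulate a pooled multi-condition single-cell experiment from a truth
#'
#' Per condition, each TF's activity is drawn around a condition-specific
#' mean; a cell's latent log-expression is `truth %*% activity` plus the
#' gene's base level plus Gaussian noise; rates are exponentiated,
#' normalized within the cell and downsampled multinomially to a depth
#' drawn log-normally around the condition's median. Cells are annotated
#' with condition, genotype and replicate barcode so the full preprocessing
#' path (including pseudobulk grouping) is exercised.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param n_conditions Number of growth conditions (tasks).
#' @param cells_per_condition Cells per condition.
#' @param noise_sd Gaussian noise on latent log-expression (default 0.25).
#' @param activity_sd Spread of per-cell activities around the condition
#'   mean (default 0.3); condition means are drawn N(0, 1) per TF.
#' @param median_depth Median UMI depth per cell (default 2250).
#' @param depth_sdlog Log-normal depth spread (default 0.35).
#' @param n_genotypes Genotype labels cycled over cells (default 12).
#' @param seed Integer seed.
#' @return List with `counts` (a [count_matrix()]), `meta` (metadata
#'   tibble), and `activities` (TFs x cells latent truth activities).
#' @export
simulate_expression <- function(truth, n_conditions = 3L,
                                cells_per_condition = 300L, noise_sd = 0.25,
                                activity_sd = 0.3, median_depth = 2250,
                                depth_sdlog = 0.35, n_genotypes = 12L,
                                seed = 1L) {
  stopifnot(n_conditions >= 1, cells_per_condition >= 1)
  set.seed(seed)
  net <- unclass(truth$network)
  n_genes <- length(truth$gene_ids)
  n_tfs <- length(truth$tf_ids)
  n_cells <- n_conditions * cells_per_condition
  cond_labels <- paste0("cond", seq_len(n_conditions))
  cond_means <- matrix(rnorm(n_tfs * n_conditions, sd = 1), n_tfs, n_conditions,
                       dimnames = list(truth$tf_ids, cond_labels))
  base_log <- log(truth$base_rates * n_genes)   # heavy-tailed base level
  counts <- matrix(0, n_cells, n_genes,
                   dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                   truth$gene_ids))
  activities <- matrix(0, n_tfs, n_cells,
                       dimnames = list(truth$tf_ids, rownames(counts)))
  conds <- rep(cond_labels, each = cells_per_condition)
  # condition-linked depth variation around the stated median
  cond_depth <- median_depth * exp(rnorm(n_conditions, sd = 0.15))
  for (j in seq_len(n_cells)) {
    cidx <- match(conds[j], cond_labels)
    a <- cond_means[, cidx] + rnorm(n_tfs, sd = activity_sd)
    activities[, j] <- a
    eta <- base_log + as.vector(net %*% a) + rnorm(n_genes, sd = noise_sd)
    rate <- exp(eta)
    pr <- rate / sum(rate)
    depth <- max(1L, round(rlnorm(1, meanlog = log(cond_depth[cidx]),
                                  sdlog = depth_sdlog)))
    counts[j, ] <- rmultinom(1, depth, pr)[, 1]
  }
  meta <- tibble::tibble(
    cell_id = rownames(counts),
    condition = conds,
    genotype = paste0("geno", (seq_len(n_cells) - 1L) %% n_genotypes + 1L),
    replicate_barcode = paste0("bc", (seq_len(n_cells) - 1L) %% (n_genotypes * 6L) + 1L)
  )
  list(counts = count_matrix(counts), meta = meta, activities = activities)
}

#' Compose a full synthetic benchmark bundle
#'
#' Generates a truth network, splits its genes into disjoint prior and
#' evaluation halves (mirroring the cross-validation protocol), and
#' simulates the pooled experiment, so every pipeline stage can be run and
#' scored without external data.
#'
#' @param n_genes,n_tfs,targets_per_tf,activator_fraction Truth parameters;
#'   see [generate_truth()].
#' @param n_conditions,cells_per_condition,noise_sd Simulation parameters;
#'   see [simulate_expression()].
#' @param fraction Prior/evaluation gene split (default 0.5).
#' @param seed Integer seed driving every stage.
#' @param ... Further arguments to [simulate_expression()].
#' @return List: `counts`, `meta`, `prior_part`, `eval_part`, `truth`,
#'   `activities`.
#' @export
make_benchmark <- function(n_genes = 200L, n_tfs = 20L, targets_per_tf = 14L,
                           activator_fraction = 0.8, n_conditions = 3L,
                           cells_per_condition = 300L, noise_sd = 0.25,
                           fraction = 0.5, seed = 1L, ...) {
  truth <- generate_truth(n_genes, n_tfs, targets_per_tf, activator_fraction,
                          seed = seed)
  sp <- cv_split_gold_standard(truth$network, truth$network,
                               fraction = fraction,
                               seed = derive_seed(seed, 17L))
  sim <- simulate_expression(truth, n_conditions = n_conditions,
                             cells_per_condition = cells_per_condition,
                             noise_sd = noise_sd,
                             seed = derive_seed(seed, 29L), ...)
  list(counts = sim$counts, meta = sim$meta, prior_part = sp$prior_part,
       eval_part = sp$eval_part, truth = truth, activities = sim$activities)
}
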