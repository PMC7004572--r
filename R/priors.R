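# Prior and gold-standard connectivity matrices (genes x TFs, signed),
# the shuffled-prior negative control, and the gene-level cross-validation
# split that keeps priors and evaluation edges disjoint.

#' Construct a genes x TFs prior connectivity matrix
#'
#' Entries are signed connectivity: positive for activation, negative for
#' repression, zero for no known interaction. A gold standard is a prior
#' whose entries are restricted to \{-1, 0, +1\}.
#'
#' @param values Numeric matrix, genes in rows, TFs in columns.
#' @param gene_ids,tf_ids Identifier vectors; default to dimnames.
#' @param gold_standard If `TRUE`, enforce the \{-1, 0, +1\} entry set.
#' @return A `prior_matrix` (additionally classed `gold_standard` when
#'   requested).
#' @export
prior_matrix <- function(values, gene_ids = rownames(values),
                         tf_ids = colnames(values), gold_standard = FALSE) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(tf_ids)) {
    stop("prior_matrix requires gene and TF identifiers", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(tf_ids)) stop("duplicate TF identifiers", call. = FALSE)
  if (!all(is.finite(values))) stop("prior entries must be finite", call. = FALSE)
  if (gold_standard && !all(values %in% c(-1, 0, 1))) {
    stop("gold standard entries must be in {-1, 0, 1}", call. = FALSE)
  }
  dimnames(values) <- list(as.character(gene_ids), as.character(tf_ids))
  cls <- c(if (gold_standard) "gold_standard", "prior_matrix", class(matrix()))
  class(values) <- cls
  values
}

is_gold_standard <- function(x) inherits(x, "gold_standard")

#' Read a genes x TFs network matrix from adjacency TSV
#'
#' The TSV has gene identifiers in the first column and TF identifiers in the
#' header row.
#'
#' @param path TSV file.
#' @param gold_standard Validate the \{-1, 0, +1\} entry set.
#' @return A [prior_matrix()].
#' @export
read_network_matrix <- function(path, gold_standard = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "")
  gene_ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  prior_matrix(vals, gene_ids = gene_ids, tf_ids = colnames(vals),
               gold_standard = gold_standard)
}

#' Write a network matrix as adjacency TSV
#'
#' @param p A [prior_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_matrix <- function(p, path) {
  df <- data.frame(gene_id = rownames(p), check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(unclass(p), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Shuffle a prior by randomly reassigning gene names
#'
#' The negative control for prior-guided inference: gene labels are permuted
#' uniformly at random so every edge points at a random gene, while TF labels
#' and all connectivity values are untouched. Per-TF column sums and the
#' global edge count are preserved exactly.
#'
#' @param p A [prior_matrix()].
#' @param seed Integer seed.
#' @return A [prior_matrix()] with permuted gene labels.
#' @export
shuffle_prior <- function(p, seed = 1L) {
  if (nrow(p) < 2) stop("need at least two genes to shuffle", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(nrow(p))
  out <- unclass(p)
  rownames(out) <- rownames(p)[perm]
  out <- out[rownames(p), , drop = FALSE]  # restore canonical row order
  prior_matrix(out, gold_standard = is_gold_standard(p))
}

#' Split a gold standard into prior and evaluation halves by gene
#'
#' Cross-validation splits the gold-standard *genes* (not edges) at random:
#' the held-out genes' interactions form the evaluation set, and every
#' held-out gene's row is removed from the prior so no evaluated interaction
#' can leak into fitting. When the prior is the gold standard itself, the
#' retained half serves as the prior.
#'
#' @param gs A gold-standard [prior_matrix()].
#' @param p The prior to be used for fitting (may be `gs` itself).
#' @param fraction Fraction of gold-standard genes retained for the prior
#'   side (default 0.5); must be in (0, 1). With an odd gene count the
#'   retained half receives the extra gene.
#' @param seed Integer seed.
#' @return List with `prior_part` (a [prior_matrix()]) and `eval_part`
#'   (a gold standard restricted to held-out genes).
#' @export
cv_split_gold_standard <- function(gs, p, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)", call. = FALSE)
  gs_genes <- rownames(gs)
  if (length(gs_genes) == 0 || all(unclass(gs) == 0)) {
    stop("gold standard is empty", call. = FALSE)
  }
  set.seed(seed)
  n_keep <- ceiling(length(gs_genes) * fraction)
  keep <- sort(sample(gs_genes, n_keep))
  held_out <- setdiff(gs_genes, keep)
  eval_part <- prior_matrix(unclass(gs)[held_out, , drop = FALSE],
                            gold_standard = TRUE)
  same_matrix <- identical(dim(p), dim(gs)) &&
    identical(dimnames(p), dimnames(gs)) &&
    all(unclass(p) == unclass(gs))
  if (same_matrix) {
    prior_part <- prior_matrix(unclass(gs)[keep, , drop = FALSE])
  } else {
    keep_rows <- setdiff(rownames(p), held_out)
    prior_part <- prior_matrix(unclass(p)[keep_rows, , drop = FALSE])
  }
  list(prior_part = prior_part, eval_part = eval_part)
}
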