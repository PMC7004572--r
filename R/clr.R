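# Mutual-information / context-likelihood-of-relatedness (CLR) scoring used
# to preselect candidate regulators per gene before best-subset regression.

discretize_equal_width <- function(v, n_bins) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  b <- floor((v - r[1]) / (r[2] - r[1]) * n_bins) + 1L
  b[b > n_bins] <- n_bins
  as.integer(b)
}

#' Mutual information of two sample vectors (equal-width binning)
#'
#' Both vectors are discretized into `n_bins` equal-width bins over their own
#' observed range and the mutual information of the joint histogram is
#' returned in bits. A constant vector carries no information and gives 0.
#'
#' @param u,v Numeric vectors of equal length (>= `n_bins`).
#' @param n_bins Number of bins per variable (default 10, the conventional
#'   CLR choice).
#' @return Mutual information in bits (non-negative, symmetric).
#' @export
mutual_information <- function(u, v, n_bins = 10L) {
  if (length(u) != length(v)) stop("u and v must have equal length", call. = FALSE)
  if (length(u) < n_bins) stop("need at least n_bins samples", call. = FALSE)
  bu <- discretize_equal_width(u, n_bins)
  bv <- discretize_equal_width(v, n_bins)
  mi_from_bins(bu, bv, n_bins)
}

mi_from_bins <- function(bu, bv, n_bins) {
  n <- length(bu)
  joint <- tabulate(bu + n_bins * (bv - 1L), nbins = n_bins * n_bins) / n
  pu <- tabulate(bu, nbins = n_bins) / n
  pv <- tabulate(bv, nbins = n_bins) / n
  outer_p <- as.vector(outer(pu, pv))
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

#' Mutual-information matrix between regulators and genes
#'
#' @param activities TFs x samples activity matrix.
#' @param expression samples x genes expression matrix.
#' @param n_bins Bins per variable.
#' @return TFs x genes matrix of mutual information in bits.
#' @export
mi_matrix <- function(activities, expression, n_bins = 10L) {
  act_bins <- apply(activities, 1L, discretize_equal_width, n_bins = n_bins)
  expr_bins <- apply(expression, 2L, discretize_equal_width, n_bins = n_bins)
  # both are samples x (TFs | genes) after apply
  out <- matrix(0, nrow = nrow(activities), ncol = ncol(expression),
                dimnames = list(rownames(activities), colnames(expression)))
  for (k in seq_len(nrow(activities))) {
    bu <- act_bins[, k]
    for (i in seq_len(ncol(expression))) {
      out[k, i] <- mi_from_bins(bu, expr_bins[, i], n_bins)
    }
  }
  out
}

#' Context likelihood of relatedness scores from a mutual-information matrix
#'
#' Standardizes each mutual-information value against its regulator-row and
#' gene-column backgrounds, clamps negative z-scores to zero, and combines
#' them as a root sum of squares. Adding a constant to every entry leaves the
#' result unchanged.
#'
#' @param mi TFs x genes mutual-information matrix (finite, non-negative).
#' @return TFs x genes matrix of non-negative CLR scores.
#' @export
clr_matrix <- function(mi) {
  if (!all(is.finite(mi)) || any(mi < 0)) {
    stop("mutual-information matrix must be finite and non-negative", call. = FALSE)
  }
  zscore <- function(m, margin) {
    mu <- apply(m, margin, mean)
    s <- apply(m, margin, sd)
    s[is.na(s) | s == 0] <- Inf   # constant background: z-score 0
    sweep(sweep(m, margin, mu, "-"), margin, s, "/")
  }
  zr <- pmax(zscore(mi, 1L), 0)
  zc <- pmax(zscore(mi, 2L), 0)
  sqrt(zr^2 + zc^2)
}

#' Select candidate regulators for one gene
#'
#' The candidate set is the top `k` TFs by CLR score (ties broken by TF
#' identifier order) plus every a priori known regulator of the gene, with
#' the gene's own TF (self-regulation) excluded.
#'
#' @param z_row Named vector of CLR scores for the gene (one per TF).
#' @param prior_row Named vector of prior connectivity for the gene (nonzero
#'   entries mark known regulators); may be `NULL`.
#' @param k Number of top-CLR TFs to keep (default 10).
#' @param self_tf Optional TF identifier equal to the gene itself, removed
#'   from the candidates.
#' @return Character vector of selected TF identifiers, in TF-id order.
#' @export
select_regulators <- function(z_row, prior_row = NULL, k = 10L, self_tf = NULL) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  tfs <- names(z_row)
  if (is.null(tfs)) stop("z_row must be named by TF", call. = FALSE)
  ord <- order(-z_row, tfs)   # ties by TF-id order
  top <- tfs[ord][seq_len(min(k, length(tfs)))]
  known <- character(0)
  if (!is.null(prior_row)) known <- names(prior_row)[prior_row != 0]
  sel <- union(top, known)
  sel <- setdiff(sel, self_tf)
  sel[order(match(sel, tfs))]
}
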