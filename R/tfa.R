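# Latent transcription-factor activity (TFA) estimation: expression is
# modelled as X = P A with X genes x cells, P the genes x TFs prior
# connectivity and A the TFs x cells activities; A is recovered as the
# minimum-norm least-squares solution.

#' Estimate transcription-factor activities from expression and a prior
#'
#' Solves the overdetermined linear system `X = P A` for the latent activity
#' matrix `A` in the least-squares sense, using the Moore-Penrose
#' pseudoinverse of `P` so that rank-deficient connectivity (for example
#' duplicate TF columns) yields the minimum-norm solution rather than
#' failing. A TF with no prior targets falls back to its own expression as a
#' proxy for its activity (zeros when the TF gene is absent from the
#' expression matrix). Genes are aligned by identifier; the intersection of
#' the expression and prior gene sets is used.
#'
#' @param x An [expression_matrix()] (cells x genes, log2 units).
#' @param p A [prior_matrix()] (genes x TFs).
#' @return An `activity_matrix`: TFs x cells matrix with TF and cell
#'   identifiers, additionally carrying attribute `"dropped_genes"` listing
#'   prior genes absent from the expression matrix.
#' @export
estimate_tfa <- function(x, p) {
  genes <- intersect(colnames(x), rownames(p))
  if (length(genes) == 0) stop("no genes shared between expression and prior", call. = FALSE)
  if (ncol(p) < 1) stop("prior has no TFs", call. = FALSE)
  dropped <- setdiff(rownames(p), genes)
  P <- unclass(p)[genes, , drop = FALSE]
  X <- t(unclass(x))[genes, , drop = FALSE]    # genes x cells
  zero_col <- colSums(P != 0) == 0
  A <- matrix(0, nrow = ncol(P), ncol = ncol(X),
              dimnames = list(colnames(P), colnames(X)))
  if (any(!zero_col)) {
    Psub <- P[, !zero_col, drop = FALSE]
    A[!zero_col, ] <- MASS::ginv(Psub) %*% X
  }
  if (any(zero_col)) {
    for (tf in colnames(P)[zero_col]) {
      if (tf %in% colnames(x)) A[tf, ] <- unclass(x)[, tf]
    }
  }
  structure(A, dropped_genes = dropped,
            class = c("activity_matrix", class(matrix())))
}
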