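# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @export
tidy.gene_model <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id,
    tf_id = x$regulators,
    estimate = unname(x$beta[x$regulators]),
    var_exp = unname(x$var_exp[x$regulators])
  )
}

#' @export
glance.gene_model <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_id, n_regulators = length(x$regulators),
                 bic = x$bic, rss = x$rss, r2 = x$r2)
}

#' @export
tidy.multitask_gene_model <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame.table(x$W, stringsAsFactors = FALSE))
  names(out) <- c("tf_id", "task", "estimate")
  out$shared <- as.vector(x$B != 0)
  out$specific <- as.vector(x$S != 0)
  out[out$estimate != 0, ]
}

#' @export
glance.multitask_gene_model <- function(x, ...) {
  tibble::tibble(n_tasks = ncol(x$W), n_nonzero = sum(x$W != 0),
                 lambda_s = x$lambda_s, lambda_b = x$lambda_b, ebic = x$ebic,
                 n_iterations = length(x$objective) - 1L)
}

#' @export
tidy.ranked_network <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.ranked_network <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x),
                 n_in_prior = sum(x$in_prior),
                 n_activating = sum(x$sign > 0),
                 n_repressing = sum(x$sign < 0),
                 max_confidence = if (nrow(x)) max(x$combined_confidence) else NA_real_)
}

#' @export
tidy.cv_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(n_repeats = nrow(x), mean_aupr = mean(x$aupr),
                 sd_aupr = sd(x$aupr),
                 mean_precision_edges = mean(x$n_precision_edges),
                 mean_confidence_edges = mean(x$n_confidence_edges))
}

#' @export
tidy.pr_curve <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.pr_curve <- function(x, ...) {
  tibble::tibble(n_ranked = nrow(x), n_positives = attr(x, "n_positives"),
                 aupr = aupr(x))
}

#' Plot a precision-recall curve
#'
#' @param object A `pr_curve` from [precision_recall()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  subtitle = sprintf("AUPR = %.3f", aupr(object))) +
    ggplot2::theme_minimal()
}

#' Plot per-repeat cross-validation AUPRs
#'
#' @param object A `cv_result` from [crossvalidate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(1), y = .data$aupr)) +
    ggplot2::geom_jitter(width = 0.05, colour = "grey50") +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
                          fun.args = list(mult = 1), colour = "black") +
    ggplot2::labs(x = NULL, y = "AUPR") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot the confidence profile of a ranked network
#'
#' Combined confidence against edge rank, with the prior membership of each
#' edge marked.
#'
#' @param object A `ranked_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranked_network <- function(object, ...) {
  df <- tibble::tibble(rank = seq_len(nrow(object)),
                       confidence = object$combined_confidence,
                       in_prior = object$in_prior)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$confidence,
                                   colour = .data$in_prior)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "Edge rank", y = "Combined confidence",
                  colour = "In prior") +
    ggplot2::theme_minimal()
}
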