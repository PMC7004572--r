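# Bootstrap orchestration and network assembly: rank combination of edge
# scores within and across tasks, sign assignment, precision thresholding,
# and TSV/GEXF output.

derive_seed <- function(seed, b) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(b) * 104729) %% 2147483647)
}

#' Bootstrap index vectors
#'
#' Draws `n_boot` resamples of `1:n` with replacement; resample `b` is
#' generated from a seed derived deterministically from `(seed, b)`, so any
#' single bootstrap is reproducible in isolation.
#'
#' @param n Number of samples (>= 1).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer master seed.
#' @return List of `n_boot` integer vectors, each of length `n`.
#' @export
bootstrap_indices <- function(n, n_boot, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  lapply(seq_len(n_boot), function(b) {
    set.seed(derive_seed(seed, b))
    sample.int(n, n, replace = TRUE)
  })
}

#' Rank-combine edge-score matrices into confidences
#'
#' Each input matrix is converted to ranks over all its entries (average
#' rank for ties, the highest score receiving the highest rank); ranks are
#' summed across inputs and min-max normalized to `[0, 1]`. The result is
#' invariant under any strictly increasing transform of any input.
#'
#' @param scores List of genes x TFs score matrices sharing axes.
#' @return A genes x TFs combined-confidence matrix in `[0, 1]`.
#' @export
combine_ranks <- function(scores) {
  if (!length(scores)) stop("no score matrices to combine", call. = FALSE)
  dn <- dimnames(scores[[1]])
  dm <- dim(scores[[1]])
  for (s in scores) {
    if (!identical(dim(s), dm) || !identical(dimnames(s), dn)) {
      stop("score matrices do not share axes", call. = FALSE)
    }
  }
  total <- Reduce(`+`, lapply(scores, function(s) rank(as.vector(s), ties.method = "average")))
  rng <- range(total)
  conf <- if (rng[1] == rng[2]) rep(0, length(total)) else (total - rng[1]) / (rng[2] - rng[1])
  matrix(conf, nrow = dm[1], ncol = dm[2], dimnames = dn)
}

#' Rank-combine per-task confidence matrices into a global network matrix
#'
#' Identical mechanics to [combine_ranks()], applied across the task-level
#' combined matrices.
#'
#' @param per_task_confidences List of per-task genes x TFs confidence
#'   matrices.
#' @return A global genes x TFs confidence matrix in `[0, 1]`.
#' @export
combine_tasks <- function(per_task_confidences) combine_ranks(per_task_confidences)

#' Build a ranked network from confidences, signs and supporting evidence
#'
#' Edges with zero confidence are treated as absent. Edges are ordered by
#' decreasing combined confidence with `(tf_id, gene_id)` lexicographic
#' tie-breaks. The sign of an edge is the sign of the mean coefficient sign
#' across bootstraps/tasks.
#'
#' @param confidence Genes x TFs combined-confidence matrix.
#' @param signs Optional list of genes x TFs sign matrices (averaged).
#' @param prior Optional [prior_matrix()] to flag `in_prior` edges.
#' @param task_presence Optional named list of per-task genes x TFs score (or
#'   confidence) matrices; an edge is flagged present in a task when its
#'   entry is positive.
#' @return A `ranked_network` tibble: `tf_id`, `gene_id`,
#'   `combined_confidence`, `sign`, `in_prior`, plus one logical
#'   `task_<name>` column per task.
#' @export
ranked_network <- function(confidence, signs = NULL, prior = NULL,
                           task_presence = NULL) {
  genes <- rownames(confidence); tfs <- colnames(confidence)
  keep <- which(confidence > 0, arr.ind = TRUE)
  net <- tibble::tibble(
    tf_id = tfs[keep[, 2]],
    gene_id = genes[keep[, 1]],
    combined_confidence = confidence[keep]
  )
  if (!is.null(signs) && length(signs)) {
    mean_sign <- Reduce(`+`, signs) / length(signs)
    net$sign <- sign(mean_sign[keep])
  } else {
    net$sign <- 0
  }
  net$in_prior <- FALSE
  if (!is.null(prior)) {
    pg <- rownames(prior); pt <- colnames(prior)
    ok <- net$gene_id %in% pg & net$tf_id %in% pt
    net$in_prior[ok] <- unclass(prior)[cbind(net$gene_id[ok], net$tf_id[ok])] != 0
  }
  if (!is.null(task_presence)) {
    tn <- names(task_presence)
    if (is.null(tn)) tn <- paste0("task", seq_along(task_presence))
    for (t in seq_along(task_presence)) {
      net[[paste0("task_", tn[t])]] <- task_presence[[t]][keep] > 0
    }
  }
  net <- net[order(-net$combined_confidence, net$tf_id, net$gene_id), ]
  structure(net, class = c("ranked_network", class(net)))
}

#' Keep the top of a ranked network to a precision threshold
#'
#' Walks the ranked edge list, computing precision at each rank against the
#' standard, restricted to the standard's gene x TF universe, and keeps the
#' longest prefix whose terminal precision is at least `target_precision`.
#' Edges outside the standard's universe are retained whenever they rank
#' above the cutoff confidence.
#'
#' @param net A `ranked_network` tibble.
#' @param standard A [prior_matrix()] or gold standard defining known
#'   interactions.
#' @param target_precision Precision threshold (default 0.5).
#' @return The thresholded `ranked_network`, with the attained `precision`
#'   and the cutoff confidence as attributes.
#' @export
threshold_by_precision <- function(net, standard, target_precision = 0.5) {
  in_univ <- net$gene_id %in% rownames(standard) & net$tf_id %in% colnames(standard)
  if (!any(in_univ)) stop("no ranked edge lies in the standard's universe", call. = FALSE)
  sub <- net[in_univ, ]
  hit <- unclass(standard)[cbind(sub$gene_id, sub$tf_id)] != 0
  prec <- cumsum(hit) / seq_along(hit)
  ok <- which(prec >= target_precision)
  if (!length(ok)) {
    out <- net[0, ]
    attr(out, "precision") <- NA_real_
    attr(out, "cutoff") <- Inf
    return(out)
  }
  last <- max(ok)
  cutoff <- sub$combined_confidence[last]
  out <- net[net$combined_confidence >= cutoff, ]
  attr(out, "precision") <- prec[last]
  attr(out, "cutoff") <- cutoff
  out
}

#' Write a ranked network to TSV or GEXF
#'
#' The TSV round-trips losslessly through [read_network()]; the GEXF form is
#' a directed graph with confidence, sign and prior-membership edge
#' attributes, suitable for Gephi.
#'
#' @param net A `ranked_network` tibble.
#' @param path Output file.
#' @param fmt `"tsv"` or `"gexf"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, fmt = c("tsv", "gexf")) {
  fmt <- match.arg(fmt)
  if (fmt == "tsv") {
    df <- as.data.frame(net)
    names(df)[names(df) == "tf_id"] <- "regulator"
    names(df)[names(df) == "gene_id"] <- "target"
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    return(invisible(path))
  }
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "confidence", type = "double")
  xml2::xml_add_child(attrs, "attribute", id = "1", title = "sign", type = "integer")
  xml2::xml_add_child(attrs, "attribute", id = "2", title = "in_prior", type = "boolean")
  nodes <- xml2::xml_add_child(graph, "nodes")
  for (id in unique(c(net$tf_id, net$gene_id))) {
    xml2::xml_add_child(nodes, "node", id = id, label = id)
  }
  edges <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(net))) {
    e <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                             source = net$tf_id[i], target = net$gene_id[i],
                             weight = format(net$combined_confidence[i]))
    av <- xml2::xml_add_child(e, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0",
                        value = format(net$combined_confidence[i]))
    xml2::xml_add_child(av, "attvalue", "for" = "1",
                        value = as.character(as.integer(net$sign[i])))
    xml2::xml_add_child(av, "attvalue", "for" = "2",
                        value = tolower(as.character(net$in_prior[i])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a ranked network written by [write_network()] (TSV form)
#'
#' @param path TSV file.
#' @return A `ranked_network` tibble.
#' @export
read_network <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  names(df)[names(df) == "regulator"] <- "tf_id"
  names(df)[names(df) == "target"] <- "gene_id"
  net <- tibble::as_tibble(df)
  structure(net, class = c("ranked_network", class(net)))
}
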