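# Core containers: cells x genes UMI counts, log2 expression, per-cell
# metadata, and the preprocessing steps applied before inference.

#' Construct a cells x genes UMI count matrix
#'
#' Validates and tags an integer matrix of unique-molecular-identifier (UMI)
#' counts with cells in rows and genes in columns. All downstream alignment
#' is by identifier, never by position.
#'
#' @param values Numeric matrix, cells in rows, genes in columns. All entries
#'   must be non-negative integers.
#' @param cell_ids,gene_ids Character vectors of unique identifiers matching
#'   the matrix dimensions. Defaults to the dimnames of `values`.
#' @return A `count_matrix`: an integer-valued matrix with class
#'   `"count_matrix"` and identifier dimnames.
#' @export
count_matrix <- function(values, cell_ids = rownames(values),
                         gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(cell_ids) || is.null(gene_ids)) {
    stop("count_matrix requires cell and gene identifiers", call. = FALSE)
  }
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers", call. = FALSE)
  if (anyNA(values) || any(values < 0) || any(values != round(values))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_ids))
  class(values) <- c("count_matrix", class(matrix()))
  values
}

#' Construct a cells x genes expression matrix (log2 units)
#'
#' @param values Numeric matrix of finite values, cells in rows.
#' @param cell_ids,gene_ids Identifier vectors; default to dimnames.
#' @return An `expression_matrix` with identifier dimnames.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(cell_ids) || is.null(gene_ids)) {
    stop("expression_matrix requires cell and gene identifiers", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers", call. = FALSE)
  if (!all(is.finite(values))) stop("expression values must be finite", call. = FALSE)
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_ids))
  class(values) <- c("expression_matrix", class(matrix()))
  values
}

is_count_matrix <- function(x) inherits(x, "count_matrix")
is_expression_matrix <- function(x) inherits(x, "expression_matrix")

retag <- function(values, template) {
  class(values) <- class(template)
  values
}

#' Validate per-cell metadata against a count matrix
#'
#' Metadata is a tibble with one row per cell carrying the experimental
#' annotations: growth condition, genotype and the transcribed strain
#' (replicate) barcode.
#'
#' @param meta A data frame with at least a `cell_id` column; `condition`,
#'   `genotype` and `replicate_barcode` columns are used when present.
#' @param counts Optional `count_matrix` to check for exact one-to-one
#'   correspondence of cells.
#' @return The metadata as a tibble, invisibly validated.
#' @export
cell_metadata <- function(meta, counts = NULL) {
  meta <- tibble::as_tibble(meta)
  if (!"cell_id" %in% names(meta)) stop("metadata must have a cell_id column", call. = FALSE)
  meta$cell_id <- as.character(meta$cell_id)
  if (anyDuplicated(meta$cell_id)) stop("duplicate cell_id in metadata", call. = FALSE)
  if (!is.null(counts)) {
    if (!setequal(meta$cell_id, rownames(counts)) ||
        nrow(meta) != nrow(counts)) {
      stop("metadata cells do not match count matrix cells one-to-one", call. = FALSE)
    }
  }
  meta
}

#' Read a UMI count matrix from disk
#'
#' Two on-disk dialects are supported: a dense TSV with the first column
#' holding cell identifiers and a header row of gene identifiers, and a
#' MatrixMarket-style triplet with `barcodes.tsv` / `features.tsv` sidecars.
#' Metadata columns (`condition`, `genotype`, `replicate_barcode`) embedded in
#' a dense TSV are split off and returned separately.
#'
#' @param path For `fmt = "dense-tsv"`, the TSV file. For `fmt = "triplet"`,
#'   the `.mtx` file; sidecar files `barcodes.tsv` and `features.tsv` must sit
#'   next to it (one identifier per line, cells and genes respectively).
#' @param fmt `"dense-tsv"` or `"triplet"`.
#' @return A list with elements `counts` (a [count_matrix()]) and `meta`
#'   (a metadata tibble, or `NULL` when no metadata columns are present).
#' @export
read_count_matrix <- function(path, fmt = c("dense-tsv", "triplet")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (fmt == "dense-tsv") {
    tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "")
    if (ncol(tab) < 2) stop("parse error: dense TSV needs a cell id column plus gene columns (header line)", call. = FALSE)
    cell_ids <- as.character(tab[[1]])
    tab <- tab[, -1, drop = FALSE]
    meta_cols <- intersect(c("condition", "genotype", "replicate_barcode"), names(tab))
    meta <- NULL
    if (length(meta_cols)) {
      meta <- tibble::tibble(cell_id = cell_ids)
      for (mc in meta_cols) meta[[mc]] <- as.character(tab[[mc]])
      tab <- tab[, setdiff(names(tab), meta_cols), drop = FALSE]
    }
    vals <- as.matrix(tab)
    if (!is.numeric(vals)) {
      bad <- names(tab)[!vapply(tab, is.numeric, logical(1))][1]
      stop("parse error: non-numeric count column '", bad, "'", call. = FALSE)
    }
    counts <- count_matrix(vals, cell_ids = cell_ids, gene_ids = colnames(vals))
    return(list(counts = counts, meta = meta))
  }
  dir <- dirname(path)
  bc_file <- file.path(dir, "barcodes.tsv")
  ft_file <- file.path(dir, "features.tsv")
  if (!file.exists(bc_file) || !file.exists(ft_file)) {
    stop("triplet format requires barcodes.tsv and features.tsv beside the mtx file", call. = FALSE)
  }
  m <- Matrix::readMM(path)
  cells <- readLines(bc_file)
  genes <- readLines(ft_file)
  # stored genes x cells per the 10x convention; transpose to cells x genes
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    m <- Matrix::t(m)
  } else if (!(nrow(m) == length(cells) && ncol(m) == length(genes))) {
    stop("triplet matrix dimensions match neither sidecar file", call. = FALSE)
  }
  counts <- count_matrix(as.matrix(m), cell_ids = cells, gene_ids = genes)
  list(counts = counts, meta = NULL)
}

#' Write a count matrix as dense TSV
#'
#' Inverse of [read_count_matrix()] for the dense dialect; metadata columns
#' are interleaved after the cell id column when supplied so a single file
#' round-trips both.
#'
#' @param counts A [count_matrix()].
#' @param path Output file.
#' @param meta Optional metadata tibble to embed.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, meta = NULL) {
  df <- data.frame(cell_id = rownames(counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    meta <- cell_metadata(meta, counts)
    meta <- meta[match(rownames(counts), meta$cell_id), ]
    for (mc in setdiff(names(meta), "cell_id")) df[[mc]] <- meta[[mc]]
  }
  df <- cbind(df, as.data.frame(unclass(counts), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove genes with zero variance across cells
#'
#' Genes whose values are constant over all cells carry no information for
#' inference and are dropped; the cell axis and the relative gene order are
#' preserved.
#'
#' @param m A [count_matrix()] or [expression_matrix()].
#' @return The same type with constant genes removed.
#' @export
filter_zero_variance <- function(m) {
  if (nrow(m) < 1) stop("need at least one cell", call. = FALSE)
  v <- matrixStats_colVars(m)
  keep <- v > 0
  if (!any(keep)) stop("no variable genes", call. = FALSE)
  retag(unclass(m)[, keep, drop = FALSE], m)
}

# column variances without an extra dependency
matrixStats_colVars <- function(m) {
  m <- unclass(m)
  n <- nrow(m)
  if (n == 1) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  colSums(m^2) / (n - 1) - mu^2 * n / (n - 1)
}

#' Log-scale a count matrix
#'
#' Applies the `log2(x + 1)` transform entrywise, the only transformation
#' applied to counts before activity estimation and regression.
#'
#' @param m A [count_matrix()].
#' @return An [expression_matrix()] of the same shape.
#' @export
log_transform <- function(m) {
  if (!is_count_matrix(m)) stop("log_transform expects a count_matrix", call. = FALSE)
  expression_matrix(log2(unclass(m) + 1))
}

#' Sum single-cell counts into pseudobulk samples
#'
#' Raw UMI counts of all cells sharing a key combination (for instance
#' genotype x replicate barcode within a condition) are summed into one
#' bulk-like sample. Defined on raw counts only; the grand total of counts is
#' conserved.
#'
#' @param m A [count_matrix()] of raw counts.
#' @param meta Metadata tibble with one row per cell.
#' @param keys Character vector of metadata columns to group by.
#' @return A [count_matrix()] with one row per observed key combination,
#'   row-named by the key values joined with `"."`. The grouping table is
#'   attached as attribute `"groups"`.
#' @export
pseudobulk_aggregate <- function(m, meta, keys) {
  if (!is_count_matrix(m)) {
    stop("pseudobulk aggregation is defined on raw counts only", call. = FALSE)
  }
  meta <- cell_metadata(meta, m)
  missing_keys <- setdiff(keys, names(meta))
  if (length(missing_keys)) {
    stop("metadata lacks key column(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  meta <- meta[match(rownames(m), meta$cell_id), ]
  key_vals <- do.call(paste, c(lapply(keys, function(k) meta[[k]]), sep = "."))
  groups <- unique(key_vals)
  out <- rowsum(unclass(m), group = factor(key_vals, levels = groups))
  grp_tab <- tibble::as_tibble(meta[match(groups, key_vals), keys, drop = FALSE])
  grp_tab$sample_id <- groups
  res <- count_matrix(out, cell_ids = groups, gene_ids = colnames(m))
  attr(res, "groups") <- grp_tab
  res
}

#' Split an expression matrix into per-condition tasks
#'
#' Each growth condition's cells become one task for (multi)task network
#' inference; the tasks partition the cells exactly.
#'
#' @param x An [expression_matrix()] (cells x genes).
#' @param meta Metadata tibble with `cell_id` and `condition` columns.
#' @return A named list of class `task_set`; each element is the
#'   [expression_matrix()] restricted to that condition's cells, in input
#'   cell order.
#' @export
split_tasks <- function(x, meta) {
  meta <- cell_metadata(meta, x)
  if (!"condition" %in% names(meta)) stop("metadata lacks a condition column", call. = FALSE)
  cond <- meta$condition[match(rownames(x), meta$cell_id)]
  bad <- rownames(x)[is.na(cond) | !nzchar(cond)]
  if (length(bad)) {
    stop("cells without a condition label: ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  conds <- unique(cond)
  tasks <- lapply(conds, function(cc) {
    retag(unclass(x)[cond == cc, , drop = FALSE], x)
  })
  names(tasks) <- conds
  structure(tasks, class = "task_set")
}
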