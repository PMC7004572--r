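# Genotype demultiplexing from transcribed strain barcodes: assignment,
# doublet flagging, and the closed-form / simulated removal rate.

#' Assign genotypes from strain-barcode UMI support
#'
#' Each droplet ("cell") carries UMI counts supporting zero or more strain
#' barcodes. A cell with sufficient support for exactly one barcode is
#' assigned that barcode's genotype; support for two or more barcodes marks a
#' doublet (two cells in one droplet), which is removed downstream; no
#' support leaves the cell unassigned.
#'
#' @param barcode_table Tibble/data frame with columns `cell_id`,
#'   `replicate_barcode`, `umi_count` (long form; zero-count rows allowed).
#' @param strain_table Tibble/data frame mapping `replicate_barcode` to
#'   `genotype`.
#' @param min_umi Minimum UMI count for a barcode to count as supported
#'   (default 1: any detected second barcode flags a doublet).
#' @return Tibble with columns `cell_id` and `label`; `label` is the
#'   genotype, `"DOUBLET"` or `"UNASSIGNED"`.
#' @export
assign_genotypes <- function(barcode_table, strain_table, min_umi = 1L) {
  if (min_umi < 1) stop("min_umi must be >= 1", call. = FALSE)
  bt <- tibble::as_tibble(barcode_table)
  st <- tibble::as_tibble(strain_table)
  stopifnot(all(c("cell_id", "replicate_barcode", "umi_count") %in% names(bt)),
            all(c("replicate_barcode", "genotype") %in% names(st)))
  if (any(bt$umi_count < 0)) stop("barcode UMI counts must be >= 0", call. = FALSE)
  unknown <- setdiff(unique(bt$replicate_barcode), st$replicate_barcode)
  if (length(unknown)) {
    stop("barcode(s) not in strain table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  supported <- bt[bt$umi_count >= min_umi, , drop = FALSE]
  per_cell <- dplyr::summarise(
    dplyr::group_by(supported, .data$cell_id),
    n_bc = dplyr::n_distinct(.data$replicate_barcode),
    barcode = .data$replicate_barcode[1],
    .groups = "drop"
  )
  all_cells <- unique(bt$cell_id)
  out <- tibble::tibble(cell_id = all_cells)
  out <- dplyr::left_join(out, per_cell, by = "cell_id")
  geno <- st$genotype[match(out$barcode, st$replicate_barcode)]
  out$label <- dplyr::case_when(
    is.na(out$n_bc) ~ "UNASSIGNED",
    out$n_bc >= 2 ~ "DOUBLET",
    TRUE ~ geno
  )
  out[, c("cell_id", "label")]
}

#' Expected doublet-removal probability for a barcoded pool
#'
#' Two cells drawn independently and uniformly from a pool of `n_barcodes`
#' barcoded strains collide (share a barcode, so the doublet escapes
#' detection) with probability 1/n; the doublet is detectable with
#' probability (n - 1)/n.
#'
#' @param n_barcodes Number of distinct strain barcodes in the pool (>= 1).
#' @return The removal probability (n - 1)/n.
#' @export
expected_doublet_removal <- function(n_barcodes) {
  if (length(n_barcodes) != 1 || is.na(n_barcodes) || n_barcodes < 1 ||
      n_barcodes != round(n_barcodes)) {
    stop("n_barcodes must be a single integer >= 1", call. = FALSE)
  }
  (n_barcodes - 1) / n_barcodes
}

#' Simulate two-cell droplets and measure the doublet-removal fraction
#'
#' Draws `n_droplets` doublets, each composed of two cells with barcodes
#' drawn independently and uniformly from the pool, runs them through
#' [assign_genotypes()], and reports the fraction flagged `DOUBLET`.
#'
#' @param n_barcodes Pool size.
#' @param n_droplets Number of simulated two-cell droplets (>= 1).
#' @param seed Integer seed; the result is reproducible per seed.
#' @param umi_per_cell UMI support generated per member cell (default 5).
#' @return Observed removal fraction in `[0, 1]`.
#' @export
simulate_doublets <- function(n_barcodes, n_droplets, seed = 1L,
                              umi_per_cell = 5L) {
  if (n_droplets < 1) stop("n_droplets must be >= 1", call. = FALSE)
  set.seed(seed)
  b1 <- sample.int(n_barcodes, n_droplets, replace = TRUE)
  b2 <- sample.int(n_barcodes, n_droplets, replace = TRUE)
  bcs <- paste0("bc", seq_len(n_barcodes))
  strain_table <- tibble::tibble(replicate_barcode = bcs,
                                 genotype = paste0("geno", seq_len(n_barcodes)))
  cell_ids <- paste0("drop", seq_len(n_droplets))
  bt <- tibble::tibble(
    cell_id = rep(cell_ids, 2L),
    replicate_barcode = bcs[c(b1, b2)],
    umi_count = rep(as.integer(umi_per_cell), 2L * n_droplets)
  )
  # collapse duplicate (cell, barcode) rows so same-barcode doublets present
  # one supported barcode, exactly as the demultiplexer would see them
  bt <- dplyr::summarise(
    dplyr::group_by(bt, .data$cell_id, .data$replicate_barcode),
    umi_count = sum(.data$umi_count), .groups = "drop"
  )
  labels <- assign_genotypes(bt, strain_table, min_umi = 1L)
  mean(labels$label == "DOUBLET")
}
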