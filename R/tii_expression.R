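# Immune-cell expression checks against a labelled single-cell count matrix.
#
# A gene "expresses" in a cell iff its raw count is > 0 — presence/absence on
# raw counts, no normalization, matching how integer cell counts are reported.

#' Default immune-label mapping for breast tumor microenvironment cell types
#'
#' The label vocabulary of published breast-tumor single-cell atlases:
#' T-cells, myeloid cells, B-cells and plasmablasts (and NK cells) are immune;
#' epithelial, fibroblast (CAF), endothelial and perivascular (PVL)
#' populations are not.
#'
#' @return named logical vector: label -> is_immune.
#' @export
default_immune_labels <- function() {
  c("T-cells" = TRUE, "Myeloid" = TRUE, "B-cells" = TRUE,
    "Plasmablasts" = TRUE, "NK-cells" = TRUE,
    "Cancer Epithelial" = FALSE, "Normal Epithelial" = FALSE,
    "CAFs" = FALSE, "Endothelial" = FALSE, "PVL" = FALSE)
}

#' Construct a labelled cell matrix
#'
#' @param counts a sparse (or dense) non-negative integer matrix, genes in
#'   rows, cells in columns.
#' @param genes gene symbols (row names).
#' @param barcodes cell barcodes (column names).
#' @param cell_type per-cell label, aligned with `barcodes`.
#' @param immune_labels named logical vector mapping labels to immune status;
#'   defaults to [default_immune_labels()]. Labels absent from the mapping are
#'   treated as non-immune with a warning.
#' @return a list of class `"cell_matrix"` with elements `counts`, `genes`,
#'   `barcodes`, `cell_type`, `is_immune` (per cell).
#' @export
cell_matrix <- function(counts, genes, barcodes, cell_type,
                        immune_labels = default_immune_labels()) {
  counts <- methods::as(methods::as(methods::as(
    counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(genes)) {
    stop("gene list length does not match matrix rows")
  }
  if (ncol(counts) != length(barcodes)) {
    stop("barcode list length does not match matrix columns")
  }
  if (length(cell_type) != length(barcodes)) {
    stop("every cell must have a cell-type label")
  }
  if (length(counts@x) && any(counts@x < 0)) stop("counts must be non-negative")
  rownames(counts) <- genes
  colnames(counts) <- barcodes
  unknown <- setdiff(unique(cell_type), names(immune_labels))
  if (length(unknown) > 0) {
    warning("cell-type label(s) not in immune mapping, treated as non-immune: ",
            paste(unknown, collapse = ", "))
  }
  is_immune <- unname(immune_labels[cell_type])
  is_immune[is.na(is_immune)] <- FALSE
  structure(list(counts = counts, genes = genes, barcodes = barcodes,
                 cell_type = cell_type, is_immune = is_immune),
            class = "cell_matrix")
}

#' Read a MatrixMarket single-cell bundle with cell-type labels
#'
#' Reads the standard MTX triplet (matrix with genes in rows and cells in
#' columns, a genes file and a barcodes file) plus a two-column cell-type TSV
#' (`barcode`, `cell_type`). Every barcode in the matrix must have a label.
#'
#' @param mtx path to the MatrixMarket counts file.
#' @param barcodes path to the one-per-line barcode file.
#' @param genes path to the one-per-line gene-symbol file.
#' @param celltypes path to the barcode/cell_type TSV (with header).
#' @param immune_labels label -> immune mapping; see [cell_matrix()].
#' @return a `"cell_matrix"` object.
#' @export
read_cell_matrix <- function(mtx, barcodes, genes, celltypes,
                             immune_labels = default_immune_labels()) {
  for (f in c(mtx, barcodes, genes, celltypes)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  counts <- Matrix::readMM(mtx)
  gene_syms <- readLines(genes)
  bcs <- readLines(barcodes)
  labels <- utils::read.delim(celltypes, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  if (!all(c("barcode", "cell_type") %in% names(labels))) {
    stop("cell-type file must have columns 'barcode' and 'cell_type'")
  }
  idx <- match(bcs, labels$barcode)
  if (anyNA(idx)) {
    stop("barcode without cell-type label: ", bcs[which(is.na(idx))[1]])
  }
  cell_matrix(counts, gene_syms, bcs, labels$cell_type[idx], immune_labels)
}

#' Expression summary of one gene across cells
#'
#' Counts the cells in which the gene is expressed (raw count > 0), how many
#' of those are immune cells, the immune fraction
#' `n_immune_cells_expressing / n_cells_expressing` (the ratio behind printed
#' summaries of the form "23% (2,810/12,075)"), the fraction of *immune*
#' cells expressing the gene, and the cell-type breakdown of the immune
#' expressing cells.
#'
#' @param matrix a `"cell_matrix"`.
#' @param gene a gene symbol present in the matrix.
#' @return a list of class `"gene_expression_summary"`: `gene`,
#'   `n_cells_expressing`, `n_immune_cells_expressing`, `immune_fraction`
#'   (NA when the gene is expressed in no cell), `fraction_of_immune_cells`
#'   (share of all immune cells expressing the gene), `celltype_breakdown`
#'   (named fractions over immune labels, summing to 1).
#' @export
summarize_gene_expression <- function(matrix, gene) {
  stopifnot(inherits(matrix, "cell_matrix"))
  i <- match(gene, matrix$genes)
  if (is.na(i)) stop("gene not present in cell matrix: ", gene)
  expr <- matrix$counts[i, ] > 0
  n_expr <- sum(expr)
  imm_expr <- expr & matrix$is_immune
  n_imm <- sum(imm_expr)
  breakdown <- if (n_imm > 0) {
    tab <- table(matrix$cell_type[imm_expr])
    stats::setNames(as.numeric(tab) / n_imm, names(tab))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  structure(list(
    gene = gene,
    n_cells_expressing = n_expr,
    n_immune_cells_expressing = n_imm,
    immune_fraction = if (n_expr > 0) n_imm / n_expr else NA_real_,
    fraction_of_immune_cells = if (sum(matrix$is_immune) > 0) {
      n_imm / sum(matrix$is_immune)
    } else NA_real_,
    celltype_breakdown = breakdown
  ), class = "gene_expression_summary")
}

#' Keep candidate variants whose gene is expressed in immune cells
#'
#' Mutations in genes not expressed in immune cells cannot affect immune
#' function; such candidates are removed. A candidate survives iff its gene is
#' expressed (count > 0) in at least one immune cell.
#'
#' @param summaries named list of `"gene_expression_summary"` objects (or a
#'   `"cell_matrix"`, in which case summaries are computed on the fly).
#' @param candidates per-variant summary table with a `gene` column.
#' @return the surviving subset of `candidates`.
#' @export
filter_expressed_in_immune <- function(summaries, candidates) {
  if (inherits(summaries, "cell_matrix")) {
    mat <- summaries
    summaries <- lapply(unique(candidates$gene), function(g) {
      summarize_gene_expression(mat, g)
    })
    names(summaries) <- unique(candidates$gene)
  }
  need <- unique(candidates$gene)
  missing <- setdiff(need, names(summaries))
  if (length(missing) > 0) {
    stop("candidate gene(s) without expression summary: ",
         paste(missing, collapse = ", "))
  }
  n_imm <- vapply(summaries, function(s) s$n_immune_cells_expressing, numeric(1))
  keep <- n_imm[candidates$gene] > 0
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled immune cell-type composition across candidate genes
#'
#' Pools the immune expressing-cell counts of the given gene summaries and
#' returns per-label fractions (summing to 1) — the composition behind
#' statements like "expressed primarily in T-cells (55.3%) and myeloid cells
#' (35.1%)".
#'
#' @param summaries list of `"gene_expression_summary"` objects.
#' @return named numeric vector of fractions per immune cell-type label.
#' @export
celltype_composition <- function(summaries) {
  if (length(summaries) == 0) stop("at least one gene summary required")
  pooled <- list()
  for (s in summaries) {
    counts <- s$celltype_breakdown * s$n_immune_cells_expressing
    for (lab in names(counts)) {
      pooled[[lab]] <- (if (is.null(pooled[[lab]])) 0 else pooled[[lab]]) +
        counts[[lab]]
    }
  }
  total <- sum(unlist(pooled))
  if (total == 0) stop("no immune expressing cells across summaries")
  vapply(pooled, function(x) x / total, numeric(1))
}
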